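# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers the
# user's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Coerce a person x item response table (tibble/data.frame with optional
# person_id column, or plain matrix) to an integer matrix of category codes
# with item ids as column names.
response_matrix <- function(data) {
  if (is.matrix(data)) {
    m <- data
    storage.mode(m) <- "integer"
    return(m)
  }
  stopifnot(is.data.frame(data))
  df <- as.data.frame(data)
  if ("person_id" %in% names(df)) {
    rn <- as.character(df$person_id)
    df$person_id <- NULL
  } else {
    rn <- as.character(seq_len(nrow(df)))
  }
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  rownames(m) <- rn
  m
}

item_columns <- function(data) {
  setdiff(colnames(data), "person_id")
}

# Gauss-Legendre nodes/weights on [lo, hi]
gl_rule <- function(n, lo, hi) {
  g <- pracma::gaussLegendre(n, lo, hi)
  list(x = g$x, w = g$w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_symmetric <- function(R, tol = 1e-8) {
  if (!is.matrix(R) || nrow(R) != ncol(R) || max(abs(R - t(R))) > tol) {
    stop("`R` must be a symmetric square matrix", call. = FALSE)
  }
  invisible(TRUE)
}

# Tucker's congruence coefficient between two loading vectors.
#' Tucker congruence coefficient
#'
#' Congruence between two factor-loading vectors,
#' \eqn{\sum x y / \sqrt{\sum x^2 \sum y^2}}; 1 in absolute value means
#' proportional loadings.  Used to match bootstrap-resample factors to the
#' point-estimate general factor.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A scalar in \[-1, 1\].
#' @export
tucker_congruence <- function(x, y) {
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}
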