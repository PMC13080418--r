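# Two-step polychoric correlation with pairwise-complete data.
#
# Step 1 fixes each item's thresholds at the normal quantiles of its
# cumulative category proportions; step 2 maximizes the bivariate-normal
# rectangle-probability likelihood of the pair's contingency table over the
# correlation alone (Brent search, tolerance 1e-8, |rho| <= 0.999).  The
# bivariate normal CDF uses Sheppard's arcsine-integral form with fixed
# 48-node Gauss-Legendre quadrature (absolute accuracy ~1e-13).

#' Merge sparse top categories
#'
#' While the highest observed category of an ordinal item has fewer than
#' `min_count` observations (and more than one category remains), its
#' values are merged into the category below; category labels are then
#' renumbered contiguously from 0.  This generalizes the routine handling
#' of rarely endorsed top categories (e.g. an aggression item with only a
#' couple of "most of the time" responses).
#'
#' @param x Integer vector of category codes (0-based), `NA` allowed.
#' @param min_count Minimum observations required to keep the top category
#'   separate (default 3).
#' @return Recoded integer vector, same length as `x`.
#' @export
#' @examples
#' x <- rep(c(0, 1, 2, 3, 4), c(10, 10, 10, 10, 2))
#' table(truncate_sparse_categories(x, min_count = 3))
truncate_sparse_categories <- function(x, min_count = 3) {
  stopifnot(min_count >= 1)
  obs <- x[!is.na(x)]
  if (length(obs) == 0) stop("all values are missing", call. = FALSE)
  repeat {
    lev <- sort(unique(x[!is.na(x)]))
    if (length(lev) < 2) break
    top <- lev[length(lev)]
    if (sum(x == top, na.rm = TRUE) >= min_count) break
    x[!is.na(x) & x == top] <- lev[length(lev) - 1]
  }
  # renumber contiguously
  lev <- sort(unique(x[!is.na(x)]))
  match(x, lev) - 1L
}

#' Estimate item thresholds from marginal proportions
#'
#' Threshold \eqn{c} is the standard-normal quantile of the cumulative
#' proportion of categories \eqn{\le c}, computed on non-missing values.
#'
#' @param x Integer vector of category codes, `NA` allowed.
#' @return Strictly increasing numeric vector of length (categories - 1).
#' @export
#' @examples
#' estimate_thresholds(rep(0:1, c(50, 50)))  # 0
estimate_thresholds <- function(x) {
  obs <- x[!is.na(x)]
  if (length(unique(obs)) < 2) {
    stop("need at least 2 observed categories", call. = FALSE)
  }
  tab <- table(obs)
  cum <- cumsum(tab) / sum(tab)
  unname(qnorm(cum[-length(cum)]))
}

#' Polychoric correlation of a pair of ordinal items
#'
#' Two-step maximum likelihood on pairwise-complete observations:
#' thresholds fixed from the pair's margins, then the correlation maximizes
#' the bivariate-normal rectangle-probability likelihood of the
#' contingency table.  The estimate is bounded to \eqn{|\rho| \le 0.999};
#' a degenerate table (fewer than two observed categories on either
#' margin, or an estimate pinned at the bound) is flagged.
#'
#' @param x,y Integer vectors of category codes, `NA` allowed.
#' @param rho_max Bound on \eqn{|\rho|} (default 0.999).
#' @param tol Brent search tolerance (default 1e-8).
#' @return The correlation estimate, with attributes `n` (pairwise-complete
#'   count) and `flagged` (degenerate/boundary indicator).
#' @export
polychoric_pair <- function(x, y, rho_max = 0.999, tol = 1e-8) {
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no pairwise-complete observations", call. = FALSE)
  x <- x[ok]
  y <- y[ok]
  tab <- table(factor(x, levels = min(x):max(x)),
               factor(y, levels = min(y):max(y)))
  res <- .polychoric_table_cpp(unclass(as.matrix(tab)), rho_max, tol)
  rho <- res$rho
  flagged <- isTRUE(res$degenerate)
  if (is.na(rho)) {
    warning("degenerate contingency table; returning 0", call. = FALSE)
    rho <- 0
    flagged <- TRUE
  } else if (flagged) {
    warning("polychoric estimate at bound; table nearly degenerate",
            call. = FALSE)
  }
  structure(rho, n = sum(ok), flagged = flagged)
}

#' Pairwise-complete polychoric correlation matrix
#'
#' Applies [truncate_sparse_categories()] per item, estimates all
#' thresholds from item margins and all pairwise correlations by two-step
#' ML on pairwise-complete rows.  If the smallest eigenvalue of the
#' assembled matrix falls below `smooth_tol`, eigenvalues are clipped at
#' `smooth_tol`, the matrix reconstructed and rescaled to unit diagonal
#' (`smoothed = TRUE`).
#'
#' @param data Person x item tibble (optional `person_id` column) or
#'   integer matrix of category codes.
#' @param min_count Sparse-category threshold passed to
#'   [truncate_sparse_categories()] (default 3).
#' @param smooth_tol Eigenvalue floor for the positive-semidefinite repair
#'   (default 1e-6).
#' @param rho_max,tol Passed to the pair estimator.
#' @param on_degenerate `"error"` (default) aborts when an item has fewer
#'   than two observed categories after truncation; `"flag"` keeps the item
#'   with zero correlations and marks it in `degenerate_items` (used by the
#'   bootstrap, where a resample can collapse an item).
#' @return An object of class `polychoric`: list with `corr`, `thresholds`
#'   (named list), `pair_n`, `smoothed`, `flagged` (pair matrix),
#'   `degenerate_items`, and the truncated `data` matrix.
#' @export
#' @examples
#' spec <- default_registry_spec()
#' coh <- sample_responses(spec$model, spec$items, n_pre = 300, seed = 7)
#' pc <- polychoric_matrix(coh$pre)
#' pc$corr[1:3, 1:3]
polychoric_matrix <- function(data, min_count = 3, smooth_tol = 1e-6,
                              rho_max = 0.999, tol = 1e-8,
                              on_degenerate = c("error", "flag")) {
  on_degenerate <- match.arg(on_degenerate)
  m <- response_matrix(data)
  if (ncol(m) < 2) stop("need at least 2 items", call. = FALSE)
  degenerate_items <- character(0)
  for (j in seq_len(ncol(m))) {
    m[, j] <- truncate_sparse_categories(m[, j], min_count)
    if (length(unique(m[!is.na(m[, j]), j])) < 2) {
      if (on_degenerate == "error") {
        stop("item ", colnames(m)[j],
             " has fewer than 2 observed categories after truncation",
             call. = FALSE)
      }
      degenerate_items <- c(degenerate_items, colnames(m)[j])
    }
  }
  res <- .polychoric_matrix_cpp(m, rho_max, tol)
  R <- res$rho
  dimnames(R) <- list(colnames(m), colnames(m))
  N <- res$pair_n
  dimnames(N) <- dimnames(R)
  flagged <- res$flagged
  dimnames(flagged) <- dimnames(R)
  if (length(degenerate_items)) {
    R[degenerate_items, ] <- 0
    R[, degenerate_items] <- 0
    diag(R) <- 1
  }
  thresholds <- lapply(seq_len(ncol(m)), function(j) {
    if (colnames(m)[j] %in% degenerate_items) return(numeric(0))
    estimate_thresholds(m[, j])
  })
  names(thresholds) <- colnames(m)
  smoothed <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < smooth_tol) {
    vals <- pmax(ev$values, smooth_tol)
    R2 <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(R2))
    R <- R2 / tcrossprod(d)
    diag(R) <- 1
    R <- (R + t(R)) / 2
    dimnames(R) <- dimnames(N)
    smoothed <- TRUE
  }
  structure(
    list(corr = R, thresholds = thresholds, pair_n = N,
         smoothed = smoothed, flagged = flagged,
         degenerate_items = degenerate_items, data = m,
         min_count = min_count),
    class = "polychoric"
  )
}

#' @export
print.polychoric <- function(x, ...) {
  cat("<polychoric> ", ncol(x$corr), " items, pairwise n in [",
      min(x$pair_n[upper.tri(x$pair_n)]), ", ",
      max(x$pair_n[upper.tri(x$pair_n)]), "], smoothed = ",
      x$smoothed, "\n", sep = "")
  invisible(x)
}

#' @describeIn polychoric_matrix Long tibble of pairwise estimates.
#' @param x A `polychoric` object.
#' @param ... Unused.
#' @method tidy polychoric
#' @export
tidy.polychoric <- function(x, ...) {
  p <- colnames(x$corr)
  idx <- which(upper.tri(x$corr), arr.ind = TRUE)
  tibble::tibble(
    item1 = p[idx[, 1]], item2 = p[idx[, 2]],
    rho = x$corr[idx], n = x$pair_n[idx], flagged = x$flagged[idx]
  )
}

#' Bivariate standard normal CDF
#'
#' \eqn{P(X \le h, Y \le k)} for standard normal variables with
#' correlation `rho`, by Sheppard's arcsine-integral form under fixed
#' Gauss-Legendre quadrature.  Vectorized over its arguments.
#'
#' @param h,k Upper limits.
#' @param rho Correlation(s) in \[-0.999, 0.999\].
#' @return Numeric vector of probabilities.
#' @export
#' @examples
#' bvn_cdf(0, 0, 0.6)  # 1/4 + asin(0.6) / (2 * pi)
bvn_cdf <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  .bvn_cdf_cpp(rep_len(h, n), rep_len(k, n), rep_len(rho, n))
}
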