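# From factor solution to multidimensional normal-ogive graded-response
# parameters, and exact marginalization over the specific factors.
#
# Conditional model: P(X >= c | theta) = Phi((lambda' theta - tau_c) / sqrt(psi)).
# With the nuisance factors conditionally normal given the general factor t
# (mean Phi21 t, covariance Phi22 - Phi21 Phi12), the marginal is again a
# normal ogive:
#   P(X >= c | t) = Phi((alpha t - tau_c) / sigma),
#   alpha  = lambda_g + lambda_s' Phi21,
#   sigma^2 = psi + lambda_s' (Phi22 - Phi21 Phi12) lambda_s,
# giving marginal discrimination a* = alpha / sigma and boundary locations
# b*_c = tau_c / alpha.  The projection is exact on the ogive metric.

new_mgrm <- function(item_id, loading, thresholds, uniqueness, factor_corr) {
  out <- tibble::tibble(item_id = item_id, loading = loading,
                        thresholds = thresholds, uniqueness = uniqueness)
  attr(out, "factor_corr") <- factor_corr
  class(out) <- c("mgrm", class(out))
  out
}

#' Convert a factor solution to graded-response items
#'
#' Packages each retained item's loading vector, estimated thresholds and
#' implied uniqueness \eqn{1 - \lambda^\top \Phi \lambda} as a
#' multidimensional normal-ogive graded-response item.  Items with
#' non-positive implied uniqueness are flagged and excluded with a
#' warning.
#'
#' @param solution An aligned `bifactor_solution`.
#' @param thresholds A `polychoric` result (or named list of threshold
#'   vectors) covering every retained item.
#' @return An object of class `mgrm`: tibble with list-columns `loading`
#'   and `thresholds` plus `uniqueness`; the factor correlation matrix is
#'   attached as an attribute.
#' @export
fa_to_mgrm <- function(solution, thresholds) {
  stopifnot(inherits(solution, "bifactor_solution"))
  if (!solution$aligned) {
    stop("align the solution first (align_general_factor)", call. = FALSE)
  }
  thr <- if (inherits(thresholds, "polychoric")) thresholds$thresholds else thresholds
  L <- solution$loadings
  Phi <- solution$factor_corr
  ids <- rownames(L)
  missing_thr <- setdiff(ids, names(thr))
  if (length(missing_thr)) {
    stop("no thresholds for item(s): ", paste(missing_thr, collapse = ", "),
         call. = FALSE)
  }
  uniq <- 1 - rowSums((L %*% Phi) * L)
  ok <- uniq > 1e-8
  if (!all(ok)) {
    warning("excluding item(s) with non-positive uniqueness: ",
            paste(ids[!ok], collapse = ", "), call. = FALSE)
  }
  new_mgrm(
    item_id = ids[ok],
    loading = lapply(which(ok), function(i) setNames(L[i, ], colnames(L))),
    thresholds = thr[ids[ok]],
    uniqueness = unname(uniq[ok]),
    factor_corr = Phi
  )
}

#' Marginalize specific factors out of graded-response items
#'
#' Exact normal-ogive marginalization of each item's conditional model
#' over the nuisance (specific) factors, leaving a unidimensional graded
#' response model in the general factor alone: marginal discrimination
#' `a_star` and boundary locations `b_star` (location form,
#' \eqn{\tau_c/\alpha}).  When the marginal slope is negative the item is
#' reverse-coded (sign flip of `a_star` and reflected thresholds) so that
#' `a_star >= 0`; `reversed` records this.  A zero marginal slope with
#' non-trivial thresholds is flagged (`a_star = 0`, `b_star` undefined).
#'
#' @param mgrm An `mgrm` object (see [fa_to_mgrm()]).
#' @param general_index Column of the general factor (default 1).
#' @return An object of class `marginal_grm`: tibble with `item_id`,
#'   `a_star`, `b_star` (list-column), `metric` (`"ogive"`), `flagged`,
#'   `reversed`.
#' @export
marginalize <- function(mgrm, general_index = 1) {
  Phi <- attr(mgrm, "factor_corr")
  k <- ncol(Phi)
  ev <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("factor correlation matrix must be positive definite",
                         call. = FALSE)
  g <- general_index
  rows <- lapply(seq_len(nrow(mgrm)), function(i) {
    lam <- mgrm$loading[[i]]
    tau <- mgrm$thresholds[[i]]
    psi <- mgrm$uniqueness[[i]]
    lam_g <- lam[g]
    lam_s <- lam[-g]
    if (k > 1) {
      Phi21 <- Phi[-g, g]
      Phi22 <- Phi[-g, -g, drop = FALSE]
      Sc <- Phi22 - tcrossprod(Phi21)
      alpha <- lam_g + sum(lam_s * Phi21)
      v <- drop(crossprod(lam_s, Sc %*% lam_s))
    } else {
      alpha <- lam_g
      v <- 0
    }
    sigma <- sqrt(psi + v)
    reversed <- FALSE
    flagged <- FALSE
    if (abs(alpha) < 1e-12) {
      a_star <- 0
      b_star <- rep(NA_real_, length(tau))
      flagged <- length(tau) > 0
    } else {
      if (alpha < 0) {
        # reverse-code: flip category order so the slope is positive
        alpha <- -alpha
        tau <- rev(-tau)
        reversed <- TRUE
      }
      a_star <- alpha / sigma
      b_star <- tau / alpha
    }
    list(a_star = a_star, b_star = b_star, flagged = flagged,
         reversed = reversed)
  })
  out <- tibble::tibble(
    item_id = mgrm$item_id,
    a_star = vapply(rows, `[[`, numeric(1), "a_star"),
    b_star = lapply(rows, `[[`, "b_star"),
    metric = "ogive",
    flagged = vapply(rows, `[[`, logical(1), "flagged"),
    reversed = vapply(rows, `[[`, logical(1), "reversed")
  )
  class(out) <- c("marginal_grm", class(out))
  attr(out, "D") <- 1.702
  out
}

#' Switch a marginal item table between ogive and logistic metrics
#'
#' The logistic metric evaluates the same `a_star`/`b_star` parameters
#' through a logistic link with scaling constant `D` (default 1.702),
#' under which the curves agree with the normal ogive to within about
#' 0.01.  The round trip is exact.
#'
#' @param mg A `marginal_grm`.
#' @param D Scaling constant (default 1.702).
#' @return The table with `metric` switched.
#' @export
to_logistic <- function(mg, D = 1.702) {
  stopifnot(inherits(mg, "marginal_grm"))
  mg$metric <- "logistic"
  attr(mg, "D") <- D
  mg
}

#' @rdname to_logistic
#' @export
to_ogive <- function(mg) {
  stopifnot(inherits(mg, "marginal_grm"))
  mg$metric <- "ogive"
  mg
}

# Boundary curves P(X >= c | theta) for one marginal item; returns a
# length(theta) x length(b) matrix.
grm_exceedance <- function(a_star, b_star, theta, metric = "ogive", D = 1.702) {
  if (length(b_star) == 0 || a_star == 0) {
    return(matrix(0.5, length(theta), length(b_star)))
  }
  z <- outer(theta, b_star, function(t, b) a_star * (t - b))
  if (metric == "ogive") pnorm(z) else plogis(D * z)
}

#' Marginal category probabilities
#'
#' \eqn{P(X = c \mid \theta)} for a single marginal graded-response item,
#' from differences of adjacent boundary curves.
#'
#' @param item One row of a `marginal_grm` (or a list with `a_star`,
#'   `b_star`, `metric`).
#' @param theta Numeric vector of general-factor values.
#' @return Matrix length(theta) x K of probabilities, rows summing to 1.
#' @export
grm_category_prob <- function(item, theta) {
  a <- item$a_star
  b <- if (is.list(item$b_star)) item$b_star[[1]] else item$b_star
  metric <- item$metric %||% "ogive"
  D <- attr(item, "D") %||% 1.702
  if (a == 0 || length(b) == 0) {
    K <- length(b) + 1
    return(matrix(1 / K, length(theta), K))
  }
  P <- grm_exceedance(a, b, theta, metric, D)
  Pfull <- cbind(1, P, 0)
  Pfull[, seq_len(ncol(P) + 1)] - Pfull[, seq_len(ncol(P) + 1) + 1]
}

#' @export
print.marginal_grm <- function(x, ...) {
  cat("<marginal_grm> ", nrow(x), " items on the ", x$metric[1],
      " metric; a* in [", signif(min(x$a_star), 3), ", ",
      signif(max(x$a_star), 3), "]\n", sep = "")
  invisible(x)
}

#' @describeIn marginalize Unnest boundary locations into a long tibble.
#' @param x A `marginal_grm`.
#' @param ... Unused.
#' @method tidy marginal_grm
#' @export
tidy.marginal_grm <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(boundary = purrr::map(.data$b_star, seq_along)) |>
    tidyr::unnest(c("b_star", "boundary")) |>
    dplyr::select("item_id", "a_star", "boundary", "b_star", "metric",
                  "flagged", "reversed")
}
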