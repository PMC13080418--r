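# First-component covariance decomposition and Horn's parallel analysis.

#' Covariance explained by principal components
#'
#' Eigendecomposition of a correlation matrix with the share of total
#' variance-covariance carried by each component and the first-to-second
#' ratio, the standard gauge of how dominant the first factor would be.
#'
#' @param R Correlation matrix, or a [polychoric_matrix()] result.
#' @return An object of class `variance_decomposition`: tibble of
#'   `component`, `eigenvalue`, `pct_explained`, plus attributes; see
#'   [tidy()] / [glance()].
#' @export
#' @examples
#' explained_covariance(diag(4))
explained_covariance <- function(R) {
  if (inherits(R, "polychoric")) R <- R$corr
  assert_symmetric(R)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  pct <- 100 * ev / sum(ev)
  structure(
    list(table = tibble::tibble(component = seq_along(ev),
                                eigenvalue = ev, pct_explained = pct),
         ratio_first_to_second = pct[1] / pct[2]),
    class = "variance_decomposition"
  )
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("<variance_decomposition> first component ",
      sprintf("%.1f%%", x$table$pct_explained[1]),
      " (", sprintf("%.1f", x$ratio_first_to_second),
      "x the second)\n", sep = "")
  invisible(x)
}

#' @describeIn explained_covariance Component table as a tibble.
#' @param x A `variance_decomposition`.
#' @param ... Unused.
#' @method tidy variance_decomposition
#' @export
tidy.variance_decomposition <- function(x, ...) x$table

#' @describeIn explained_covariance One-row summary with the first-component
#'   share and first/second ratio.
#' @method glance variance_decomposition
#' @export
glance.variance_decomposition <- function(x, ...) {
  tibble::tibble(
    pct_first = x$table$pct_explained[1],
    pct_second = x$table$pct_explained[2],
    ratio_first_to_second = x$ratio_first_to_second
  )
}

#' Item-level change scores
#'
#' Posttreatment minus pretreatment item scores for persons present in
#' both waves.
#'
#' @param pre,post Person x item tibbles with a shared `person_id` column.
#' @return Tibble of `person_id` plus one difference column per shared
#'   item; differences of a K-category item lie in \[-(K-1), K-1\].
#' @export
change_scores <- function(pre, post) {
  shared_items <- intersect(item_columns(pre), item_columns(post))
  ids <- intersect(pre$person_id, post$person_id)
  if (length(ids) == 0) stop("no overlapping persons", call. = FALSE)
  pre_m <- response_matrix(dplyr::filter(pre, .data$person_id %in% ids))
  post_m <- response_matrix(dplyr::filter(post, .data$person_id %in% ids))
  ord_pre <- match(as.character(ids), rownames(pre_m))
  ord_post <- match(as.character(ids), rownames(post_m))
  d <- post_m[ord_post, shared_items, drop = FALSE] -
    pre_m[ord_pre, shared_items, drop = FALSE]
  dplyr::bind_cols(tibble::tibble(person_id = ids), tibble::as_tibble(d))
}

#' Horn's parallel analysis
#'
#' Compares the observed correlation-matrix eigenvalues to eigenvalues of
#' null datasets obtained by independently permuting each item's column
#' (which preserves every item's marginal distribution exactly).  The
#' suggested factor count is the number of leading observed eigenvalues
#' exceeding the criterion statistic (mean or 95th percentile) of their
#' null counterparts, stopping at the first failure.
#'
#' @param data Person x item tibble or matrix of category codes (or
#'   numeric scores when `cor_method = "pearson"`).
#' @param n_random Number of permutation null datasets (default 100).
#' @param criterion `"mean"` (default) or `"p95"`.
#' @param seed Integer seed for the permutations.
#' @param cor_method `"polychoric"` (default) or `"pearson"`; change
#'   scores, which are differences rather than bounded ordinal scales, are
#'   analysed with Pearson correlations.
#' @param min_count Sparse-category truncation threshold (polychoric only).
#' @return Object of class `parallel_analysis` with the suggested count,
#'   observed eigenvalues and null thresholds.
#' @export
parallel_analysis <- function(data, n_random = 100,
                              criterion = c("mean", "p95"), seed = 1,
                              cor_method = c("polychoric", "pearson"),
                              min_count = 3) {
  criterion <- match.arg(criterion)
  cor_method <- match.arg(cor_method)
  m <- response_matrix(data)
  if (nrow(m) < ncol(m)) {
    warning("fewer persons than items; parallel analysis may be unstable",
            call. = FALSE)
  }
  stopifnot(n_random >= 1)
  eig_of <- function(mm) {
    R <- if (cor_method == "polychoric") {
      polychoric_matrix(mm, min_count = min_count, on_degenerate = "flag")$corr
    } else {
      stats::cor(mm, use = "pairwise.complete.obs")
    }
    R[is.na(R)] <- 0
    diag(R) <- 1
    eigen(R, symmetric = TRUE, only.values = TRUE)$values
  }
  observed <- eig_of(m)
  null_eigs <- with_seed(seed, {
    vapply(seq_len(n_random), function(b) {
      perm <- apply(m, 2, sample)
      eig_of(perm)
    }, numeric(ncol(m)))
  })
  null_mean <- rowMeans(null_eigs)
  null_p95 <- apply(null_eigs, 1, quantile, probs = 0.95, names = FALSE)
  thresholds <- if (criterion == "mean") null_mean else null_p95
  exceeds <- observed > thresholds
  suggested <- if (exceeds[1]) which.min(c(exceeds, FALSE)) - 1L else 0L
  structure(
    list(n_factors = as.integer(suggested),
         observed = observed, null_mean = null_mean, null_p95 = null_p95,
         criterion = criterion, n_random = n_random, seed = seed,
         cor_method = cor_method),
    class = "parallel_analysis"
  )
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat("<parallel_analysis> suggests ", x$n_factors, " factor(s) (",
      x$criterion, " criterion, ", x$n_random, " permutations, ",
      x$cor_method, ")\n", sep = "")
  invisible(x)
}

#' @describeIn parallel_analysis Eigenvalues and null thresholds per
#'   component.
#' @param x A `parallel_analysis`.
#' @param ... Unused.
#' @method tidy parallel_analysis
#' @export
tidy.parallel_analysis <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$observed),
    observed = x$observed,
    null_mean = x$null_mean,
    null_p95 = x$null_p95,
    retained = seq_along(x$observed) <= x$n_factors
  )
}

#' @describeIn parallel_analysis One-row summary.
#' @method glance parallel_analysis
#' @export
glance.parallel_analysis <- function(x, ...) {
  tibble::tibble(n_factors = x$n_factors, criterion = x$criterion,
                 n_random = x$n_random, cor_method = x$cor_method)
}
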