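# End-to-end orchestration of the five analysis stages:
# (1) first-component covariance share of the polychoric matrix,
# (2) parallel analysis (pretreatment and change scores),
# (3) bifactor EFA with bi-geomin rotation and a stability screen,
# (4) marginalization of the specific factors,
# (5) Fisher information statistics per inventory.

#' Run the full inventory-comparison pipeline
#'
#' Executes truncation, polychoric estimation, covariance decomposition
#' and parallel analysis (on pretreatment scores and, when a posttreatment
#' wave is supplied, on change scores), bifactor extraction with bi-geomin
#' rotation and general-factor alignment, an optional stability screen
#' that drops items with extreme estimates, exact marginalization, and the
#' information profile.
#'
#' @param pre Pretreatment person x item tibble (`person_id` + items).
#' @param items Item specification tibble.
#' @param post Optional posttreatment tibble (enables the change-score
#'   stage).
#' @param n_factors Total factor count, or `"auto"` to use the parallel
#'   analysis suggestion (minimum 2).
#' @param exclude_items Item ids to drop before fitting.
#' @param screen Run [stability_screen()] and refit without flagged items
#'   (default `TRUE`).
#' @param min_count Sparse-category truncation threshold (default 3).
#' @param n_random Parallel-analysis permutations (default 100).
#' @param run_parallel Run the parallel-analysis stage (default `TRUE`).
#'   Requires `TRUE` when `n_factors = "auto"`; a re-fit at a known factor
#'   count (e.g. the short-form sensitivity analysis) can skip it.
#' @param pa_criterion `"mean"` (default) or `"p95"`.
#' @param oblique,epsilon,n_starts Rotation settings (see
#'   [rotate_bigeomin()]).
#' @param align_threshold Loading cut-off for the general column.
#' @param screen_bound Absolute loading bound for the stability screen.
#' @param theta_grid,bounds,nodes Information settings (see
#'   [information_profile()]).
#' @param seed Seed for all randomized steps.
#' @param out_dir Optional directory: writes scree/loadings/marginal
#'   parameter CSVs, information curves and summary JSON, and a run
#'   manifest.
#' @return Object of class `pipeline_result`; see the elements
#'   `variance_pre`, `parallel_pre`, `variance_change`, `parallel_change`,
#'   `fit`, `excluded`, `marginal`, `profile`, `comparison`, `meta`.
#' @export
run_pipeline <- function(pre, items, post = NULL, n_factors = "auto",
                         exclude_items = character(0), screen = TRUE,
                         min_count = 3, n_random = 100, run_parallel = TRUE,
                         pa_criterion = "mean", oblique = TRUE,
                         epsilon = 0.01, n_starts = 30,
                         align_threshold = 0.20, screen_bound = 1.5,
                         theta_grid = seq(-4, 4, length.out = 201),
                         bounds = c(-6, 6), nodes = 101, seed = 1,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  keep <- setdiff(intersect(items$item_id, item_columns(pre)), exclude_items)
  pre_use <- pre[, c("person_id", keep)]
  items_use <- items[items$item_id %in% keep, ]

  if (identical(n_factors, "auto") && !run_parallel) {
    stop("`n_factors = \"auto\"` requires `run_parallel = TRUE`", call. = FALSE)
  }
  pc <- stage("polychoric", polychoric_matrix(pre_use, min_count = min_count))
  vd_pre <- stage("explained_covariance", explained_covariance(pc))
  pa_pre <- NULL
  if (run_parallel) {
    pa_pre <- stage("parallel_analysis_pre",
                    parallel_analysis(pre_use, n_random = n_random,
                                      criterion = pa_criterion, seed = seed,
                                      cor_method = "polychoric",
                                      min_count = min_count))
  }
  vd_change <- pa_change <- NULL
  if (!is.null(post)) {
    ch <- stage("change_scores", change_scores(pre_use, post))
    chm <- response_matrix(ch)
    storage.mode(chm) <- "double"
    Rch <- stats::cor(chm, use = "pairwise.complete.obs")
    Rch[is.na(Rch)] <- 0
    diag(Rch) <- 1
    vd_change <- stage("explained_covariance_change", explained_covariance(Rch))
    if (run_parallel) {
      pa_change <- stage("parallel_analysis_change",
                         parallel_analysis(ch, n_random = n_random,
                                           criterion = pa_criterion,
                                           seed = seed,
                                           cor_method = "pearson"))
    }
  }
  k <- if (identical(n_factors, "auto")) max(2L, pa_pre$n_factors) else as.integer(n_factors)

  excluded <- character(0)
  fit <- NULL
  if (screen) {
    sc <- stage("stability_screen",
                stability_screen(pc, k, items = items_use,
                                 bound = screen_bound, oblique = oblique,
                                 epsilon = epsilon, n_starts = n_starts,
                                 seed = seed, min_count = min_count))
    excluded <- sc$excluded
    fit <- if (is.null(sc$refit)) sc$fit else sc$refit
    if (length(excluded)) {
      keep <- setdiff(keep, excluded)
      items_use <- items_use[items_use$item_id %in% keep, ]
    }
  } else {
    fit <- stage("bifactor_efa",
                 suppressWarnings(
                   fit_bifactor(pc, k, items = items_use, oblique = oblique,
                                epsilon = epsilon, n_starts = n_starts,
                                seed = seed,
                                align_threshold = align_threshold)))
  }
  poly_fit <- fit$polychoric %||% pc
  mgrm <- stage("fa_to_mgrm", fa_to_mgrm(fit, poly_fit))
  marginal <- stage("marginalize", marginalize(mgrm))
  profile <- stage("information",
                   information_profile(marginal, items_use,
                                       theta_grid = theta_grid,
                                       bounds = bounds, nodes = nodes))
  comparison <- stage("comparison", comparison_table(profile))
  res <- structure(
    list(polychoric = pc, variance_pre = vd_pre, parallel_pre = pa_pre,
         variance_change = vd_change, parallel_change = pa_change,
         k = k, fit = fit, excluded = excluded, marginal = marginal,
         profile = profile, comparison = comparison,
         general_share = general_factor_covariance_share(fit),
         meta = list(seed = seed, n_factors = n_factors, k = k,
                     min_count = min_count, n_random = n_random,
                     pa_criterion = pa_criterion, oblique = oblique,
                     epsilon = epsilon, n_starts = n_starts,
                     align_threshold = align_threshold,
                     screen = screen, screen_bound = screen_bound,
                     bounds = bounds, nodes = nodes,
                     package_version = as.character(utils::packageVersion("geninfo")))),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> k = ", x$k, "; first component ",
      sprintf("%.1f%%", x$variance_pre$table$pct_explained[1]),
      "; general-factor share ", sprintf("%.1f%%", x$general_share),
      "\n", sep = "")
  if (length(x$excluded)) {
    cat("  excluded by stability screen:",
        paste(x$excluded, collapse = ", "), "\n")
  }
  print(x$comparison)
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(res$variance_pre), file.path(out_dir, "scree_pre.csv"))
  if (!is.null(res$variance_change)) {
    readr::write_csv(tidy(res$variance_change),
                     file.path(out_dir, "scree_change.csv"))
  }
  readr::write_csv(tidy(res$fit), file.path(out_dir, "loadings.csv"))
  readr::write_csv(tibble::as_tibble(res$fit$factor_corr, rownames = "factor"),
                   file.path(out_dir, "factor_corr.csv"))
  readr::write_csv(tidy(res$marginal),
                   file.path(out_dir, "marginal_parameters.csv"))
  readr::write_csv(res$profile$curves,
                   file.path(out_dir, "information_curves.csv"))
  jsonlite::write_json(
    list(totals = res$profile$totals, comparison = res$comparison,
         general_share = res$general_share,
         pct_first_pre = res$variance_pre$table$pct_explained[1],
         suggested_factors_pre = res$parallel_pre$n_factors,
         meta = res$meta),
    file.path(out_dir, "information_summary.json"),
    digits = NA, auto_unbox = TRUE
  )
  invisible(out_dir)
}

#' Sensitivity analysis restricted to the short-form item pool
#'
#' Re-runs the full pipeline after dropping the long-form-only items
#' (CORE-OM items not in the embedded CORE-10), so the short form's
#' information is computed from a joint model of the reduced pool.
#'
#' @inheritParams run_pipeline
#' @param k Factor count for the reduced fit; defaults to the main run's
#'   choice when supplied, else `"auto"`.
#' @param ... Passed to [run_pipeline()].
#' @return A `pipeline_result` for the reduced item pool.
#' @export
core10_sensitivity <- function(pre, items, post = NULL, k = "auto", ...) {
  drop_ids <- items$item_id[items$inventory == "CORE_OM" & !items$in_core10]
  keep <- setdiff(items$item_id, drop_ids)
  items_red <- items[items$item_id %in% keep, ]
  pre_red <- pre[, c("person_id", intersect(keep, item_columns(pre)))]
  post_red <- if (!is.null(post)) {
    post[, c("person_id", intersect(keep, item_columns(post)))]
  }
  res <- run_pipeline(pre_red, items_red, post = post_red, n_factors = k, ...)
  res$meta$sensitivity <- "core10"
  res$meta$dropped_items <- drop_ids
  res
}
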