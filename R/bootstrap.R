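# Nonparametric bootstrap of the information statistics: persons are
# resampled with replacement and the polychoric -> extraction -> rotation
# -> marginalization -> information chain is re-run per resample with the
# factor count held fixed at the point estimate's k.  Each resample's
# general factor is matched to the point estimate by maximal Tucker
# congruence (with sign correction) before statistics are computed, since
# rotational indeterminacy would otherwise invalidate percentile
# intervals.

#' Bootstrap confidence intervals for the information statistics
#'
#' Percentile 95% confidence intervals for per-inventory total and
#' length-averaged test information and for the adjacent-rank differences
#' in averaged information, from `B` person resamples.  A statistic is
#' flagged as skewed when its point estimate falls outside the central
#' third of its interval, the usual symptom of unstable bifactor
#' estimates.
#'
#' @param pre Pretreatment person x item tibble.
#' @param items Item specification tibble.
#' @param k Total factor count (held fixed across resamples).
#' @param B Number of resamples (default 1000).
#' @param seed Integer seed.
#' @param n_starts Rotation starts per resample (default 5; the point
#'   estimate uses `point_n_starts`).
#' @param point_n_starts Rotation starts for the point estimate
#'   (default 30).
#' @param exclude_items Item ids dropped up front (e.g. from a stability
#'   screen of the point estimate).
#' @inheritParams run_pipeline
#' @return Object of class `bootstrap_result`: tibble with `statistic`,
#'   `inventory`, `estimate`, `lower`, `upper`, `B`, `skewed`; resample
#'   draws, congruences and degenerate-item events are attached as
#'   attributes.
#' @export
bootstrap_pipeline <- function(pre, items, k, B = 1000, seed = 1,
                               n_starts = 5, point_n_starts = 30,
                               exclude_items = character(0),
                               min_count = 3, oblique = TRUE,
                               epsilon = 0.01, align_threshold = 0.20,
                               bounds = c(-6, 6), nodes = 101) {
  stopifnot(B >= 1)
  keep <- setdiff(intersect(items$item_id, item_columns(pre)), exclude_items)
  pre_use <- pre[, c("person_id", keep)]
  items_use <- items[items$item_id %in% keep, ]
  m <- response_matrix(pre_use)

  fit_once <- function(mm, starts, ref_general = NULL) {
    pc <- polychoric_matrix(mm, min_count = min_count, on_degenerate = "flag")
    ex <- suppressWarnings(extract_factors(pc$corr, k))
    sol <- rotate_bigeomin(ex, oblique = oblique, epsilon = epsilon,
                           n_starts = starts, seed = 1)
    if (is.null(ref_general)) {
      sol <- align_general_factor(sol, items = items_use,
                                  threshold = align_threshold)
      congruence <- NA_real_
    } else {
      # congruence matching against the point estimate's general loadings
      cg <- apply(sol$loadings, 2, tucker_congruence, y = ref_general)
      cg[!is.finite(cg)] <- 0  # null loadings (degenerate resample)
      g <- which.max(abs(cg))
      ord <- c(g, setdiff(seq_len(ncol(sol$loadings)), g))
      L <- sol$loadings[, ord, drop = FALSE]
      Phi <- sol$factor_corr[ord, ord, drop = FALSE]
      if (cg[g] < 0) {
        L[, 1] <- -L[, 1]
        Phi[1, ] <- -Phi[1, ]
        Phi[, 1] <- -Phi[, 1]
        diag(Phi) <- 1
      }
      colnames(L)[1] <- "general"
      dimnames(Phi) <- list(colnames(L), colnames(L))
      sol$loadings <- L
      sol$factor_corr <- Phi
      sol$aligned <- TRUE
      congruence <- abs(cg[g])
    }
    mg <- marginalize(suppressWarnings(fa_to_mgrm(sol, pc)))
    prof <- information_profile(mg, items_use,
                                theta_grid = c(-1, 0, 1), # curves unused here
                                bounds = bounds, nodes = nodes)
    list(sol = sol, totals = prof$totals, congruence = congruence,
         degenerate = pc$degenerate_items)
  }

  point <- fit_once(m, point_n_starts)
  ref_general <- point$sol$loadings[, 1]
  ranked <- comparison_table(
    structure(list(totals = point$totals), class = "information_profile")
  )
  stat_vec <- function(totals) {
    tot <- setNames(totals$total, totals$inventory)
    avg <- setNames(totals$averaged, totals$inventory)
    diffs <- avg[ranked$inventory[-nrow(ranked)]] - avg[ranked$inventory[-1]]
    names(diffs) <- paste0("diff_", ranked$inventory[-nrow(ranked)],
                           "_vs_", ranked$inventory[-1])
    c(setNames(tot, paste0("total_", names(tot))),
      setNames(avg, paste0("averaged_", names(avg))), diffs)
  }
  est <- stat_vec(point$totals)

  events <- character(0)
  draws <- matrix(NA_real_, B, length(est),
                  dimnames = list(NULL, names(est)))
  congr <- numeric(B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(m), replace = TRUE)
      rb <- fit_once(m[idx, , drop = FALSE], n_starts,
                     ref_general = ref_general)
      draws[b, ] <- stat_vec(rb$totals)[names(est)]
      congr[b] <- rb$congruence
      if (length(rb$degenerate)) {
        events <- c(events, paste0("resample ", b, ": degenerate item(s) ",
                                   paste(rb$degenerate, collapse = ", ")))
      }
    }
  })
  ci <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  width <- ci[2, ] - ci[1, ]
  skewed <- est < ci[1, ] + width / 3 | est > ci[2, ] - width / 3
  out <- tibble::tibble(
    statistic = names(est),
    inventory = sub("^(total_|averaged_|diff_)", "", names(est)),
    estimate = unname(est),
    lower = unname(ci[1, ]), upper = unname(ci[2, ]),
    B = B, skewed = unname(skewed)
  )
  class(out) <- c("bootstrap_result", class(out))
  attr(out, "draws") <- draws
  attr(out, "congruence") <- congr
  attr(out, "events") <- events
  attr(out, "seed") <- seed
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> B = ", x$B[1], "; mean general-factor congruence ",
      sprintf("%.3f", mean(attr(x, "congruence"), na.rm = TRUE)),
      "\n", sep = "")
  NextMethod()
}
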