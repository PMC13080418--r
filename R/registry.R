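# Default registry-like item pool and data-generating model.
#
# The pool mirrors a routine psychotherapy outcome battery: CORE-OM (34
# items, 0-4, with the 10-item CORE-10 embedded subset), PHQ-9 (9 items,
# 0-3), OASIS (5 items, 0-4) and AUDIT-C (3 items, 0-4) -- 51 unique items.
# The generating model is a graded-response factor model with one general
# internalizing factor plus eight content-specific factors; alcohol items
# (AUDIT-C) and the two aggression/risk-to-others CORE-OM items carry no
# general-factor loading, so the general factor is internalizing rather
# than a p-style factor touching every item.

INVENTORIES <- c("CORE_OM", "PHQ9", "OASIS", "AUDIT_C")
SPECIFIC_FACTORS <- c("anxiety", "alcohol", "risk", "mood", "somatic",
                      "functioning", "social", "wellbeing")

# CORE-OM content allocation by item number
CORE_OM_CONTENT <- list(
  risk        = c(6L, 9L, 16L, 22L, 24L, 34L),
  anxiety     = c(2L, 11L, 15L, 20L),
  mood        = c(5L, 17L, 23L, 27L),
  somatic     = c(8L, 18L),
  functioning = c(10L, 12L, 21L, 26L, 29L, 32L),
  social      = c(1L, 3L, 19L, 25L, 30L, 33L),
  wellbeing   = c(4L, 7L, 13L, 14L, 28L, 31L)
)
# aggression / risk-to-others items: no general loading
CORE_OM_AGGRESSION <- c(6L, 22L)
# embedded CORE-10 subset (includes the two high-information mood items and
# one risk item, mirroring the embedded-short-form design)
CORE10_ITEMS <- c(2L, 11L, 13L, 15L, 18L, 23L, 27L, 28L, 31L, 34L)

PHQ9_CONTENT <- list(
  mood = c(1L, 2L, 6L), somatic = c(3L, 4L, 5L),
  functioning = c(7L, 8L), risk = 9L
)

#' Registry item specification
#'
#' The default 51-item pool: 34 CORE-OM items (5 categories, 10 of them
#' flagged as the embedded CORE-10), 9 PHQ-9 items (4 categories), 5 OASIS
#' items (5 categories) and 3 AUDIT-C items (5 categories).
#'
#' @return A tibble with columns `item_id`, `inventory`, `in_core10`,
#'   `n_categories` and `specific` (the content factor the item loads).
#' @export
#' @examples
#' registry_item_spec()
registry_item_spec <- function() {
  pad <- function(inv, i) sprintf("%s_%02d", inv, i)
  specific_of <- function(content, i) {
    hit <- names(content)[vapply(content, function(v) i %in% v, logical(1))]
    hit[1]
  }
  core <- tibble::tibble(
    item_id = pad("CORE_OM", 1:34),
    inventory = "CORE_OM",
    in_core10 = 1:34 %in% CORE10_ITEMS,
    n_categories = 5L,
    specific = vapply(1:34, function(i) specific_of(CORE_OM_CONTENT, i), character(1))
  )
  phq <- tibble::tibble(
    item_id = pad("PHQ9", 1:9),
    inventory = "PHQ9",
    in_core10 = FALSE,
    n_categories = 4L,
    specific = vapply(1:9, function(i) specific_of(PHQ9_CONTENT, i), character(1))
  )
  oasis <- tibble::tibble(
    item_id = pad("OASIS", 1:5), inventory = "OASIS",
    in_core10 = FALSE, n_categories = 5L, specific = "anxiety"
  )
  audit <- tibble::tibble(
    item_id = pad("AUDIT_C", 1:3), inventory = "AUDIT_C",
    in_core10 = FALSE, n_categories = 5L, specific = "alcohol"
  )
  dplyr::bind_rows(core, phq, oasis, audit)
}

# Strictly increasing threshold vector: base profile for the inventory,
# shifted per item and lightly jittered, with a minimum gap enforced.
make_thresholds <- function(base, shift, jitter) {
  tau <- base + shift + jitter
  for (j in seq_along(tau)[-1]) {
    tau[j] <- max(tau[j], tau[j - 1] + 0.15)
  }
  tau
}

#' Registry data-generating model
#'
#' A fixed, admissible graded-response factor model for the 51-item pool:
#' one general factor plus eight specific factors (anxiety, alcohol, risk,
#' mood, somatic, functioning, social, wellbeing).  Loadings are drawn once
#' from fixed uniform ranges under an internal build seed, so the model is
#' a frozen package constant: general loadings of loading items lie in
#' \[0.4, 0.85\], AUDIT-C and the two aggression items have zero general
#' loading, and OASIS loads an anxiety-specific factor strongly.  Factors
#' are uncorrelated (bifactor convention); thresholds emulate a distressed
#' pretreatment population, with a deliberately sparse top category on
#' CORE-OM 22 so the sparse-category truncation rule has work to do.
#'
#' @param items Item specification tibble, by default [registry_item_spec()].
#' @return An object of class `true_model`: list with `loadings` (51 x 9,
#'   column 1 = general), `factor_corr`, `thresholds` (named list),
#'   `uniqueness`, and the `items` tibble.
#' @export
registry_true_model <- function(items = registry_item_spec()) {
  with_seed(20260415, {
    p <- nrow(items)
    k <- 1L + length(SPECIFIC_FACTORS)
    L <- matrix(0, p, k, dimnames = list(items$item_id, c("general", SPECIFIC_FACTORS)))
    zero_general <- items$inventory == "AUDIT_C" |
      items$item_id %in% sprintf("CORE_OM_%02d", CORE_OM_AGGRESSION)
    L[, "general"] <- ifelse(zero_general, 0, runif(p, 0.4, 0.85))
    # Specific (content) factors are bipolar: loadings alternate in sign
    # within a block, as when a block mixes straight- and reverse-worded
    # items.  With uniformly positive specific loadings the general column
    # would lie almost in the span of the specifics, and the smallest
    # structural eigenvalue of the implied correlation matrix would sink
    # below any permutation-null baseline -- the familiar
    # one-factor under-extraction of parallel analysis on bifactor data --
    # making the generating factor count unrecoverable in principle.
    sign_state <- rep(1, k)
    for (i in seq_len(p)) {
      s <- match(items$specific[i], SPECIFIC_FACTORS) + 1L
      lam_s <- if (items$inventory[i] == "OASIS") {
        runif(1, 0.50, 0.70)
      } else if (items$inventory[i] == "AUDIT_C") {
        runif(1, 0.60, 0.80)
      } else if (zero_general[i]) {
        runif(1, 0.55, 0.70)
      } else {
        runif(1, 0.35, 0.60)
      }
      # keep communality comfortably below 1
      lam_s <- min(lam_s, sqrt(max(0.93 - L[i, "general"]^2, 0.02)))
      sgn <- if (items$inventory[i] %in% c("AUDIT_C", "OASIS") ||
                 zero_general[i]) 1 else sign_state[s]
      sign_state[s] <- -sign_state[s]
      L[i, s] <- sgn * lam_s
    }
    Phi <- diag(k)
    dimnames(Phi) <- list(colnames(L), colnames(L))
    uniq <- 1 - rowSums((L %*% Phi) * L)
    base_tau <- list(
      CORE_OM = c(-1.1, -0.1, 0.8, 1.7),
      PHQ9    = c(-0.9, 0.2, 1.2),
      OASIS   = c(-1.3, -0.3, 0.7, 1.7),
      AUDIT_C = c(-0.4, 0.4, 1.1, 1.9)
    )
    rare_tau <- c(0.6, 1.3, 2.0, 2.7) # risk/aggression items are rarely endorsed
    thr <- vector("list", p)
    names(thr) <- items$item_id
    for (i in seq_len(p)) {
      base <- if (items$specific[i] %in% c("risk", "alcohol") &&
                  items$inventory[i] == "CORE_OM") {
        rare_tau
      } else {
        base_tau[[items$inventory[i]]]
      }
      nth <- items$n_categories[i] - 1L
      thr[[i]] <- make_thresholds(base[seq_len(nth)], runif(1, -0.35, 0.35),
                                  runif(nth, -0.15, 0.15))
    }
    # CORE-OM 22: top category deliberately sparse (a handful of counts at
    # registry scale), exercising the truncation rule downstream
    thr[["CORE_OM_22"]][4] <- 3.45
    structure(
      list(loadings = L, factor_corr = Phi, thresholds = thr,
           uniqueness = uniq, items = items),
      class = "true_model"
    )
  })
}

#' Default registry specification
#'
#' Bundles the 51-item specification and the frozen true model used as
#' ground truth in recovery analyses.
#'
#' @return A list with elements `items` and `model`.
#' @export
#' @examples
#' spec <- default_registry_spec()
#' nrow(spec$items)     # 51
#' sum(spec$items$in_core10)  # 10
default_registry_spec <- function() {
  items <- registry_item_spec()
  list(items = items, model = registry_true_model(items))
}

#' @export
print.true_model <- function(x, ...) {
  cat("<true_model> ", nrow(x$loadings), " items, ",
      ncol(x$loadings), " factors (general + ",
      ncol(x$loadings) - 1L, " specific)\n", sep = "")
  cat("  zero-general items:",
      paste(rownames(x$loadings)[x$loadings[, 1] == 0], collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn registry_true_model Tidy the loading matrix into a long tibble.
#' @param x A `true_model`.
#' @param ... Unused.
#' @method tidy true_model
#' @export
tidy.true_model <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "item_id") |>
    tidyr::pivot_longer(-"item_id", names_to = "factor", values_to = "loading") |>
    dplyr::filter(.data$loading != 0 | .data$factor == "general")
}
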