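# Synthetic registry-like cohort generation from a known graded-response
# factor model, plus the ground-truth information oracle.

#' Simulate a registry-like cohort
#'
#' Draws ordinal pre- and posttreatment responses from a multidimensional
#' normal-ogive graded response model.  Latent factors are multivariate
#' normal with the model's factor correlation matrix; the underlying item
#' response is \eqn{y^* = \lambda^\top\theta + \epsilon} with normal error
#' variance equal to the item uniqueness, and the observed category is the
#' number of thresholds below \eqn{y^*}.  A random subset of
#' `floor(completion_rate * n_pre)` persons completes the posttreatment
#' wave, where the general factor is shifted down by `treatment_effect`
#' (in SD units) and carries fresh variation controlled by `stability`
#' (latent pre/post correlation), so change scores retain a factor
#' structure rather than being pure noise.
#'
#' @param model A `true_model`, e.g. [registry_true_model()].
#' @param items Item specification tibble matching `model`.
#' @param n_pre Number of pretreatment respondents (default 5223).
#' @param completion_rate Share completing posttreatment (default 0.593).
#' @param treatment_effect Downward shift of the general factor at
#'   posttreatment, in SD units (default 0.8, a typical pre/post
#'   psychotherapy effect size).
#' @param stability Latent autocorrelation of each factor across waves
#'   (default 0.5).
#' @param missing_rate Item-level missing-completely-at-random rate
#'   (default 0).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return An object of class `cohort`: list with tibbles `pre` and `post`
#'   (first column `person_id`, then one integer column per item, `NA` for
#'   missing), the latent scores `theta_pre`/`theta_post`, and `completers`.
#' @export
#' @examples
#' spec <- default_registry_spec()
#' coh <- sample_responses(spec$model, spec$items, n_pre = 200, seed = 1)
#' dim(coh$pre)
sample_responses <- function(model, items, n_pre = 5223,
                             completion_rate = 0.593,
                             treatment_effect = 0.8,
                             stability = 0.5,
                             missing_rate = 0,
                             seed = 1) {
  stopifnot(inherits(model, "true_model") || is.list(model))
  if (n_pre < 1) stop("`n_pre` must be >= 1", call. = FALSE)
  if (any(model$uniqueness <= 0)) {
    stop("inadmissible model: non-positive uniqueness", call. = FALSE)
  }
  if (completion_rate <= 0 || completion_rate > 1) {
    stop("`completion_rate` must be in (0, 1]", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  L <- model$loadings
  p <- nrow(L)
  k <- ncol(L)
  with_seed(seed, {
    Ck <- chol(model$factor_corr)
    theta_pre <- matrix(rnorm(n_pre * k), n_pre, k) %*% Ck
    colnames(theta_pre) <- colnames(L)
    pre <- draw_categories(theta_pre, model)
    n_post <- floor(completion_rate * n_pre)
    completers <- sort(sample.int(n_pre, n_post))
    innov <- matrix(rnorm(n_post * k), n_post, k) %*% Ck
    theta_post <- stability * theta_pre[completers, , drop = FALSE] +
      sqrt(1 - stability^2) * innov
    theta_post[, 1] <- theta_post[, 1] - treatment_effect
    post <- draw_categories(theta_post, model)
    if (missing_rate > 0) {
      pre[matrix(runif(length(pre)) < missing_rate, nrow(pre))] <- NA_integer_
      post[matrix(runif(length(post)) < missing_rate, nrow(post))] <- NA_integer_
    }
    as_wave <- function(m, ids) {
      dplyr::bind_cols(tibble::tibble(person_id = ids),
                       tibble::as_tibble(m))
    }
    structure(
      list(pre = as_wave(pre, seq_len(n_pre)),
           post = as_wave(post, completers),
           theta_pre = theta_pre, theta_post = theta_post,
           completers = completers,
           config = list(n_pre = n_pre, completion_rate = completion_rate,
                         treatment_effect = treatment_effect,
                         stability = stability,
                         missing_rate = missing_rate, seed = seed)),
      class = "cohort"
    )
  })
}

# categorize underlying responses for a matrix of latent scores
draw_categories <- function(theta, model) {
  n <- nrow(theta)
  L <- model$loadings
  p <- nrow(L)
  ystar <- theta %*% t(L) +
    matrix(rnorm(n * p), n, p) %*% diag(sqrt(model$uniqueness), p)
  X <- matrix(0L, n, p, dimnames = list(NULL, rownames(L)))
  for (j in seq_len(p)) {
    X[, j] <- as.integer(rowSums(outer(ystar[, j], model$thresholds[[j]], `>`)))
  }
  X
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$pre), " pretreatment x ",
      ncol(x$pre) - 1L, " items; ", nrow(x$post),
      " posttreatment completers\n", sep = "")
  invisible(x)
}

#' Model-implied category response curve
#'
#' \eqn{P(X \ge c \mid \theta)} under the generating model, marginal over
#' the item's error only (latent scores fixed).  Used as a closed-form
#' check of the simulated category frequencies.
#'
#' @param model A `true_model`.
#' @param item_id Item identifier.
#' @param theta Matrix (or vector) of latent factor scores, one row per
#'   person, columns in the model's factor order.
#' @return Matrix persons x (K-1) of exceedance probabilities.
#' @export
model_exceedance_prob <- function(model, item_id, theta) {
  theta <- rbind(theta)
  lam <- model$loadings[item_id, ]
  eta <- drop(theta %*% lam)
  tau <- model$thresholds[[item_id]]
  s <- sqrt(model$uniqueness[[item_id]])
  sapply(tau, function(t) pnorm((eta - t) / s))
}

#' Ground-truth marginal information of an inventory
#'
#' Applies the exact normal-ogive marginalization to the true model's item
#' parameters and integrates the resulting Fisher information about the
#' general factor, giving the target value that estimates from synthetic
#' data should recover.
#'
#' @param model A `true_model`.
#' @param inventory One of `"CORE_OM"`, `"PHQ9"`, `"OASIS"`, `"AUDIT_C"`,
#'   `"CORE_10"` (the embedded subset) or `"ALL"`.
#' @param bounds,nodes Integration range and Gauss-Legendre node count,
#'   defaults \[-6, 6\] with 101 nodes.
#' @return Total test information about the general factor (scalar).
#' @export
true_marginal_information <- function(model, inventory,
                                      bounds = c(-6, 6), nodes = 101) {
  items <- model$items
  ids <- switch(inventory,
    ALL = items$item_id,
    CORE_10 = items$item_id[items$in_core10],
    {
      if (!inventory %in% items$inventory) {
        stop("unknown inventory: ", inventory, call. = FALSE)
      }
      items$item_id[items$inventory == inventory]
    }
  )
  mg <- marginalize(true_model_mgrm(model, ids))
  sum(vapply(seq_len(nrow(mg)), function(i) {
    total_information(mg[i, ], bounds = bounds, nodes = nodes)
  }, numeric(1)))
}

# package the true parameters of selected items as an mgrm table
true_model_mgrm <- function(model, ids = rownames(model$loadings)) {
  idx <- match(ids, rownames(model$loadings))
  new_mgrm(
    item_id = ids,
    loading = lapply(idx, function(i) model$loadings[i, ]),
    thresholds = model$thresholds[idx],
    uniqueness = unname(model$uniqueness[idx]),
    factor_corr = model$factor_corr
  )
}

#' Write / read a cohort as plain CSV
#'
#' One CSV per wave: first column `person_id`, remaining columns named
#' `<inventory>_<item>`; missing cells are empty.  The true model can be
#' stored alongside as JSON.
#'
#' @param cohort A `cohort` object.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` invisibly returns the paths written;
#'   `read_cohort` returns a list with `pre` and `post` tibbles.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pre = file.path(dir, "pre.csv"), post = file.path(dir, "post.csv"))
  readr::write_csv(cohort$pre, paths[["pre"]], na = "")
  readr::write_csv(cohort$post, paths[["post"]], na = "")
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f) {
    readr::read_csv(f, na = "", show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_integer()))
  }
  list(pre = rd(file.path(dir, "pre.csv")),
       post = rd(file.path(dir, "post.csv")))
}

#' @rdname write_cohort
#' @param model A `true_model`.
#' @param path JSON file path.
#' @export
write_true_model <- function(model, path) {
  obj <- list(
    loadings = as.data.frame(model$loadings),
    item_id = rownames(model$loadings),
    factor_corr = unname(as.data.frame(model$factor_corr)),
    thresholds = model$thresholds,
    uniqueness = as.list(model$uniqueness)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
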