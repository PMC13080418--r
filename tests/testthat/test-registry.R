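test_that("registry item pool matches the battery design", {
  items <- registry_item_spec()
  expect_equal(nrow(items), 51)
  expect_equal(sum(items$in_core10), 10)
  expect_true(all(items$inventory[items$in_core10] == "CORE_OM"))
  counts <- table(items$inventory)
  expect_equal(counts[["CORE_OM"]], 34)
  expect_equal(counts[["PHQ9"]], 9)
  expect_equal(counts[["OASIS"]], 5)
  expect_equal(counts[["AUDIT_C"]], 3)
  expect_true(all(items$n_categories[items$inventory == "CORE_OM"] == 5))
  expect_true(all(items$n_categories[items$inventory == "PHQ9"] == 4))
  expect_true(all(items$n_categories[items$inventory %in% c("OASIS", "AUDIT_C")] == 5))
})

test_that("frozen true model is admissible and has the designed structure", {
  spec <- default_registry_spec()
  m <- spec$model
  L <- m$loadings
  # deterministic: same model on every call
  expect_identical(L, registry_true_model()$loadings)
  expect_true(all(m$uniqueness > 0))
  zero_g <- c("AUDIT_C_01", "AUDIT_C_02", "AUDIT_C_03",
              "CORE_OM_06", "CORE_OM_22")
  expect_true(all(L[zero_g, "general"] == 0))
  loaders <- setdiff(rownames(L), zero_g)
  expect_true(all(L[loaders, "general"] >= 0.4 & L[loaders, "general"] <= 0.85))
  # OASIS loads the anxiety specific, AUDIT-C only the alcohol specific
  expect_true(all(L[paste0("OASIS_0", 1:5), "anxiety"] >= 0.5))
  audit <- L[paste0("AUDIT_C_0", 1:3), ]
  expect_true(all(audit[, "alcohol"] > 0))
  expect_true(all(audit[, setdiff(colnames(L), "alcohol")] == 0))
  # thresholds strictly increasing
  expect_true(all(vapply(m$thresholds, function(t) all(diff(t) > 0), logical(1))))
})

test_that("cohort simulation is seed-deterministic and respects completion", {
  spec <- default_registry_spec()
  a <- sample_responses(spec$model, spec$items, n_pre = 300, seed = 9)
  b <- sample_responses(spec$model, spec$items, n_pre = 300, seed = 9)
  expect_identical(a$pre, b$pre)
  expect_identical(a$post, b$post)
  expect_equal(nrow(a$post), floor(0.593 * 300))
  d <- sample_responses(spec$model, spec$items, n_pre = 300, seed = 10)
  expect_false(identical(a$pre, d$pre))
})

test_that("simulated category frequencies follow the model curves", {
  spec <- default_registry_spec()
  m <- spec$model
  # large cohort, fixed latent stratum via regeneration of theta
  coh <- sample_responses(m, spec$items, n_pre = 50000, seed = 77,
                          completion_rate = 0.01)
  theta <- coh$theta_pre
  for (item in c("CORE_OM_01", "PHQ9_05", "OASIS_03")) {
    x <- coh$pre[[item]]
    pexp <- model_exceedance_prob(m, item, theta)
    for (cc in seq_len(ncol(pexp))) {
      phat <- mean(x >= cc)
      p0 <- mean(pexp[, cc])
      se <- sqrt(p0 * (1 - p0) / length(x))
      expect_lt(abs(phat - p0), max(3 * se, 1e-3))
    }
  }
})

test_that("category draws at fixed theta match model probabilities (chi-square)", {
  spec <- default_registry_spec()
  m <- spec$model
  item <- "CORE_OM_03"
  n <- 50000
  theta0 <- setNames(rep(0, ncol(m$loadings)), colnames(m$loadings))
  pexc <- model_exceedance_prob(m, item, rbind(theta0))
  probs <- diff(-c(1, as.numeric(pexc), 0))
  probs <- abs(probs) / sum(abs(probs))
  lam <- m$loadings[item, ]
  set.seed(123)
  ystar <- sum(lam * theta0) + rnorm(n, sd = sqrt(m$uniqueness[[item]]))
  x <- findInterval(ystar, m$thresholds[[item]])
  obs <- tabulate(x + 1, nbins = length(probs))
  pval <- suppressWarnings(chisq.test(obs, p = probs)$p.value)
  expect_gt(pval, 0.01)
})

test_that("no treatment effect leaves pre/post margins equal within MC error", {
  spec <- default_registry_spec()
  coh <- sample_responses(spec$model, spec$items, n_pre = 6000, seed = 31,
                          treatment_effect = 0, stability = 0.5)
  for (item in c("CORE_OM_10", "PHQ9_02")) {
    mpre <- mean(coh$pre[[item]])
    mpost <- mean(coh$post[[item]])
    spre <- sd(coh$pre[[item]]) / sqrt(nrow(coh$post))
    expect_lt(abs(mpre - mpost), 4 * spre)
  }
})

test_that("treatment shifts posttreatment scores down on general-loading items", {
  spec <- default_registry_spec()
  coh <- sample_responses(spec$model, spec$items, n_pre = 3000, seed = 32,
                          treatment_effect = 0.8)
  ch <- change_scores(coh$pre, coh$post)
  gload <- spec$model$loadings[, "general"]
  loaded <- names(gload)[gload >= 0.5]
  expect_true(all(colMeans(ch[loaded]) < 0))
  # untreated alcohol items essentially unshifted
  expect_lt(abs(mean(ch$AUDIT_C_01)), 0.1)
})

test_that("generated pairwise polychorics converge to model-implied correlations", {
  spec <- default_registry_spec()
  m <- spec$model
  coh <- sample_responses(m, spec$items, n_pre = 20000, seed = 55)
  pairs <- list(c("CORE_OM_01", "CORE_OM_03"),
                c("OASIS_01", "OASIS_04"),
                c("CORE_OM_05", "PHQ9_01"))
  for (pr in pairs) {
    lam1 <- m$loadings[pr[1], ]
    lam2 <- m$loadings[pr[2], ]
    rho_true <- drop(crossprod(lam1, m$factor_corr %*% lam2))
    est <- polychoric_pair(coh$pre[[pr[1]]], coh$pre[[pr[2]]])
    expect_lt(abs(as.numeric(est) - rho_true), 0.02)
  }
})

test_that("inadmissible configurations are rejected", {
  spec <- default_registry_spec()
  bad <- spec$model
  bad$uniqueness[1] <- -0.1
  expect_error(sample_responses(bad, spec$items, n_pre = 10, seed = 1),
               "inadmissible")
  expect_error(sample_responses(spec$model, spec$items, n_pre = 0, seed = 1),
               "n_pre")
  expect_error(true_marginal_information(spec$model, "NOPE"), "unknown")
})

test_that("cohort CSV round trip preserves data and encodes missing as empty", {
  spec <- default_registry_spec()
  coh <- sample_responses(spec$model, spec$items, n_pre = 60, seed = 2,
                          missing_rate = 0.1)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  rt <- read_cohort(dir)
  expect_equal(as.data.frame(rt$pre), as.data.frame(coh$pre))
  expect_equal(as.data.frame(rt$post), as.data.frame(coh$post))
  raw <- readLines(file.path(dir, "pre.csv"), n = 2)
  expect_match(raw[1], "^person_id,CORE_OM_01")
})

test_that("true marginal information oracle matches closed forms", {
  spec <- default_registry_spec()
  m <- spec$model
  # an all-zero-general inventory carries no information
  expect_equal(true_marginal_information(m, "AUDIT_C"), 0, tolerance = 1e-6)
  # default model: value equals independent quadrature of summed true curves
  mg <- marginalize(geninfo:::true_model_mgrm(m))
  ids <- m$items$item_id[m$items$inventory == "OASIS"]
  f <- function(t) point_test_information(mg[mg$item_id %in% ids, ], t)
  gl <- pracma::gaussLegendre(301, -6, 6)
  expect_equal(true_marginal_information(m, "OASIS"),
               sum(gl$w * f(gl$x)), tolerance = 1e-6)
})
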