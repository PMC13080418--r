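test_that("minres recovers an exact one-factor structure", {
  lam <- c(0.8, 0.7, 0.6, 0.5, 0.75, 0.65)
  R <- tcrossprod(lam)
  diag(R) <- 1
  ex <- extract_factors(R, 1)
  expect_true(ex$converged)
  expect_equal(abs(as.numeric(ex$loadings)), lam, tolerance = 1e-4)
  expect_lt(ex$objective, 1e-8)
  expect_error(extract_factors(R, 0), "k")
  expect_error(extract_factors(R, 6), "k")
})

test_that("minres reconstructs a known 3-factor model", {
  L <- matrix(0, 12, 3)
  L[1:4, 1] <- c(0.7, 0.65, 0.6, 0.55)
  L[5:8, 2] <- c(0.75, 0.7, 0.6, 0.5)
  L[9:12, 3] <- c(0.8, 0.6, 0.55, 0.65)
  R <- tcrossprod(L)
  diag(R) <- 1
  ex <- extract_factors(R, 3)
  implied <- tcrossprod(ex$loadings)
  diag(implied) <- 1
  expect_lt(max(abs(implied - R)), 1e-3)
  # unrotated columns orthogonal
  ctc <- crossprod(ex$loadings)
  expect_lt(max(abs(ctc[upper.tri(ctc)])), 1e-6)
  expect_true(all(ex$communality >= 0 & ex$communality <= 1))
})

test_that("a perfect bifactor pattern is a fixed point of bi-geomin", {
  set.seed(10)
  gen <- runif(12, 0.45, 0.8)
  s <- runif(12, 0.35, 0.65)
  block <- rep(1:3, each = 4)
  keying <- rep(c(1, -1), 6)
  L <- cbind(gen = gen,
             s1 = ifelse(block == 1, s, 0) * keying,
             s2 = ifelse(block == 2, s, 0) * keying,
             s3 = ifelse(block == 3, s, 0) * keying)
  sol <- rotate_bigeomin(L, oblique = FALSE, n_starts = 10, seed = 2)
  sol <- align_general_factor(sol)
  # recovered pattern equals the original up to column order/sign,
  # matching columns by Tucker congruence
  rec <- sol$loadings
  congr <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    congr[i, j] <- abs(tucker_congruence(rec[, i], L[, j]))
  }
  perm <- apply(congr, 2, which.max)
  expect_equal(sort(perm), 1:4)  # a genuine permutation
  expect_lt(max(abs(abs(rec[, perm]) - abs(L))), 0.02)
})

test_that("rotation preserves the common part and communalities", {
  set.seed(42)
  X <- simulate_simple_structure(800, 4, 3, loading = 0.65, seed = 23)
  R <- polychoric_matrix(X)$corr
  ex <- extract_factors(R, 3)
  sol <- rotate_bigeomin(ex, oblique = TRUE, n_starts = 10, seed = 1)
  common_rot <- sol$loadings %*% sol$factor_corr %*% t(sol$loadings)
  common_unrot <- tcrossprod(ex$loadings)
  expect_lt(max(abs(common_rot - common_unrot)), 1e-8)
  expect_equal(unname(rowSums((sol$loadings %*% sol$factor_corr) * sol$loadings)),
               unname(ex$communality), tolerance = 1e-8)
  # determinism under the same seed
  sol2 <- rotate_bigeomin(ex, oblique = TRUE, n_starts = 10, seed = 1)
  expect_identical(sol$rotation_criterion_value, sol2$rotation_criterion_value)
  expect_identical(sol$loadings, sol2$loadings)
  # the kept criterion value is the best of all starts
  expect_true(all(sol$rotation_criterion_value <= sol$start_values + 1e-12))
  expect_error(rotate_bigeomin(ex$loadings[, 1, drop = FALSE]), "k >= 2")
})

test_that("general factor alignment moves, flips and thresholds correctly", {
  set.seed(1)
  dense <- runif(10, 0.5, 0.8)
  L <- cbind(a = c(rep(0.6, 3), rep(0, 7)) * rep(c(1, -1), 5),
             b = c(rep(0, 3), rep(0.55, 4), rep(0, 3)) * rep(c(1, -1), 5),
             g = -dense)
  sol <- structure(
    list(loadings = L, factor_corr = diag(3), uniqueness = rep(0.3, 10),
         rotation_criterion_value = 0, start_values = 0, converged = TRUE,
         n_starts = 1, oblique = FALSE, epsilon = 0.01, unrotated = L,
         aligned = FALSE, excluded_items = character(0)),
    class = "bifactor_solution")
  al <- align_general_factor(sol)
  expect_equal(colnames(al$loadings)[1], "general")
  expect_equal(al$general_col, 3)
  expect_true(mean(al$loadings[, 1]) > 0)
  expect_equal(al$loadings[, 1], dense)
})

test_that("registry simulation flags designated zero-general items as non-loading", {
  fx <- registry_fixture()
  g <- fx$fit$loadings[, 1]
  zero_g <- c("AUDIT_C_01", "AUDIT_C_02", "AUDIT_C_03",
              "CORE_OM_06", "CORE_OM_22")
  expect_true(all(abs(g[zero_g]) < 0.20))
  expect_true(all(abs(g[setdiff(names(g), zero_g)]) >= 0.20))
})

test_that("covariance share behaves on canonical cases and the registry", {
  L1 <- cbind(general = c(0.8, 0.7, 0.6))
  sol1 <- structure(list(loadings = L1, factor_corr = diag(1), aligned = TRUE),
                    class = "bifactor_solution")
  expect_equal(general_factor_covariance_share(sol1), 100)
  L2 <- cbind(general = c(0.6, 0.6, 0, 0), s = c(0, 0, 0.6, 0.6))
  sol2 <- structure(list(loadings = L2, factor_corr = diag(2), aligned = TRUE),
                    class = "bifactor_solution")
  expect_equal(general_factor_covariance_share(sol2), 50)
  fx <- registry_fixture()
  Ltrue <- fx$spec$model$loadings
  share_true <- 100 * sum(Ltrue[, 1]^2) / sum(Ltrue^2)
  expect_lt(abs(general_factor_covariance_share(fx$fit) - share_true), 10)
})

test_that("parameter recovery at registry scale is accurate", {
  fx <- registry_fixture()
  g_est <- fx$fit$loadings[, 1]
  g_true <- fx$spec$model$loadings[names(g_est), 1]
  loaders <- g_true > 0
  rmse <- sqrt(mean((g_est[loaders] - g_true[loaders])^2))
  expect_lt(rmse, 0.05)
})

test_that("stability screen is empty on clean data and catches planted pathology", {
  X <- simulate_simple_structure(800, 4, 2, loading = 0.6, seed = 37)
  sc <- stability_screen(X, k = 2, n_starts = 5, seed = 1)
  expect_length(sc$excluded, 0)
  expect_null(sc$refit)
  # plant a duplicate of item 1: its polychoric with the original pins at
  # the bound and extraction drives the pair to the communality clip
  Xp <- cbind(X, bad = X[, 1])
  sc2 <- stability_screen(Xp, k = 3, n_starts = 5, seed = 1)
  expect_true(length(sc2$excluded) >= 1)
  expect_true(all(c(sc2$excluded) %in% c("it1", "bad")))
  expect_true(sc2$refit$converged)
})
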