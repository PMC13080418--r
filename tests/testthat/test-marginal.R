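make_solution <- function(L, Phi, items = NULL) {
  rownames(L) <- paste0("i", seq_len(nrow(L)))
  cn <- c("general", if (ncol(L) > 1) paste0("s", seq_len(ncol(L) - 1)))
  colnames(L) <- cn
  dimnames(Phi) <- list(colnames(L), colnames(L))
  structure(
    list(loadings = L, factor_corr = Phi,
         uniqueness = 1 - rowSums((L %*% Phi) * L),
         rotation_criterion_value = 0, start_values = 0, converged = TRUE,
         n_starts = 1, oblique = FALSE, epsilon = 0.01, unrotated = L,
         aligned = TRUE, excluded_items = character(0)),
    class = "bifactor_solution")
}

test_that("factor-to-GRM conversion gives the right conditional slopes", {
  L <- cbind(0.6)
  sol <- make_solution(L, diag(1))
  mgrm <- fa_to_mgrm(sol, list(i1 = 0))
  # conditional discrimination lambda / sqrt(1 - lambda^2) = 0.75
  lam <- mgrm$loading[[1]]
  expect_equal(lam[["general"]] / sqrt(mgrm$uniqueness[[1]]), 0.75,
               tolerance = 1e-12)
  # lambda = 0: flat curves
  sol0 <- make_solution(cbind(0), diag(1))
  mg0 <- marginalize(fa_to_mgrm(sol0, list(i1 = c(-0.5, 0.5))))
  expect_equal(mg0$a_star, 0)
  expect_true(mg0$flagged)
})

test_that("conditional curves match a latent-variable Monte-Carlo simulation", {
  set.seed(61)
  item <- random_admissible_item(3)
  n <- 200000
  Ck <- chol(item$Phi)
  th <- matrix(rnorm(n * 3), n, 3) %*% Ck
  y <- drop(th %*% item$lam) + rnorm(n, sd = sqrt(item$psi))
  # condition on a narrow general-factor stratum around t0
  t0 <- 0.5
  sel <- abs(th[, 1] - t0) < 0.05
  p_hat <- vapply(item$tau, function(tc) mean(y[sel] > tc), numeric(1))
  p_model <- oracle_marginal_curve(item$lam, item$tau, item$psi, item$Phi, t0)
  mc_se <- sqrt(pmax(p_model * (1 - p_model), 1e-4) / sum(sel))
  expect_true(all(abs(p_hat - as.numeric(p_model)) < 3 * mc_se + 0.01))
})

test_that("orthogonal-case marginalization matches hand algebra", {
  L <- cbind(0.6, 0.5)
  sol <- make_solution(L, diag(2))
  mg <- marginalize(fa_to_mgrm(sol, list(i1 = c(-0.4, 0.8))))
  # sigma^2 = (1 - 0.36 - 0.25) + 0.25 = 0.64; a* = 0.6 / 0.8
  expect_equal(mg$a_star, 0.75, tolerance = 1e-12)
  expect_equal(mg$b_star[[1]], c(-0.4, 0.8) / 0.6, tolerance = 1e-12)
  # equals the unidimensional conversion of a lambda = 0.6 item whose
  # uniqueness is 0.64 (the specific loading folded into the error)
  mg_uni <- marginalize(as_mgrm_item(0.6, c(-0.4, 0.8), 0.64, diag(1)))
  expect_equal(mg$a_star, mg_uni$a_star, tolerance = 1e-12)
  expect_equal(mg$b_star[[1]], mg_uni$b_star[[1]], tolerance = 1e-12)
})

test_that("marginalizing a one-factor item is the identity", {
  sol <- make_solution(cbind(0.7), diag(1))
  tau <- c(-1, 0.2, 1.4)
  mg <- marginalize(fa_to_mgrm(sol, list(i1 = tau)))
  expect_equal(mg$a_star, 0.7 / sqrt(1 - 0.49), tolerance = 1e-12)
  expect_equal(mg$b_star[[1]], tau / 0.7, tolerance = 1e-12)
  # zero specific loading: marginal equals conditional exactly
  sol2 <- make_solution(cbind(0.7, 0), diag(2))
  mg2 <- marginalize(fa_to_mgrm(sol2, list(i1 = tau)))
  expect_equal(mg2$a_star, mg$a_star, tolerance = 1e-12)
  expect_equal(mg2$b_star[[1]], mg$b_star[[1]], tolerance = 1e-12)
})

test_that("closed-form marginal equals the quadrature oracle on random items", {
  set.seed(71)
  theta <- seq(-5, 5, length.out = 201)
  for (rep in 1:25) {
    k <- sample(2:9, 1)
    item <- random_admissible_item(k)
    mg <- marginalize(as_mgrm_item(item$lam, item$tau, item$psi, item$Phi))
    if (mg$flagged) next
    curve <- grm_exceedance(mg$a_star, mg$b_star[[1]], theta)
    if (mg$reversed) {
      curve <- 1 - curve[, rev(seq_len(ncol(curve))), drop = FALSE]
    }
    oracle <- oracle_marginal_curve(item$lam, item$tau, item$psi, item$Phi,
                                    theta)
    expect_lt(max(abs(curve - oracle)), 1e-6)
  }
})

test_that("marginal discrimination shrinks under orthogonal specific loadings", {
  set.seed(81)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    lam <- c(runif(1, 0.3, 0.7), runif(k - 1, 0.2, 0.5))
    psi <- 1 - sum(lam^2)
    if (psi <= 0.05) next
    mg <- marginalize(as_mgrm_item(lam, c(-0.5, 0.5), psi, diag(k)))
    conditional_a <- lam[1] / sqrt(psi)
    expect_lt(mg$a_star, conditional_a)
  }
})

test_that("category probabilities sum to one everywhere", {
  set.seed(91)
  theta <- seq(-4, 4, length.out = 81)
  for (rep in 1:10) {
    item <- random_admissible_item(sample(1:4, 1))
    mg <- marginalize(as_mgrm_item(item$lam, item$tau, item$psi, item$Phi))
    P <- grm_category_prob(mg[1, ], theta)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_true(all(P >= -1e-12))
  }
})

test_that("logistic metric round-trips and approximates the ogive to 0.011", {
  sol <- make_solution(cbind(0.65, 0.3), diag(2))
  mg <- marginalize(fa_to_mgrm(sol, list(i1 = c(-1, 0, 1))))
  lg <- to_logistic(mg)
  expect_equal(lg$metric, "logistic")
  back <- to_ogive(lg)
  expect_equal(back$a_star, mg$a_star)
  expect_equal(back$b_star, mg$b_star)
  expect_equal(back$metric, mg$metric)
  # known bound of the 1.702 approximation, checked at unit slope
  z <- seq(-8, 8, length.out = 2001)
  expect_lt(max(abs(pnorm(z) - plogis(1.702 * z))), 0.011)
  one <- as_mgrm_item(c(1, 0) * 0.705, c(0), 1 - 0.705^2, diag(2))
  m1 <- marginalize(one)
  curve_o <- grm_exceedance(m1$a_star, m1$b_star[[1]], z, "ogive")
  curve_l <- grm_exceedance(m1$a_star, m1$b_star[[1]], z, "logistic", 1.702)
  expect_lt(max(abs(curve_o - curve_l)), 0.011)
})
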