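# Independent oracles used across the suite.  These deliberately avoid the
# package's own numerical routines: bivariate normal rectangle
# probabilities come from adaptive 1-D integration of the conditional
# form, maximum-likelihood estimates from grid search, and marginal
# response curves from Gauss-Hermite integration over the nuisance
# direction.

# P(X <= h, Y <= k) for standard bivariate normal, via integrate()
oracle_bvn <- function(h, k, rho) {
  if (abs(rho) < 1e-14) return(pnorm(h) * pnorm(k))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) dnorm(x) * pnorm((k - rho * x) / s),
                   -Inf, h, rel.tol = 1e-12)$value
}

# cell probabilities of a discretized bivariate normal (interior
# thresholds a, b)
oracle_cell_probs <- function(a, b, rho) {
  aa <- c(-Inf, a, Inf)
  bb <- c(-Inf, b, Inf)
  Cm <- matrix(0, length(aa), length(bb))
  for (i in seq_along(aa)) {
    for (j in seq_along(bb)) {
      Cm[i, j] <- if (i == 1 || j == 1) {
        0
      } else if (is.infinite(aa[i]) && is.infinite(bb[j])) {
        1
      } else if (is.infinite(aa[i])) {
        pnorm(bb[j])
      } else if (is.infinite(bb[j])) {
        pnorm(aa[i])
      } else {
        oracle_bvn(aa[i], bb[j], rho)
      }
    }
  }
  Cm[-1, -1] + Cm[-nrow(Cm), -ncol(Cm)] - Cm[-1, -ncol(Cm)] - Cm[-nrow(Cm), -1]
}

oracle_table_loglik <- function(tab, rho) {
  rowc <- rowSums(tab)
  colc <- colSums(tab)
  a <- qnorm(cumsum(rowc)[-length(rowc)] / sum(rowc))
  b <- qnorm(cumsum(colc)[-length(colc)] / sum(colc))
  P <- pmax(oracle_cell_probs(a, b, rho), 1e-300)
  sum(tab * log(P))
}

# brute-force grid ML for the polychoric correlation of a table:
# coarse pass at `coarse`, refined pass at `fine` around the maximum
oracle_grid_polychoric <- function(tab, coarse = 1e-3, fine = 1e-4,
                                   lim = 0.99) {
  grid <- seq(-lim, lim, by = coarse)
  ll <- vapply(grid, function(r) oracle_table_loglik(tab, r), numeric(1))
  best <- grid[which.max(ll)]
  grid2 <- seq(max(-lim, best - 2 * coarse), min(lim, best + 2 * coarse),
               by = fine)
  ll2 <- vapply(grid2, function(r) oracle_table_loglik(tab, r), numeric(1))
  grid2[which.max(ll2)]
}

# marginal exceedance curve P(X >= c | t) by Gauss-Hermite integration of
# the conditional ogive over the nuisance-normal contribution
oracle_marginal_curve <- function(lam, tau, psi, Phi, t, g = 1, n_nodes = 256) {
  gh <- pracma::gaussHermite(n_nodes)
  lam_g <- lam[g]
  lam_s <- lam[-g]
  if (length(lam_s)) {
    Phi21 <- Phi[-g, g]
    Sc <- Phi[-g, -g, drop = FALSE] - tcrossprod(Phi21)
    mu_slope <- lam_g + sum(lam_s * Phi21)
    v <- drop(crossprod(lam_s, Sc %*% lam_s))
  } else {
    mu_slope <- lam_g
    v <- 0
  }
  sapply(tau, function(tc) {
    vapply(t, function(tt) {
      # w ~ N(0, v): physicists' Hermite nodes scaled by sqrt(2v)
      sum(gh$w / sqrt(pi) *
            pnorm((mu_slope * tt + sqrt(2 * v) * gh$x - tc) / sqrt(psi)))
    }, numeric(1))
  })
}

# random admissible multidimensional GRM item with k factors and a random
# positive-definite factor correlation matrix
random_admissible_item <- function(k, n_thresholds = 3) {
  repeat {
    A <- matrix(rnorm(k * k + k), k + 1, k)
    Phi <- stats::cov2cor(crossprod(A) + diag(k) * 0.5)
    lam <- runif(k, -0.6, 0.8)
    if (1 - drop(crossprod(lam, Phi %*% lam)) > 0.05) break
  }
  list(lam = lam, Phi = Phi,
       tau = sort(runif(n_thresholds, -2, 2.5)),
       psi = 1 - drop(crossprod(lam, Phi %*% lam)))
}

# wrap raw parameters as a single-item mgrm table
as_mgrm_item <- function(lam, tau, psi, Phi, id = "item") {
  geninfo:::new_mgrm(item_id = id, loading = list(lam),
                     thresholds = list(tau), uniqueness = psi,
                     factor_corr = Phi)
}

# small simple-structure factor model data generator (ordinal, complete)
simulate_simple_structure <- function(n, n_items_per_factor, n_factors,
                                      loading = 0.7, n_categories = 4,
                                      seed = 1) {
  p <- n_items_per_factor * n_factors
  withr_seed <- function(expr) geninfo:::with_seed(seed, expr)
  withr_seed({
    Th <- matrix(rnorm(n * n_factors), n, n_factors)
    L <- matrix(0, p, n_factors)
    for (f in seq_len(n_factors)) {
      L[(f - 1) * n_items_per_factor + seq_len(n_items_per_factor), f] <- loading
    }
    y <- Th %*% t(L) + matrix(rnorm(n * p), n, p) %*%
      diag(sqrt(1 - rowSums(L^2)), p)
    cuts <- qnorm(seq_len(n_categories - 1) / n_categories)
    X <- apply(y, 2, findInterval, vec = cuts)
    colnames(X) <- paste0("it", seq_len(p))
    storage.mode(X) <- "integer"
    X
  })
}

# cached medium registry cohort shared by the heavier tests
registry_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- default_registry_spec()
      coh <- sample_responses(spec$model, spec$items, n_pre = 1500, seed = 401)
      cache <<- list(spec = spec, cohort = coh,
                     fit = fit_bifactor(coh$pre, k = 9, items = spec$items,
                                        seed = 1))
    }
    cache
  }
})
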