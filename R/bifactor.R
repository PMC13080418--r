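# Exploratory bifactor analysis: minimum-residual extraction followed by
# bi-geomin rotation (geomin complexity on the specific columns, the
# general column unpenalized), by oblique gradient projection.

#' Minimum-residual factor extraction
#'
#' Least-squares fit of a k-factor model to the off-diagonal elements of a
#' correlation matrix: uniquenesses are optimized by L-BFGS-B, and for
#' given uniquenesses the loadings are the scaled leading eigenvectors of
#' the reduced matrix.  Communalities are clipped at 0.995 (Heywood
#' guard) and flagged.
#'
#' @param R Correlation matrix or [polychoric_matrix()] result.
#' @param k Number of factors (1 <= k < number of items).
#' @param max_iter Maximum L-BFGS-B iterations (default 1000).
#' @return List with `loadings` (p x k, columns orthogonal), `uniqueness`,
#'   `communality`, `heywood` (per-item flag), `converged`, `objective`.
#' @export
extract_factors <- function(R, k, max_iter = 1000) {
  if (inherits(R, "polychoric")) R <- R$corr
  assert_symmetric(R)
  p <- nrow(R)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (k >= p) stop("`k` must be < number of items", call. = FALSE)
  lower <- 0.005
  loadings_of <- function(psi) {
    Rs <- R
    diag(Rs) <- 1 - psi
    e <- eigen(Rs, symmetric = TRUE)
    vals <- pmax(e$values[seq_len(k)], 0)
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(vals), k)
  }
  obj <- function(psi) {
    L <- loadings_of(psi)
    resid <- R - tcrossprod(L)
    diag(resid) <- 0
    sum(resid^2) / 2
  }
  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, p))
  psi0 <- pmin(pmax(1 - smc, lower), 1)
  fit <- optim(psi0, obj, method = "L-BFGS-B", lower = lower, upper = 1,
               control = list(maxit = max_iter))
  psi <- fit$par
  L <- loadings_of(psi)
  rownames(L) <- rownames(R)
  colnames(L) <- paste0("F", seq_len(k))
  heywood <- psi <= lower + 1e-8
  if (any(heywood)) {
    warning(sum(heywood), " item(s) at the communality bound (Heywood)",
            call. = FALSE)
  }
  list(loadings = L, uniqueness = psi, communality = rowSums(L^2),
       heywood = heywood, converged = fit$convergence == 0,
       objective = fit$value, k = k)
}

# bi-geomin criterion and gradient: geomin complexity over columns 2..k,
# column 1 (general) unpenalized
vgq_bigeomin <- function(L, epsilon) {
  k <- ncol(L)
  Ls <- L[, -1, drop = FALSE]
  m <- k - 1
  L2 <- Ls^2 + epsilon
  pro <- exp(rowSums(log(L2)) / m)
  G <- matrix(0, nrow(L), k)
  G[, -1] <- (2 / m) * (Ls / L2) * pro
  list(f = sum(pro), G = G)
}

# Oblique gradient-projection rotation (Jennrich's algorithm).
gp_oblique <- function(A, Tmat, vgq, max_iter = 5000, tol = 1e-6) {
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  v <- vgq(L)
  f <- v$f
  G <- -t(t(L) %*% v$G %*% Ti)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(Tmat))
    s <- sqrt(sum(Gp^2))
    if (s < tol) {
      converged <- TRUE
      break
    }
    al <- 2 * al
    for (inner in 1:20) {
      X <- Tmat - al * Gp
      Xn <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(X))
      Ti2 <- solve(Xn)
      L2 <- A %*% t(Ti2)
      v2 <- vgq(L2)
      if (v2$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Xn
    Ti <- Ti2
    L <- L2
    f <- v2$f
    G <- -t(t(L) %*% v2$G %*% Ti)
  }
  Phi <- t(Tmat) %*% Tmat
  list(loadings = L, Phi = Phi, Tmat = Tmat, f = f, converged = converged,
       iterations = iter)
}

# Orthogonal gradient projection (used when oblique = FALSE).
gp_orth <- function(A, Tmat, vgq, max_iter = 5000, tol = 1e-6) {
  al <- 1
  L <- A %*% Tmat
  v <- vgq(L)
  f <- v$f
  G <- crossprod(A, v$G)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    M <- crossprod(Tmat, G)
    S <- (M + t(M)) / 2
    Gp <- G - Tmat %*% S
    s <- sqrt(sum(Gp^2))
    if (s < tol) {
      converged <- TRUE
      break
    }
    al <- 2 * al
    for (inner in 1:20) {
      X <- Tmat - al * Gp
      sv <- svd(X)
      Tt <- sv$u %*% t(sv$v)
      L2 <- A %*% Tt
      v2 <- vgq(L2)
      if (v2$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    L <- L2
    f <- v2$f
    G <- crossprod(A, v2$G)
  }
  list(loadings = L, Phi = diag(ncol(Tmat)), Tmat = Tmat, f = f,
       converged = converged, iterations = iter)
}

#' Bi-geomin rotation
#'
#' Rotates an unrotated loading matrix to a bifactor pattern by gradient
#' projection on the bi-geomin criterion: the geomin simplicity penalty is
#' applied to columns 2..k while column 1 -- the general factor -- is left
#' unpenalized.  The best of `n_starts` random starts (plus the identity)
#' is kept; the common part \eqn{L \Phi L^\top} is invariant under the
#' rotation.
#'
#' @param L Unrotated p x k loading matrix (k >= 2), or the result of
#'   [extract_factors()].
#' @param oblique Allow correlated factors (default `TRUE`).
#' @param epsilon Geomin smoothing constant (default 0.01).
#' @param n_starts Number of random starts (default 30).
#' @param seed Seed for the random starts.
#' @param max_iter,tol Gradient-projection iteration controls.
#' @return An object of class `bifactor_solution`: `loadings`, `factor_corr`,
#'   `uniqueness`, `rotation_criterion_value`, `start_values`, `converged`,
#'   `n_starts`, plus the unrotated matrix.
#' @export
rotate_bigeomin <- function(L, oblique = TRUE, epsilon = 0.01,
                            n_starts = 30, seed = 1,
                            max_iter = 5000, tol = 1e-6) {
  extraction <- NULL
  if (is.list(L) && !is.null(L$loadings)) {
    extraction <- L
    L <- extraction$loadings
  }
  k <- ncol(L)
  if (k < 2) stop("rotation needs k >= 2 columns", call. = FALSE)
  vgq <- function(M) vgq_bigeomin(M, epsilon)
  rotor <- if (oblique) gp_oblique else gp_orth
  starts <- with_seed(seed, {
    c(list(diag(k)), lapply(seq_len(max(n_starts - 1, 0)), function(i) {
      M <- matrix(rnorm(k * k), k, k)
      if (oblique) {
        M %*% diag(1 / sqrt(colSums(M^2)), k)
      } else {
        qr.Q(qr(M))
      }
    }))
  })
  runs <- lapply(starts, function(Tm) {
    tryCatch(rotor(L, Tm, vgq, max_iter = max_iter, tol = tol),
             error = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  conv <- vapply(runs, `[[`, logical(1), "converged")
  if (!any(conv)) {
    stop("bi-geomin rotation failed to converge from every start; ",
         "criterion values: ",
         paste(signif(vapply(runs, `[[`, numeric(1), "f"), 6), collapse = ", "),
         call. = FALSE)
  }
  fvals <- vapply(runs, `[[`, numeric(1), "f")
  fvals[!conv] <- Inf
  best <- runs[[which.min(fvals)]]
  Lr <- best$loadings
  dimnames(Lr) <- dimnames(L)
  Phi <- best$Phi
  dimnames(Phi) <- list(colnames(L), colnames(L))
  uniq <- 1 - rowSums((Lr %*% Phi) * Lr)
  names(uniq) <- rownames(L)
  structure(
    list(loadings = Lr, factor_corr = Phi, uniqueness = uniq,
         rotation_criterion_value = best$f,
         start_values = vapply(runs, `[[`, numeric(1), "f"),
         converged = best$converged, n_starts = length(starts),
         oblique = oblique, epsilon = epsilon,
         unrotated = L, extraction = extraction,
         aligned = FALSE, excluded_items = character(0)),
    class = "bifactor_solution"
  )
}

#' Align the general factor
#'
#' Moves the column with the largest count of absolute loadings at or
#' above `threshold` to position 1 and flips its sign so the mean loading
#' is positive (ties broken by the larger sum of squared loadings, with a
#' warning).  Specific columns are sign-aligned the same way and, when an
#' item specification is given, ordered by the inventory they dominate.
#'
#' @param solution A `bifactor_solution`.
#' @param items Optional item specification tibble (for specific-column
#'   ordering).
#' @param threshold Loading magnitude counted as "loads" (default 0.20).
#' @return The solution with reordered/sign-aligned `loadings` and
#'   `factor_corr`, `aligned = TRUE` and `general_col` recording the
#'   original column.
#' @export
align_general_factor <- function(solution, items = NULL, threshold = 0.20) {
  L <- solution$loadings
  Phi <- solution$factor_corr
  counts <- colSums(abs(L) >= threshold)
  cand <- which(counts == max(counts))
  if (length(cand) > 1) {
    warning("tie between candidate general columns; using largest ",
            "sum of squared loadings", call. = FALSE)
    ss <- colSums(L[, cand, drop = FALSE]^2)
    cand <- cand[which.max(ss)]
  }
  g <- unname(cand[1])
  ord <- c(g, setdiff(seq_len(ncol(L)), g))
  # order specific columns for reporting: by dominant inventory, then size
  spec_cols <- ord[-1]
  if (!is.null(items) && length(spec_cols) > 1) {
    inv_rank <- match(items$inventory[match(rownames(L), items$item_id)],
                      INVENTORIES)
    dom <- vapply(spec_cols, function(j) {
      w <- L[, j]^2
      sum(inv_rank * w, na.rm = TRUE) / sum(w)
    }, numeric(1))
    ss <- colSums(L[, spec_cols, drop = FALSE]^2)
    spec_cols <- spec_cols[order(dom, -ss)]
    ord <- c(g, spec_cols)
  }
  L <- L[, ord, drop = FALSE]
  Phi <- Phi[ord, ord, drop = FALSE]
  signs <- ifelse(colMeans(L) < 0, -1, 1)
  L <- sweep(L, 2, signs, `*`)
  Phi <- diag(signs) %*% Phi %*% diag(signs)
  dimnames(Phi) <- list(colnames(L), colnames(L))
  colnames(L)[1] <- "general"
  dimnames(Phi) <- list(colnames(L), colnames(L))
  solution$loadings <- L
  solution$factor_corr <- Phi
  solution$aligned <- TRUE
  solution$general_col <- g
  solution$threshold <- threshold
  solution
}

#' Share of factor-explained covariance carried by the general factor
#'
#' Sum of squared general-column loadings over the total sum of squared
#' loadings across all columns, as a percentage.  With oblique factors the
#' loadings are first orthogonalized through the Cholesky factor of the
#' factor correlation matrix (general factor first, so shared variance is
#' credited to it).
#'
#' @param solution An aligned `bifactor_solution`.
#' @return Percentage in \[0, 100\].
#' @export
general_factor_covariance_share <- function(solution) {
  L <- solution$loadings
  Phi <- solution$factor_corr
  Lo <- L %*% t(chol(Phi))
  100 * sum(Lo[, 1]^2) / sum(Lo^2)
}

#' Fit an exploratory bifactor model
#'
#' Convenience wrapper: polychoric correlation (if raw data are given),
#' minres extraction, bi-geomin rotation and general-factor alignment.
#'
#' @param data Person x item data, correlation matrix, or `polychoric`
#'   object.
#' @param k Total number of factors (general + specific).
#' @param items Optional item specification for column ordering.
#' @inheritParams rotate_bigeomin
#' @param min_count Truncation threshold when `data` is raw.
#' @param align_threshold Loading cut-off for [align_general_factor()].
#' @return An aligned `bifactor_solution`; the `polychoric` result (if
#'   computed here) is attached as `$polychoric`.
#' @export
fit_bifactor <- function(data, k, items = NULL, oblique = TRUE,
                         epsilon = 0.01, n_starts = 30, seed = 1,
                         min_count = 3, align_threshold = 0.20) {
  pc <- NULL
  if (inherits(data, "polychoric")) {
    pc <- data
    R <- pc$corr
  } else if (is.matrix(data) && isTRUE(all.equal(unname(diag(data)),
                                                 rep(1, ncol(data))))) {
    R <- data
  } else {
    pc <- polychoric_matrix(data, min_count = min_count)
    R <- pc$corr
  }
  ex <- extract_factors(R, k)
  sol <- rotate_bigeomin(ex, oblique = oblique, epsilon = epsilon,
                         n_starts = n_starts, seed = seed)
  sol <- align_general_factor(sol, items = items, threshold = align_threshold)
  sol$polychoric <- pc
  sol
}

#' Screen items for unstable estimates
#'
#' Fits the model, lists items whose extraction hit the Heywood bound
#' (communality clipped at 0.995) or whose rotated loadings exceed
#' `bound` in absolute value, then refits without them.  Mirrors the
#' practice of dropping an item whose extreme, unstable parameters block
#' convergence.
#'
#' @param data Person x item data (or `polychoric`).
#' @param k Number of factors.
#' @param items Optional item specification.
#' @param bound Absolute loading bound (default 1.5).
#' @inheritParams fit_bifactor
#' @return List with `excluded` (item ids), the initial `fit`, and the
#'   `refit` without the excluded items (`NULL` if nothing was excluded).
#' @export
stability_screen <- function(data, k, items = NULL, bound = 1.5,
                             oblique = TRUE, epsilon = 0.01,
                             n_starts = 30, seed = 1, min_count = 3) {
  fit <- suppressWarnings(
    fit_bifactor(data, k, items = items, oblique = oblique,
                 epsilon = epsilon, n_starts = n_starts, seed = seed,
                 min_count = min_count)
  )
  ids <- rownames(fit$loadings)
  bad <- fit$extraction$heywood | apply(abs(fit$loadings) > bound, 1, any)
  excluded <- ids[bad]
  refit <- NULL
  if (length(excluded) > 0) {
    keep <- setdiff(ids, excluded)
    dat2 <- if (inherits(data, "polychoric")) {
      data$data[, keep, drop = FALSE]
    } else if (is.matrix(data) && is.null(rownames(data))) {
      data[, keep, drop = FALSE]
    } else {
      df <- tibble::as_tibble(data)
      df[, c(intersect("person_id", names(df)), keep)]
    }
    refit <- suppressWarnings(
      fit_bifactor(dat2, k, items = items, oblique = oblique,
                   epsilon = epsilon, n_starts = n_starts, seed = seed,
                   min_count = min_count)
    )
    refit$excluded_items <- excluded
  }
  list(excluded = excluded, fit = fit, refit = refit)
}

#' @export
print.bifactor_solution <- function(x, ...) {
  cat("<bifactor_solution> ", nrow(x$loadings), " items, ",
      ncol(x$loadings), " factors (", if (x$oblique) "oblique" else "orthogonal",
      " bi-geomin), criterion ", signif(x$rotation_criterion_value, 6),
      if (x$aligned) ", aligned" else "", "\n", sep = "")
  invisible(x)
}

#' @describeIn rotate_bigeomin Long tibble of rotated loadings.
#' @param x A `bifactor_solution`.
#' @param ... Unused.
#' @method tidy bifactor_solution
#' @export
tidy.bifactor_solution <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "item_id") |>
    tidyr::pivot_longer(-"item_id", names_to = "factor",
                        values_to = "loading")
}

#' @describeIn rotate_bigeomin One-row fit summary.
#' @method glance bifactor_solution
#' @export
glance.bifactor_solution <- function(x, ...) {
  tibble::tibble(
    n_items = nrow(x$loadings),
    n_factors = ncol(x$loadings),
    criterion = x$rotation_criterion_value,
    converged = x$converged,
    n_starts = x$n_starts,
    general_share_pct = if (x$aligned) general_factor_covariance_share(x) else NA_real_
  )
}
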