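# Fisher information statistics about the marginal general factor:
# point and total item/test information, length-averaged information and
# standard error of measurement.

#' Point item information
#'
#' Fisher information of one ordered-categorical item about the general
#' factor at trait value(s) `theta`:
#' \eqn{I(\theta) = \sum_c (\partial \pi_c / \partial \theta)^2 / \pi_c}
#' with \eqn{\pi_c} the marginal category probabilities.  Zero for a flat
#' item (`a_star = 0`); category probabilities are floored at 1e-300.
#'
#' @param item One row of a `marginal_grm`, or a list with `a_star`,
#'   `b_star` and `metric`.
#' @param theta Numeric vector of trait values.
#' @return Numeric vector of non-negative information values.
#' @export
#' @examples
#' it <- list(a_star = 1.2, b_star = c(-1, 0, 1), metric = "ogive")
#' point_item_information(it, 0)
point_item_information <- function(item, theta) {
  a <- item$a_star
  b <- if (is.list(item$b_star)) item$b_star[[1]] else item$b_star
  metric <- item$metric %||% "ogive"
  D <- attr(item, "D") %||% 1.702
  if (is.na(a) || a == 0 || length(b) == 0 || anyNA(b)) {
    return(rep(0, length(theta)))
  }
  z <- outer(theta, b, function(t, bb) a * (t - bb))
  if (metric == "ogive") {
    P <- pnorm(z)
    Q <- pnorm(z, lower.tail = FALSE)
    dP <- a * dnorm(z)
  } else {
    P <- plogis(D * z)
    Q <- plogis(D * z, lower.tail = FALSE)
    dP <- D * a * P * Q
  }
  # virtual boundaries at +/-Inf; pi_c = P(z_c) - P(z_(c+1)), computed from
  # the upper tails when both z are positive to avoid cancellation
  P <- cbind(1, P, 0)
  Q <- cbind(0, Q, 1)
  dP <- cbind(0, dP, 0)
  zpos <- cbind(TRUE, z > 0, FALSE)
  K <- ncol(P) - 1
  info <- numeric(length(theta))
  for (c in seq_len(K)) {
    pic <- ifelse(zpos[, c + 1], Q[, c + 1] - Q[, c], P[, c] - P[, c + 1])
    pic <- pmax(pic, 1e-300)
    dpic <- dP[, c] - dP[, c + 1]
    info <- info + dpic^2 / pic
  }
  info
}

#' Point test information
#'
#' Sum of point item information over a set of marginal items.
#'
#' @param mg A `marginal_grm` (rows = items in the measure).
#' @param theta Numeric vector of trait values.
#' @return Numeric vector, one value per element of `theta`.
#' @export
point_test_information <- function(mg, theta) {
  stopifnot(nrow(mg) >= 1)
  rowSums(point_information_matrix(mg, theta))
}

# items x theta handled as a theta x items matrix internally
point_information_matrix <- function(mg, theta) {
  D <- attr(mg, "D") %||% 1.702
  out <- vapply(seq_len(nrow(mg)), function(i) {
    it <- structure(list(a_star = mg$a_star[i], b_star = mg$b_star[[i]],
                         metric = mg$metric[i]), D = D)
    point_item_information(it, theta)
  }, numeric(length(theta)))
  matrix(out, nrow = length(theta),
         dimnames = list(NULL, mg$item_id))
}

#' Total (item or test) information
#'
#' Area under a point-information curve over a finite trait range, by
#' Gauss-Legendre quadrature (defaults: bounds \[-6, 6\], 101 nodes).
#'
#' @param curve A function of theta, a `marginal_grm` (summed over its
#'   rows), or a single `marginal_grm` row.
#' @param bounds Integration limits (finite, increasing).
#' @param nodes Number of quadrature nodes.
#' @return Scalar total information.
#' @export
#' @examples
#' total_information(function(t) rep(0, length(t)))  # 0
total_information <- function(curve, bounds = c(-6, 6), nodes = 101) {
  stopifnot(length(bounds) == 2, is.finite(bounds), bounds[1] < bounds[2])
  g <- gl_rule(nodes, bounds[1], bounds[2])
  f <- if (is.function(curve)) {
    curve
  } else if (inherits(curve, "marginal_grm") || is.data.frame(curve)) {
    function(t) point_test_information(curve, t)
  } else {
    function(t) point_item_information(curve, t)
  }
  sum(g$w * f(g$x))
}

#' Length-averaged total test information
#'
#' Total test information divided by the number of items in the measure,
#' the per-item yardstick used to compare inventories of different
#' lengths.
#'
#' @param total Total test information.
#' @param n_items Number of items (>= 1).
#' @return Scalar.
#' @export
#' @examples
#' averaged_total_test_information(51.6, 10)  # 5.16
averaged_total_test_information <- function(total, n_items) {
  if (any(n_items < 1)) stop("`n_items` must be >= 1", call. = FALSE)
  total / n_items
}

#' Standard error of measurement
#'
#' \eqn{1/\sqrt{I}} for a point-information value; zero information maps
#' to `Inf`.
#'
#' @param point_info Non-negative information value(s).
#' @return Numeric vector of StdEM values.
#' @export
stdem <- function(point_info) {
  ifelse(point_info > 0, 1 / sqrt(point_info), Inf)
}

#' Scale a point curve to a 10-item set
#'
#' Pointwise \eqn{10 \times I / n_{items}}, so measures of different
#' lengths can be displayed on a common per-10-items scale.
#'
#' @param curve Numeric vector of point information values.
#' @param n_items Number of items in the measure (>= 1).
#' @return Rescaled curve.
#' @export
scaled_point_curve <- function(curve, n_items) {
  if (n_items < 1) stop("`n_items` must be >= 1", call. = FALSE)
  10 * curve / n_items
}

#' Information profile of the inventories
#'
#' Point information, StdEM and total/averaged information per inventory
#' (including the embedded CORE-10 subset and the pooled item set) from a
#' marginal item table.
#'
#' @param mg A `marginal_grm`.
#' @param items Item specification tibble (`item_id`, `inventory`,
#'   `in_core10`).
#' @param theta_grid Grid for the point curves (default 201 points on
#'   \[-4, 4\], the inner ~95% of a standard-normal trait).
#' @param bounds,nodes Integration settings for totals (default \[-6, 6\],
#'   101 Gauss-Legendre nodes).
#' @return Object of class `information_profile` with `curves` (long
#'   tibble: inventory, theta, point_info, stdem, scaled), `totals`
#'   (inventory, n_items, total, averaged), `item_totals`, and settings.
#' @export
information_profile <- function(mg, items,
                                theta_grid = seq(-4, 4, length.out = 201),
                                bounds = c(-6, 6), nodes = 101) {
  items <- items[items$item_id %in% mg$item_id, ]
  groups <- c(
    split(items$item_id, items$inventory),
    list(CORE_10 = items$item_id[items$in_core10], ALL = items$item_id)
  )
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  imat <- point_information_matrix(mg, theta_grid)
  g <- gl_rule(nodes, bounds[1], bounds[2])
  qmat <- point_information_matrix(mg, g$x)
  item_totals <- tibble::tibble(
    item_id = mg$item_id,
    total_info = colSums(qmat * g$w)
  )
  curves <- purrr::imap_dfr(groups, function(ids, nm) {
    pt <- rowSums(imat[, ids, drop = FALSE])
    tibble::tibble(inventory = nm, theta = theta_grid, point_info = pt,
                   stdem = stdem(pt),
                   scaled = scaled_point_curve(pt, length(ids)))
  })
  totals <- purrr::imap_dfr(groups, function(ids, nm) {
    tot <- sum(item_totals$total_info[item_totals$item_id %in% ids])
    tibble::tibble(inventory = nm, n_items = length(ids), total = tot,
                   averaged = averaged_total_test_information(tot, length(ids)))
  })
  structure(
    list(curves = curves, totals = totals, item_totals = item_totals,
         theta_grid = theta_grid, bounds = bounds, nodes = nodes),
    class = "information_profile"
  )
}

#' @export
print.information_profile <- function(x, ...) {
  cat("<information_profile> totals over [", x$bounds[1], ", ",
      x$bounds[2], "]:\n", sep = "")
  print(x$totals)
  invisible(x)
}

#' @describeIn information_profile Per-inventory totals as a tibble.
#' @param x An `information_profile`.
#' @param ... Unused.
#' @method tidy information_profile
#' @export
tidy.information_profile <- function(x, ...) x$totals

#' Ranked inventory comparison
#'
#' Orders inventories by length-averaged total test information
#' (descending) and reports the difference in averaged information
#' between adjacent ranks.
#'
#' @param profile An `information_profile`, or a tibble with columns
#'   `inventory`, `total` and `n_items` (e.g. published totals to check
#'   for internal consistency).
#' @param include Inventories to keep (default: drop the pooled `"ALL"`
#'   row).
#' @return Tibble with `rank`, `inventory`, `n_items`, `total`,
#'   `averaged`, `comparison` and `diff_averaged` (vs the previous rank).
#' @export
#' @examples
#' comparison_table(tibble::tibble(
#'   inventory = c("A", "B"), total = c(26.2, 51.6), n_items = c(5, 10)
#' ))
comparison_table <- function(profile, include = NULL) {
  tab <- if (inherits(profile, "information_profile")) {
    profile$totals
  } else {
    tibble::as_tibble(profile)
  }
  if (!"averaged" %in% names(tab)) {
    tab$averaged <- averaged_total_test_information(tab$total, tab$n_items)
  }
  if (is.null(include)) {
    tab <- dplyr::filter(tab, .data$inventory != "ALL")
  } else {
    tab <- dplyr::filter(tab, .data$inventory %in% include)
  }
  if (nrow(tab) < 2) stop("need at least 2 inventories", call. = FALSE)
  tab <- dplyr::arrange(tab, dplyr::desc(.data$averaged), .data$inventory)
  tab$rank <- seq_len(nrow(tab))
  tab$comparison <- c(NA_character_,
                      paste0(head(tab$rank, -1), ". vs. ", tab$rank[-1], "."))
  tab$diff_averaged <- c(NA_real_, -diff(tab$averaged))
  dplyr::select(tab, "rank", "inventory", "n_items", "total", "averaged",
                "comparison", "diff_averaged")
}
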