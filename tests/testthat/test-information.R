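ogive_item <- function(a, b) list(a_star = a, b_star = b, metric = "ogive")
logistic_item <- function(a, b) list(a_star = a, b_star = b, metric = "logistic")

test_that("flat items carry zero information; curves are symmetric", {
  theta <- seq(-4, 4, length.out = 41)
  expect_equal(point_item_information(ogive_item(0, c(-1, 1)), theta),
               rep(0, 41))
  # thresholds symmetric about b give a curve symmetric about b
  it <- ogive_item(1.1, c(-0.8, 0.8) + 0.5)
  info <- point_item_information(it, 0.5 + theta)
  expect_equal(info, rev(info), tolerance = 1e-12)
})

test_that("information formula matches a finite-difference derivative oracle", {
  items <- list(ogive_item(1.3, 0.4), ogive_item(0.7, c(-1, 0.2, 1.5)),
                logistic_item(1.1, c(-0.6, 0.9)))
  theta <- seq(-3, 3, length.out = 25)
  h <- 1e-5
  for (it in items) {
    probs <- function(t) grm_category_prob(it, t)
    dpi <- (probs(theta + h) - probs(theta - h)) / (2 * h)
    pi0 <- probs(theta)
    oracle <- rowSums(dpi^2 / pi0)
    expect_equal(point_item_information(it, theta), oracle, tolerance = 1e-6)
  }
})

test_that("test information is additive over items", {
  it <- ogive_item(1.2, c(-0.5, 0.7))
  mg <- tibble::tibble(item_id = c("a", "b"),
                       a_star = c(1.2, 1.2),
                       b_star = list(c(-0.5, 0.7), c(-0.5, 0.7)),
                       metric = "ogive",
                       flagged = FALSE, reversed = FALSE)
  class(mg) <- c("marginal_grm", class(mg))
  theta <- seq(-4, 4, length.out = 31)
  expect_equal(point_test_information(mg, theta),
               2 * point_item_information(it, theta), tolerance = 1e-12)
  expect_equal(point_test_information(mg[1, ], theta),
               point_item_information(it, theta))
})

test_that("embedded subset information never exceeds the full measure", {
  fx <- registry_fixture()
  mg <- marginalize(fa_to_mgrm(fx$fit, fx$fit$polychoric))
  prof <- information_profile(mg, fx$spec$items)
  wide <- tidyr::pivot_wider(prof$curves[, c("inventory", "theta", "point_info")],
                             names_from = "inventory",
                             values_from = "point_info")
  expect_true(all(wide$CORE_10 <= wide$CORE_OM + 1e-12))
  expect_true(all(wide$ALL >= wide$CORE_OM))
  # additivity at each grid point: ALL = sum of the four inventories
  expect_equal(wide$ALL,
               wide$CORE_OM + wide$PHQ9 + wide$OASIS + wide$AUDIT_C,
               tolerance = 1e-12)
})

test_that("total information integrates correctly", {
  expect_equal(total_information(function(t) rep(0, length(t))), 0)
  # logistic 2PL closed form: integral of D^2 a^2 P Q over the line = D a
  it <- logistic_item(1, 0)
  expect_lt(abs(total_information(it, bounds = c(-10, 10)) - 1.702), 1e-3)
  # interval additivity
  it2 <- ogive_item(1.4, c(-1, 0.3, 1.2))
  full <- total_information(it2, bounds = c(-6, 6), nodes = 201)
  parts <- total_information(it2, bounds = c(-6, 0), nodes = 201) +
    total_information(it2, bounds = c(0, 6), nodes = 201)
  expect_lt(abs(full - parts), 1e-9)
})

test_that("totals are insensitive to widening the integration range", {
  fx <- registry_fixture()
  mg <- marginalize(fa_to_mgrm(fx$fit, fx$fit$polychoric))
  ok <- vapply(mg$b_star, function(b) all(abs(b) < 3), logical(1)) &
    mg$a_star > 0
  sub <- mg[ok, ]
  t6 <- total_information(sub, bounds = c(-6, 6))
  t8 <- total_information(sub, bounds = c(-8, 8))
  expect_lt(abs(t8 - t6) / t6, 0.005)
})

test_that("averaging, StdEM and scaling follow their definitions", {
  expect_equal(averaged_total_test_information(51.6, 10), 5.16)
  expect_equal(averaged_total_test_information(26.2, 5), 5.24)
  expect_equal(averaged_total_test_information(0, 7), 0)
  expect_error(averaged_total_test_information(10, 0), "n_items")
  expect_equal(stdem(4), 0.5)
  expect_equal(stdem(1), 1)
  expect_equal(stdem(0), Inf)
  expect_true(stdem(9) < stdem(4))
  curve <- c(1, 2, 3)
  expect_equal(scaled_point_curve(curve, 10), curve)
  expect_equal(scaled_point_curve(curve, 5), 2 * curve)
  expect_equal(scaled_point_curve(curve, 34), 10 * curve / 34)
})

test_that("comparison table ranks by averaged information with differences", {
  tab <- tibble::tibble(inventory = c("PHQ9", "OASIS", "CORE_10"),
                        total = c(27.1, 26.2, 51.6),
                        n_items = c(9, 5, 10))
  cmp <- comparison_table(tab)
  expect_equal(cmp$inventory, c("OASIS", "CORE_10", "PHQ9"))
  expect_equal(cmp$diff_averaged, c(NA, 5.24 - 5.16, 5.16 - 27.1 / 9))
  # permuting the input leaves the output unchanged
  cmp2 <- comparison_table(tab[c(3, 1, 2), ])
  expect_equal(cmp, cmp2)
  # identical inventories: zero difference
  same <- tibble::tibble(inventory = c("A", "B"), total = c(10, 10),
                         n_items = c(5, 5))
  expect_equal(comparison_table(same)$diff_averaged[2], 0)
  expect_error(comparison_table(same[1, ]), "at least 2")
})
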