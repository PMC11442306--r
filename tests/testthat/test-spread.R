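test_that("spread-rate scalars take their printed values at the reference indices", {
  # the BUI exponential equals 1 exactly at the reference BUI
  expect_equal(spread_rate(1e9, 64, "needleleaf", 2.3), 2.3 * 0.7568,
               tolerance = 1e-9)
  expect_equal(spread_rate(1e9, 32, "broadleaf", 0.92), 0.92 * 0.8482,
               tolerance = 1e-9)
  # fully cured grass asymptote 1.3 * vdmax
  expect_equal(spread_rate(1e4, 0, "grass", 4.97, r_green = 0), 1.3 * 4.97,
               tolerance = 1e-6)
  # zero ISI kills every branch
  expect_equal(spread_rate(0, 100, "needleleaf", 2.3), 0)
  expect_equal(spread_rate(0, 100, "broadleaf", 0.92), 0)
  expect_equal(spread_rate(0, 0, "grass", 4.97, r_green = 0.5), 0)
  expect_error(spread_rate(5, 50, "shrubland", 1), "spread_class")
  expect_error(spread_rate(5, 50, "grass", 4.97), "r_green")
})

test_that("tree spread scalars are normalized to 1 in the large-index limit", {
  expect_equal(spread_rate(1e6, 1e6, "needleleaf", 1), 1, tolerance = 1e-3)
  expect_equal(spread_rate(1e6, 1e6, "broadleaf", 1), 1, tolerance = 1e-3)
})

test_that("tree spread rates are nondecreasing in ISI and BUI", {
  set.seed(11)
  for (cl in c("needleleaf", "broadleaf")) {
    for (i in 1:50) {
      isi <- sort(runif(2, 0, 30))
      bui <- sort(runif(2, 1, 200))
      expect_gte(spread_rate(isi[2], bui[1], cl, 2),
                 spread_rate(isi[1], bui[1], cl, 2))
      expect_gte(spread_rate(isi[1], bui[2], cl, 2),
                 spread_rate(isi[1], bui[1], cl, 2))
    }
  }
})

test_that("grass branch endpoints reproduce the pure-green and pure-cured forms", {
  isi <- c(0.5, 2, 8, 25)
  vdmax <- 4.97
  green <- vdmax * (1 - exp(-0.031 * isi))^1.4
  cured <- 1.3 * vdmax * (1 - exp(-0.035 * isi))^1.7
  expect_equal(spread_rate(isi, 0, "grass", vdmax, r_green = 1), green)
  expect_equal(spread_rate(isi, 0, "grass", vdmax, r_green = 0), cured)
  # interior mixes the two linearly
  expect_equal(spread_rate(isi, 0, "grass", vdmax, r_green = 0.3),
               0.3 * green + 0.7 * cured)
})

test_that("ellipse elongation starts circular and saturates with wind", {
  expect_equal(length_to_breadth(0), 1)
  expect_equal(length_to_breadth(10), 5.511884, tolerance = 1e-6)
  expect_equal(length_to_breadth(1e6), 11)
  w <- seq(0, 80, by = 2)
  expect_true(all(diff(length_to_breadth(w)) >= 0))
})

test_that("daily elliptical area follows the closed form and scales quadratically", {
  expect_equal(daily_area(0, 0, 1), 0)
  expect_equal(daily_area(1, 0, 1), (pi / 4) * 24^2, tolerance = 1e-12)
  a1 <- daily_area(0.4, 0.08, 3)
  a2 <- daily_area(0.8, 0.16, 3)
  expect_equal(a2 / a1, 4)
  expect_error(daily_area(1, 2, 3), "v_u")
})

test_that("extinction probability matches the printed endpoints and is monotone", {
  expect_equal(extinguish_prob(0.001), 0.521607, tolerance = 1e-6)
  expect_equal(extinguish_prob(0.1), 0.5 + 0.5 * (1 - exp(-pi)),
               tolerance = 1e-12)
  p <- sort(c(0, 10^runif(50, -4, 1)))
  q <- extinguish_prob(p)
  expect_true(all(diff(q) >= 0))
  expect_true(all(q[p >= 0.001] >= 0.5 & q[p >= 0.001] <= 1))
  expect_lt(extinguish_prob(0.05), 1)
  expect_error(extinguish_prob(0.01, pdmin = 0.2, pdmax = 0.1), "pdmin")
})

test_that("fire-duration multiplier follows the exponential-duration formula", {
  expect_equal(area_per_fire(1, 0.5), 3)
  expect_equal(area_per_fire(10, 1), 0)
  q <- seq(0.5, 0.99, by = 0.01)
  expect_true(all(diff(area_per_fire(1, q)) < 0))
  expect_error(area_per_fire(1, 0), "q")
})

test_that("per-PFT burned area applies the representative-area scaling and cap", {
  expect_equal(burned_area_pft(0.5, 10, 800, 1), 5)
  expect_equal(burned_area_pft(0, 10, 800, 1), 0)
  # cap at the PFT extent
  expect_equal(burned_area_pft(1, 1e6, 100, 1), 100)
  # sum over PFTs never exceeds the cell area
  set.seed(12)
  for (i in 1:50) {
    f <- rexp(4)
    f <- f / sum(f)
    ba <- burned_area_pft(runif(1), runif(1, 0, 1e5), 576, f)
    expect_lte(sum(ba), 576 + 1e-9)
  }
})

test_that("fire_geometry composes the chain on a cell-day table", {
  df <- tibble::tibble(isi = c(0, 5, 12), bui = c(10, 60, 120),
                       wind_kmh = c(0, 10, 30), popdens_km2 = c(0, 0.01, 1))
  out <- fire_geometry(df, "needleleaf", 2.3)
  expect_equal(out$v_d,
               spread_rate(df$isi, df$bui, "needleleaf", 2.3))
  expect_equal(out$v_u, 0.2 * out$v_d)
  expect_equal(out$ar_km2, area_per_fire(out$a1_km2, out$q))
  expect_equal(out$a1_km2[1], 0)
})
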