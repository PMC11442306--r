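tiny_cfg <- function(...) {
  scenario_config(nx = 2, ny = 2, years = 2, seed = 42, ...)
}

test_that("forcing generation is deterministic given the seed", {
  f1 <- generate_forcing(tiny_cfg())
  f2 <- generate_forcing(tiny_cfg())
  expect_identical(f1$met, f2$met)
  expect_identical(f1$cells, f2$cells)
  f3 <- generate_forcing(scenario_config(nx = 2, ny = 2, years = 2,
                                         seed = 43))
  expect_false(identical(f1$met$tmax, f3$met$tmax))
})

test_that("zero noise and zero trend leave a pure seasonal sinusoid", {
  cfg <- tiny_cfg(tmax_sd = 0, tmax_spatial_sd = 0, tmax_trend = 0)
  f <- generate_forcing(cfg)
  expected <- cfg$tmax_mean + cfg$tmax_amp *
    cos(2 * pi * (f$dates$doy - 201) / 365)
  expect_equal(f$met$tmax[, 1], expected, tolerance = 1e-12)
  expect_equal(f$met$tmax[, 4], expected, tolerance = 1e-12)
})

test_that("a configured warming trend is recovered by regression", {
  cfg <- scenario_config(nx = 2, ny = 2, years = 100, seed = 9,
                         tmax_trend = 4)
  f <- generate_forcing(cfg)
  ann <- tapply(rowMeans(f$met$tmax), f$dates$year, mean)
  fit <- lm(ann ~ I(as.numeric(names(ann)) / 100))
  expect_equal(unname(coef(fit)[2]), 4, tolerance = 0.5)
})

test_that("generated fields respect physical ranges", {
  f <- generate_forcing(scenario_config(nx = 3, ny = 3, years = 3,
                                        seed = 1))
  expect_true(all(f$met$rh >= 0 & f$met$rh <= 100))
  expect_true(all(f$met$wind >= 0))
  expect_true(all(f$met$rain >= 0))
  expect_true(all(f$met$lightning >= 0))
  expect_true(all(rowSums(f$covers) <= 1 + 1e-9))
  expect_true(all(f$cells$popdens_km2 >= 0))
})

test_that("fixing a driver suppresses its trend but not its noise", {
  cfg <- scenario_config(nx = 2, ny = 2, years = 10, seed = 4,
                         lightning_trend = 2)
  full <- generate_forcing(cfg)
  fixed <- generate_forcing(cfg, fixed = "lightning")
  # identical noise: ratio of the two fields is a deterministic ramp
  ratio <- full$met$lightning[, 1] / pmax(fixed$met$lightning[, 1], 1e-300)
  cent <- (seq_len(nrow(full$dates)) - 1) / 36500
  expect_equal(ratio, 1 + 2 * cent, tolerance = 1e-9)
  # other variables untouched
  expect_identical(full$met$tmax, fixed$met$tmax)
  expect_error(generate_forcing(cfg, fixed = "volcanoes"), "Unknown driver")
})

test_that("multiplicative delta correction conserves the target total", {
  set.seed(31)
  x <- rexp(500, 2)
  corr <- delta_correct_multiplicative(x, 1.7)
  expect_equal(mean(corr), 1.7, tolerance = 1e-12)
  expect_equal(sum(corr), 1.7 * 500, tolerance = 1e-9)
  # relative variability preserved
  expect_equal(corr / mean(corr), x / mean(x), tolerance = 1e-12)
  # identity when target equals the source climatology
  expect_equal(delta_correct_multiplicative(x, mean(x)), x)
  # halving
  expect_equal(delta_correct_multiplicative(c(2, 2, 2), 1), c(1, 1, 1))
  # per-column matrix correction
  m <- matrix(rexp(200), 50, 4)
  cm <- delta_correct_multiplicative(m, c(1, 2, 3, 4))
  expect_equal(colMeans(cm), c(1, 2, 3, 4), tolerance = 1e-12)
  # zero-mean column with nonzero target is flagged, not corrected
  m0 <- cbind(m[, 1], 0)
  expect_warning(c0 <- delta_correct_multiplicative(m0, c(1, 1)),
                 "zero climatology")
  expect_equal(attr(c0, "flagged"), 2L)
  expect_equal(c0[, 2], m0[, 2])
})

test_that("additive delta correction offsets the mean and accounts for clamping", {
  x <- c(0, 1, 2)
  expect_equal(delta_correct_additive(x, 3), x + 2)
  expect_equal(delta_correct_additive(x, mean(x)), x)
  # clamping: shifting down pushes values below zero
  y <- c(0, 0.2, 5)
  expect_warning(corr <- delta_correct_additive(y, 0.5), "clamp")
  mass <- attr(corr, "clamp_mass")
  expect_true(all(corr >= 0))
  expect_lte(mean(corr), 0.5 + mass + 1e-12)
  expect_equal(mean(corr) - 0.5, mass, tolerance = 1e-12)
})

test_that("delta corrections accept data-frame series", {
  df <- tibble::tibble(day = 1:4, value = c(1, 2, 3, 2))
  out <- delta_correct_multiplicative(df, 1)
  expect_s3_class(out, "tbl_df")
  expect_equal(mean(out$value), 1)
})

test_that("biomass regrowth relaxes toward capacity at the stated rate", {
  # at capacity with no fire: unchanged
  expect_equal(step_biomass(2, 0, capacity = 2, rate_per_yr = 0.1), 2)
  # total burn recovers to 1 - 1/e of capacity after one e-folding time
  expect_equal(step_biomass(5, 1, capacity = 5, rate_per_yr = 0.25,
                            dt_yr = 4),
               5 * (1 - exp(-1)))
  # zero regrowth freezes the post-fire pools
  expect_equal(step_biomass(3, 0.5, capacity = 10, rate_per_yr = 0), 1.5)
  # data-frame pools with per-column capacities
  pools <- tibble::tibble(leaf = c(1, 0.5), stem = c(4, 2))
  caps <- tibble::tibble(leaf = 1, stem = 4)
  out <- step_biomass(pools, 0, caps, rate_per_yr = 0.5, dt_yr = 1)
  expect_true(all(out$leaf <= 1 + 1e-12))
  expect_true(all(out >= pools * exp(-0.5) - 1e-12))
})
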