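# Attribution, sensitivity, and significance machinery on small grids
# and constructed data; the full-size study conditions live in the
# acceptance suite.

small_base <- function(lightning_trend = 0, tmax_trend = 0, ...) {
  scenario_config(nx = 4, ny = 4, years = 30, seed = 11,
                  tmax_trend = tmax_trend, rh_trend = 0,
                  lightning_trend = lightning_trend, ...)
}

run_small <- function(cfg, fixed = character()) {
  run_simulation(cfg, fixed = fixed, spinup_years = 2)
}

test_that("a single trending driver receives the whole attribution", {
  cfg <- small_base(lightning_trend = 0.8)
  full <- run_small(cfg)
  fixed <- lapply(setNames(
    c("climate", "lightning", "population", "co2_biomass"),
    c("climate", "lightning", "population", "co2_biomass")),
    function(d) run_small(cfg, fixed = d))
  at <- factorial_attribution(full, fixed, ref_window = 8, end_window = 8)
  tbl <- tidy(at)
  expect_equal(tbl$contribution[tbl$driver == "lightning"], 1)
  expect_equal(sum(tbl$contribution), 1, tolerance = 1e-9)
  expect_equal(tbl$contribution_raw[tbl$driver == "climate"], 0)
  expect_s3_class(ggplot2::autoplot(at), "ggplot")
})

test_that("no trends at all yields a flagged undefined attribution", {
  cfg <- small_base()
  full <- run_small(cfg)
  fixed <- list(lightning = run_small(cfg, fixed = "lightning"))
  expect_warning(at <- factorial_attribution(full, fixed, ref_window = 8,
                                             end_window = 8),
                 "undefined")
  expect_true(all(is.na(tidy(at)$contribution)))
  expect_true(glance(at)$undefined)
})

test_that("attribution refuses runs from different seeds", {
  a <- run_small(small_base(lightning_trend = 0.5))
  b <- run_simulation(scenario_config(nx = 4, ny = 4, years = 30,
                                      seed = 12, rh_trend = 0,
                                      tmax_trend = 0,
                                      lightning_trend = 0.5),
                      fixed = "lightning", spinup_years = 2)
  expect_error(factorial_attribution(a, list(lightning = b)),
               "seed")
})

test_that("an engineered linear response is recovered by the slope fit", {
  set.seed(44)
  n <- 400
  df <- tibble::tibble(
    run = rep(c("a", "b"), each = n / 2),
    year = rep(1:(n / 2), 2),
    tmax_mean = runif(n, 10, 25),
    burned_area_mha = 1.2 * tmax_mean + rnorm(n, 0, 0.8)
  )
  sens <- sensitivity_curves(df, drivers = "tmax_mean")
  sl <- tidy(sens)
  expect_equal(sl$slope, 1.2, tolerance = 0.1)
  expect_true(sl$conf_low < 1.2 && 1.2 < sl$conf_high)
  # point bookkeeping: runs x years
  expect_equal(glance(sens)$n_points, n)
  expect_equal(nrow(sens$points), n)
  expect_s3_class(ggplot2::autoplot(sens), "ggplot")
})

test_that("a constant driver yields a flagged undefined slope", {
  df <- tibble::tibble(tmax_mean = rep(5, 30),
                       burned_area_mha = rnorm(30))
  sens <- sensitivity_curves(df, drivers = "tmax_mean")
  expect_true(tidy(sens)$constant)
  expect_true(is.na(tidy(sens)$slope))
})

test_that("sensitivity pools annual tables across runs", {
  runs <- list(a = run_simulation(scenario_config(nx = 2, ny = 2,
                                                  years = 3, seed = 1),
                                  spinup_years = 1),
               b = run_simulation(scenario_config(nx = 2, ny = 2,
                                                  years = 3, seed = 2),
                                  spinup_years = 1))
  pooled <- collect_annual(runs)
  expect_equal(nrow(pooled), 6)
  expect_setequal(unique(pooled$run), c("a", "b"))
  sens <- sensitivity_curves(runs, drivers = "tmax_mean")
  expect_equal(glance(sens)$n_points, 6)
})

test_that("identical periods are everywhere flagged as no change", {
  m <- matrix(rnorm(5 * 50), 5, 50)
  res <- ensemble_change_test(m, m)
  expect_true(all(res$no_change))
})

test_that("a strongly shifted region is detected as changed", {
  set.seed(55)
  ref <- matrix(rnorm(6 * 100), 6, 100)
  end <- matrix(rnorm(6 * 100), 6, 100)
  end[, 1:20] <- end[, 1:20] + 10    # ten-sigma shift
  res <- ensemble_change_test(ref, end)
  expect_true(all(!res$no_change[1:20]))
  expect_gt(mean(res$no_change[21:100]), 0.8)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})

test_that("the test attains its nominal type-I error under the null", {
  set.seed(66)
  n_cells <- 10000
  ref <- matrix(rnorm(6 * n_cells), 6, n_cells)
  end <- matrix(rnorm(6 * n_cells), 6, n_cells)
  res <- ensemble_change_test(ref, end, alpha = 0.05)
  rate <- mean(!res$no_change)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("change-test input contracts are enforced", {
  m <- matrix(rnorm(10), 2, 5)
  expect_error(ensemble_change_test(m[1, , drop = FALSE], m), "members")
  expect_error(ensemble_change_test(m, m[, 1:3]), "same number")
})

test_that("period_means extracts window means from a run", {
  run <- run_simulation(scenario_config(nx = 2, ny = 2, years = 10,
                                        seed = 3), spinup_years = 1)
  pm <- period_means(run, ref_window = 3, end_window = 3)
  expect_equal(pm$reference,
               colMeans(run$ba_cell_year[1:3, ]))
  expect_equal(pm$end, colMeans(run$ba_cell_year[8:10, ]))
  expect_error(period_means(run, 6, 6), "shorter")
})

test_that("variance partition splits sums of squares across a run matrix", {
  set.seed(77)
  df <- tidyr::expand_grid(model = c("m1", "m2", "m3"),
                           lightning = c("l1", "l2"),
                           rep = 1:4)
  df$y <- ifelse(df$model == "m1", 0, ifelse(df$model == "m2", 1, 2)) +
    ifelse(df$lightning == "l1", 0, 0.5) + rnorm(nrow(df), 0, 0.05)
  part <- partition_uncertainty(df, "y", c("model", "lightning"))
  expect_equal(sum(part$share), 1, tolerance = 1e-9)
  expect_gt(part$share[part$term == "model"],
            part$share[part$term == "lightning"])
})
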