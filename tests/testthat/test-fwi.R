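test_that("moisture codes agree with the independent scalar oracle", {
  set.seed(42)
  wx <- random_weather(100)
  state <- fwi_initial(ffmc = runif(1, 60, 95), dmc = runif(1, 0, 80),
                       dc = runif(1, 0, 400))
  for (i in seq_len(nrow(wx))) {
    got <- fwi_step(state, wx$tmax_c[i], wx$rh_pct[i], wx$wind_kmh[i],
                    wx$rain_mm[i], wx$month[i])
    want <- oracle_step(state$ffmc, state$dmc, state$dc, wx$tmax_c[i],
                        wx$rh_pct[i], wx$wind_kmh[i], wx$rain_mm[i],
                        wx$month[i])
    expect_equal(unlist(got[c("ffmc", "dmc", "dc", "isi", "bui")]),
                 want, tolerance = 1e-9)
    state <- got[c("ffmc", "dmc", "dc")]
  }
})

test_that("a benchmark spring day reproduces the hand-stepped chain", {
  # F0=85, P0=6, D0=15; T=17, H=42, W=25, no rain, April
  st <- fwi_step(fwi_initial(), tmax_c = 17, rh_pct = 42, wind_kmh = 25,
                 rain_mm = 0, month = 4)
  expect_equal(st$ffmc, 87.649354, tolerance = 1e-6)
  expect_equal(st$dmc, 8.545051, tolerance = 1e-6)
  expect_equal(st$dc, 19.014, tolerance = 1e-6)
  expect_equal(st$isi, 10.776233, tolerance = 1e-6)
  expect_equal(st$bui, 8.490427, tolerance = 1e-6)
})

test_that("single-update hand calculations are reproduced", {
  expect_equal(ffmc_update(85, 20, 40, 10, 5), 71.033619, tolerance = 1e-6)
  expect_equal(dmc_update(6, 25, 40, 0, 7), 9.677845, tolerance = 1e-6)
  expect_equal(dc_update(15, 25, 0, 7), 23.204, tolerance = 1e-6)
  expect_equal(isi_index(90, 20), 11.736178, tolerance = 1e-6)
  expect_equal(bui_index(50, 300), 70.588235, tolerance = 1e-6)
})

test_that("FFMC responds physically to wetting and drying days", {
  # saturated air cannot dry the fuel below its wet equilibrium
  expect_lt(ffmc_update(85, 25, 100, 0, 0), 85)
  # a hot, dry, windy day dries fine fuel
  expect_gt(ffmc_update(85, 30, 20, 15, 0), 85)
  # heavy rain wets the duff and deep layers
  expect_lt(dmc_update(100, 20, 60, 50, 7), 100)
  expect_lt(dc_update(200, 20, 30, 7), 200)
  # warm rain-free day deepens drought
  expect_gt(dc_update(15, 25, 0, 7), 15)
  # a freezing day adds at most the minimal drying increment to DMC
  expect_equal(dmc_update(6, -10, 40, 0, 7), 6)
})

test_that("ISI and BUI are monotone in their drivers", {
  set.seed(7)
  for (i in 1:50) {
    f <- runif(1, 0, 101)
    w <- sort(runif(2, 0, 60))
    expect_gt(isi_index(f, w[2]), isi_index(f, w[1]))
    f2 <- sort(runif(2, 0, 101))
    w1 <- runif(1, 0, 60)
    expect_gte(isi_index(f2[2], w1), isi_index(f2[1], w1))
    p <- sort(runif(2, 1, 150))
    d <- sort(runif(2, 1, 600))
    expect_gte(bui_index(p[2], d[1]), bui_index(p[1], d[1]))
    expect_gte(bui_index(p[1], d[2]), bui_index(p[1], d[1]))
  }
  expect_equal(bui_index(0, 500), 0)
  expect_lt(isi_index(0, 30), 1e-6)
})

test_that("codes stay in range along long random weather sequences", {
  set.seed(99)
  n_days <- 2000
  n_cells <- 50
  state <- fwi_initial(ffmc = runif(n_cells, 0, 101),
                       dmc = runif(n_cells, 0, 100),
                       dc = runif(n_cells, 0, 500))
  ok <- TRUE
  for (i in seq_len(n_days)) {
    wx <- random_weather(n_cells)
    state <- fwi_step(state, wx$tmax_c, wx$rh_pct, wx$wind_kmh,
                      wx$rain_mm, wx$month)
    ok <- ok &&
      all(state$ffmc >= 0 & state$ffmc <= 101) &&
      all(state$dmc >= 0) && all(state$dc >= 0) &&
      all(state$isi >= 0) && all(state$bui >= 0)
    state <- state[c("ffmc", "dmc", "dc")]
  }
  expect_true(ok)
})

test_that("constant weather drives FFMC to a fixed point within 30 days", {
  f <- 85
  trace <- numeric(40)
  for (i in 1:40) {
    f <- ffmc_update(f, 22, 45, 12, 0)
    trace[i] <- f
  }
  expect_lt(abs(trace[30] - trace[29]), 1e-6)
  expect_lt(abs(trace[40] - trace[30]), 1e-6)
})

test_that("fwi_run chains days and matches manual stepping, per cell", {
  set.seed(3)
  met <- dplyr::bind_rows(
    dplyr::mutate(random_weather(20), cell = 1L),
    dplyr::mutate(random_weather(20), cell = 2L)
  )
  out <- fwi_run(met)
  # manual chain for cell 2
  st <- fwi_initial()
  m2 <- met[met$cell == 2L, ]
  for (i in seq_len(nrow(m2))) {
    st <- fwi_step(st, m2$tmax_c[i], m2$rh_pct[i], m2$wind_kmh[i],
                   m2$rain_mm[i], m2$month[i])
    st <- st[c("ffmc", "dmc", "dc")]
  }
  got <- out[out$cell == 2L, ]
  expect_equal(got$ffmc[nrow(got)], st$ffmc)
  expect_equal(got$dmc[nrow(got)], st$dmc)
  expect_equal(got$dc[nrow(got)], st$dc)
  # row order of the input is preserved
  expect_equal(out$cell, met$cell)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(ffmc_update(120, 20, 50, 10, 0), "ffmc")
  expect_error(ffmc_update(85, 20, 130, 10, 0), "rh_pct")
  expect_error(ffmc_update(85, 20, 50, 10, -1), "rain_mm")
  expect_error(dmc_update(6, 20, 50, 0, 13), "month")
  expect_error(dc_update(-5, 20, 0, 7), "dc")
  expect_error(isi_index(90, -3), "wind")
})
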