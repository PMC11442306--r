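# Synthetic gridded forcing: seasonal cycles plus AR(1) weather noise,
# secular trends (warming, drying, lightning increase, population and
# fertilization multipliers), spatially heterogeneous population and
# lightning-climatology fields, and PFT cover.  All randomness is seeded
# with one named stream per variable, so adding or regenerating one
# variable never perturbs the others.

DRIVERS <- c("climate", "lightning", "population", "co2_biomass")
DAYS_PER_YEAR <- 365L
MONTH_LENGTHS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Default PFT table for the synthetic landscape
#'
#' Spread parameters, mean fractional cover, carrying-capacity carbon
#' densities per pool (kg C m-2), and regrowth e-folding rates (yr-1)
#' for a four-PFT boreal mosaic.
#'
#' @return A tibble with one row per PFT.
#' @export
default_pfts <- function() {
  tibble(
    pft = c("needleleaf_evergreen", "needleleaf_continental",
            "broadleaf_deciduous", "grass"),
    spread_class = c("needleleaf", "needleleaf", "broadleaf", "grass"),
    vdmax_kmh = c(2.3, 3.8, 0.92, 4.97),
    cover = c(0.35, 0.15, 0.20, 0.20),
    k_leaf = c(0.30, 0.28, 0.25, 0.25),
    k_stem = c(6.0, 5.0, 4.0, 0.05),
    k_root = c(1.5, 1.3, 1.0, 0.50),
    k_litter = c(1.5, 1.4, 1.0, 0.30),
    k_soil = c(15, 14, 12, 8),
    regrowth_live_per_yr = c(1 / 25, 1 / 25, 1 / 20, 1.0),
    regrowth_litter_per_yr = 1 / 10,
    regrowth_soil_per_yr = 1 / 100
  )
}

#' Synthetic-forcing scenario configuration
#'
#' Defines the study conditions of a desk-scale simulation: a regular
#' toy grid (default 20 x 20 cells of 576 km2, comparable to a 0.22 deg
#' grid), the run length, seasonal climatologies, AR(1) noise, secular
#' trends per driver, and landscape fields.  Trends are expressed per
#' century so the default transient scenario (warming +4 degC, drying
#' -5 % RH, lightning +50 %) reads directly in the field's usual units.
#'
#' @param nx,ny Grid dimensions (cells).
#' @param cell_area_km2 Area of every cell (km2).
#' @param years Simulated years.
#' @param start_year First calendar year (labels only).
#' @param seed Base random seed; each variable derives its own stream.
#' @param tmax_mean,tmax_amp Annual-mean and seasonal semi-amplitude of
#'   daily maximum temperature (degC); the seasonal peak is in late July.
#' @param tmax_spatial_sd Across-cell spread of the temperature mean (degC).
#' @param tmax_sd,tmax_ar1 AR(1) noise: marginal SD (degC) and lag-1
#'   autocorrelation.
#' @param tmax_trend Warming trend (degC per century).
#' @param rh_mean,rh_amp Relative-humidity mean and seasonal depression
#'   at the temperature peak (%).
#' @param rh_sd,rh_ar1 RH AR(1) noise parameters (%).
#' @param rh_trend Drying trend (% RH per century, negative dries).
#' @param rh_temp_coupling RH response to the temperature noise anomaly
#'   (% RH per degC); negative couples warm anomalies to dry air.
#' @param wind_mean,wind_amp,wind_sd,wind_ar1,wind_trend Wind speed
#'   climatology, noise, and trend (km/h; winter maximum).
#' @param rain_wet_wet,rain_wet_dry Wet-day persistence probabilities of
#'   the two-state precipitation occurrence chain.
#' @param rain_mean_mm Mean wet-day rainfall (mm), with a summer maximum.
#' @param rain_shape Gamma shape of wet-day amounts.
#' @param rain_trend Fractional change in wet-day amounts per century.
#' @param lightning_mean Median of the cell lightning climatology
#'   (strikes km-2 yr-1).
#' @param lightning_sdlog Log-SD of the lightning climatology field.
#' @param lightning_kappa Seasonal concentration of strikes (larger =
#'   sharper mid-summer peak).
#' @param lightning_noise_sdlog Log-SD of day-to-day multiplicative
#'   lightning noise (unit mean).
#' @param lightning_trend Fractional change in strike rate per century.
#' @param pop_median,pop_sdlog Median and log-SD of the (static) cell
#'   population-density field (persons km-2).
#' @param pop_trend Fractional change in population density per century.
#' @param co2_biomass_trend Fractional change per century of the
#'   carrying-capacity multiplier (a CO2-fertilization proxy).
#' @param r_green Green (uncured) fraction of grass leaf biomass.
#' @param cover_concentration Dirichlet-like concentration of the cell
#'   PFT-cover jitter (larger = more uniform covers).
#' @param veg_fraction Total vegetated fraction of each cell.
#' @param pft PFT table, see [default_pfts()].
#' @return A `scenario_config` object (a validated list).
#' @examples
#' cfg <- scenario_config(nx = 4, ny = 4, years = 2)
#' @export
scenario_config <- function(nx = 20, ny = 20, cell_area_km2 = 576,
                            years = 50, start_year = 2000, seed = 1,
                            tmax_mean = 3, tmax_amp = 18,
                            tmax_spatial_sd = 1.5,
                            tmax_sd = 3.5, tmax_ar1 = 0.75, tmax_trend = 4,
                            rh_mean = 70, rh_amp = 12,
                            rh_sd = 8, rh_ar1 = 0.6, rh_trend = -5,
                            rh_temp_coupling = -1.2,
                            wind_mean = 12, wind_amp = 2, wind_sd = 4,
                            wind_ar1 = 0.4, wind_trend = 0,
                            rain_wet_wet = 0.55, rain_wet_dry = 0.25,
                            rain_mean_mm = 4.5, rain_shape = 0.7,
                            rain_trend = 0,
                            lightning_mean = 1.2, lightning_sdlog = 0.8,
                            lightning_kappa = 6,
                            lightning_noise_sdlog = 1,
                            lightning_trend = 0.5,
                            pop_median = 0.02, pop_sdlog = 2.5,
                            pop_trend = 0,
                            co2_biomass_trend = 0,
                            r_green = 0.5,
                            cover_concentration = 60,
                            veg_fraction = 0.9,
                            pft = default_pfts()) {
  cfg <- as.list(environment())
  if (nx < 1 || ny < 1 || years < 1) {
    abort("Grid dimensions and `years` must be positive.")
  }
  check_range(r_green, 0, 1, "r_green")
  check_range(veg_fraction, 0, 1, "veg_fraction")
  if (sum(pft$cover) > 1 + 1e-9) {
    abort("PFT mean covers must sum to at most 1.")
  }
  structure(cfg, class = "scenario_config")
}

# One seeded stream per variable: the stream id, not the draw order,
# identifies the variable.
stream_seed <- function(seed, name) {
  offsets <- c(fields = 11L, covers = 12L, tmax = 21L, rh = 22L,
               wind = 23L, rain = 24L, lightning = 25L)
  set.seed(as.integer(seed) + offsets[[name]])
}

# AR(1) with marginal SD `sd` and lag-1 autocorrelation `phi`,
# column-wise over an nd x nc matrix.
ar1_noise <- function(nd, nc, sd, phi) {
  if (sd <= 0) return(matrix(0, nd, nc))
  eps <- matrix(rnorm(nd * nc, 0, sd * sqrt(1 - phi^2)), nd, nc)
  if (phi == 0) return(eps)
  m <- stats::filter(eps, phi, method = "recursive")
  matrix(as.numeric(m), nd, nc)
}

forcing_calendar <- function(years, start_year) {
  nd <- years * DAYS_PER_YEAR
  doy <- rep(seq_len(DAYS_PER_YEAR), times = years)
  month <- rep(rep.int(seq_len(12L), MONTH_LENGTHS), times = years)
  tibble(
    day = seq_len(nd),
    year = rep(start_year + seq_len(years) - 1L, each = DAYS_PER_YEAR),
    doy = doy,
    month = month
  )
}

#' Generate synthetic gridded daily forcing
#'
#' Realizes a scenario as daily day-by-cell fields of maximum
#' temperature, relative humidity, wind, rainfall, and lightning strike
#' density, plus static population and PFT-cover fields and per-day
#' population / carrying-capacity multipliers.  Reproducible given the
#' scenario seed.  Drivers named in `fixed` are held at their first-year
#' (reference) level: their secular trends are suppressed while every
#' noise stream is left bit-identical, which is the factorial-experiment
#' contract.
#'
#' @param cfg A [scenario_config()].
#' @param fixed Character subset of
#'   `c("climate", "lightning", "population", "co2_biomass")`.
#' @return A `fire_forcing` object: list with `config`, `fixed`, `cells`
#'   (tibble), `covers` (cell x PFT matrix), `dates` (tibble), `met`
#'   (list of day x cell matrices `tmax`, `rh`, `wind`, `rain`,
#'   `lightning`), `pop_mult`, `k_mult` (per-day multipliers).
#' @examples
#' f <- generate_forcing(scenario_config(nx = 2, ny = 2, years = 1))
#' dim(f$met$tmax)
#' @export
generate_forcing <- function(cfg, fixed = character()) {
  if (!inherits(cfg, "scenario_config")) {
    abort("`cfg` must be a `scenario_config` object.")
  }
  bad <- setdiff(fixed, DRIVERS)
  if (length(bad)) {
    abort(sprintf("Unknown driver(s) in `fixed`: %s.",
                  paste(bad, collapse = ", ")))
  }
  nc <- cfg$nx * cfg$ny
  nd <- cfg$years * DAYS_PER_YEAR
  dates <- forcing_calendar(cfg$years, cfg$start_year)
  # centuries elapsed since the reference (first) day
  cent <- (dates$day - 1) / (DAYS_PER_YEAR * 100)
  phase <- cos(2 * pi * (dates$doy - 201) / DAYS_PER_YEAR)

  trend <- function(per_century, driver) {
    if (driver %in% fixed) 0 else per_century
  }

  # --- static landscape fields -------------------------------------------
  stream_seed(cfg$seed, "fields")
  cell_toffset <- rnorm(nc, 0, cfg$tmax_spatial_sd)
  popdens <- rlnorm(nc, log(cfg$pop_median), cfg$pop_sdlog)
  light_clim <- rlnorm(nc, log(cfg$lightning_mean), cfg$lightning_sdlog)

  stream_seed(cfg$seed, "covers")
  npft <- nrow(cfg$pft)
  if (cfg$cover_concentration > 0 && npft > 1) {
    g <- matrix(rgamma(nc * npft,
                       shape = rep(cfg$pft$cover * cfg$cover_concentration,
                                   each = nc)), nc, npft)
    covers <- cfg$veg_fraction * g / rowSums(g)
  } else {
    covers <- matrix(rep(cfg$veg_fraction * cfg$pft$cover / sum(cfg$pft$cover),
                         each = nc), nc, npft)
  }
  colnames(covers) <- cfg$pft$pft

  ix <- rep(seq_len(cfg$nx), times = cfg$ny)
  iy <- rep(seq_len(cfg$ny), each = cfg$nx)
  cells <- tibble(
    cell = seq_len(nc), ix = ix, iy = iy,
    lon = -120 + 0.22 * (ix - 1), lat = 52 + 0.22 * (iy - 1),
    area_km2 = cfg$cell_area_km2, popdens_km2 = popdens
  )

  # --- weather ------------------------------------------------------------
  stream_seed(cfg$seed, "tmax")
  tnoise <- ar1_noise(nd, nc, cfg$tmax_sd, cfg$tmax_ar1)
  tmax <- outer(cfg$tmax_mean + cfg$tmax_amp * phase +
                  trend(cfg$tmax_trend, "climate") * cent,
                rep(1, nc)) +
    outer(rep(1, nd), cell_toffset) + tnoise

  stream_seed(cfg$seed, "rh")
  rh <- outer(cfg$rh_mean - cfg$rh_amp * phase +
                trend(cfg$rh_trend, "climate") * cent, rep(1, nc)) +
    cfg$rh_temp_coupling * tnoise +
    ar1_noise(nd, nc, cfg$rh_sd, cfg$rh_ar1)
  rh <- pmin(pmax(rh, 2), 100)

  stream_seed(cfg$seed, "wind")
  wind <- outer(cfg$wind_mean + cfg$wind_amp *
                  cos(2 * pi * (dates$doy - 15) / DAYS_PER_YEAR) +
                  trend(cfg$wind_trend, "climate") * cent, rep(1, nc)) +
    ar1_noise(nd, nc, cfg$wind_sd, cfg$wind_ar1)
  wind <- pmax(wind, 0)

  stream_seed(cfg$seed, "rain")
  u <- matrix(runif(nd * nc), nd, nc)
  wet <- matrix(FALSE, nd, nc)
  prev <- u[1, ] < cfg$rain_wet_dry
  wet[1, ] <- prev
  for (t in seq_len(nd)[-1]) {
    p <- ifelse(prev, cfg$rain_wet_wet, cfg$rain_wet_dry)
    prev <- u[t, ] < p
    wet[t, ] <- prev
  }
  wet_mean <- pmax(cfg$rain_mean_mm * (1 + 0.4 * phase) *
                     (1 + trend(cfg$rain_trend, "climate") * cent), 0)
  if (cfg$rain_mean_mm > 0) {
    amt <- matrix(rgamma(nd * nc, shape = cfg$rain_shape,
                         scale = rep(wet_mean, nc) / cfg$rain_shape), nd, nc)
  } else {
    amt <- matrix(0, nd, nc)
  }
  rain <- wet * amt

  # --- lightning ----------------------------------------------------------
  stream_seed(cfg$seed, "lightning")
  season <- exp(cfg$lightning_kappa * (phase - 1))
  season <- season / mean(season[seq_len(DAYS_PER_YEAR)])
  lmult <- pmax(1 + trend(cfg$lightning_trend, "lightning") * cent, 0)
  lnoise <- matrix(rlnorm(nd * nc, -0.5 * cfg$lightning_noise_sdlog^2,
                          cfg$lightning_noise_sdlog), nd, nc)
  lightning <- outer(season * lmult / DAYS_PER_YEAR, light_clim) * lnoise

  pop_mult <- pmax(1 + trend(cfg$pop_trend, "population") * cent, 0)
  k_mult <- pmax(1 + trend(cfg$co2_biomass_trend, "co2_biomass") * cent, 0)

  structure(list(
    config = cfg, fixed = fixed, cells = cells, covers = covers,
    dates = dates,
    met = list(tmax = tmax, rh = rh, wind = wind, rain = rain,
               lightning = lightning),
    pop_mult = pop_mult, k_mult = k_mult
  ), class = "fire_forcing")
}

#' @export
print.fire_forcing <- function(x, ...) {
  cat(sprintf(
    "<fire_forcing> %d x %d cells, %d years (%d days), seed %d%s\n",
    x$config$nx, x$config$ny, x$config$years, nrow(x$dates),
    x$config$seed,
    if (length(x$fixed)) paste0(", fixed: ", paste(x$fixed, collapse = ", "))
    else ""))
  invisible(x)
}

#' Forcing as a long cell-day tibble
#'
#' Flattens a `fire_forcing` object into one row per cell-day, joined
#' with the calendar and cell tables.  Intended for inspection and small
#' grids; the simulation engine consumes the matrix form directly.
#'
#' @param forcing A `fire_forcing` object.
#' @return A tibble with calendar columns, cell attributes, and
#'   `tmax_c`, `rh_pct`, `wind_kmh`, `rain_mm`, `lightning_km2_day`.
#' @export
forcing_tbl <- function(forcing) {
  nd <- nrow(forcing$dates)
  nc <- nrow(forcing$cells)
  out <- tidyr::expand_grid(cell = forcing$cells$cell,
                            day = forcing$dates$day)
  out %>%
    left_join(forcing$dates, by = "day") %>%
    left_join(forcing$cells, by = "cell") %>%
    mutate(
      tmax_c = as.vector(forcing$met$tmax)[(cell - 1) * nd + day],
      rh_pct = as.vector(forcing$met$rh)[(cell - 1) * nd + day],
      wind_kmh = as.vector(forcing$met$wind)[(cell - 1) * nd + day],
      rain_mm = as.vector(forcing$met$rain)[(cell - 1) * nd + day],
      lightning_km2_day = as.vector(forcing$met$lightning)[(cell - 1) * nd + day]
    )
}

# ---------------------------------------------------------------------------
# Delta-method bias correction

delta_prepare <- function(series) {
  if (is.data.frame(series)) {
    check_cols(series, "value", "series")
    x <- series$value
  } else {
    x <- series
  }
  x
}

delta_finish <- function(series, corrected, flagged = NULL,
                         clamp_mass = NULL) {
  if (is.data.frame(series)) {
    out <- as_tibble(series)
    out$value <- as.vector(corrected)[seq_len(nrow(out))]
    corrected <- out
  }
  if (!is.null(flagged)) attr(corrected, "flagged") <- flagged
  if (!is.null(clamp_mass)) attr(corrected, "clamp_mass") <- clamp_mass
  corrected
}

#' Multiplicative delta-method bias correction
#'
#' Rescales a series so its long-term mean equals a target climatology
#' while preserving relative (intra-series) variability; the corrected
#' cumulative total equals the target cumulative total exactly.  For a
#' matrix (days x cells), each column is corrected against its own
#' target.  Columns with zero mean but a nonzero target cannot be
#' rescaled; they are left unchanged and flagged with a warning.
#'
#' @param series Numeric vector, days x cells matrix, or data frame with
#'   a `value` column.
#' @param target_climatology Target mean: scalar, or one value per
#'   column for a matrix.
#' @return The corrected series in the same shape, with attribute
#'   `flagged` marking uncorrectable columns (if any).
#' @examples
#' x <- c(1, 2, 3)
#' delta_correct_multiplicative(x, 1)  # mean rescaled from 2 to 1
#' @export
delta_correct_multiplicative <- function(series, target_climatology) {
  x <- delta_prepare(series)
  check_nonneg(target_climatology, "target_climatology")
  if (is.matrix(x)) {
    mu <- colMeans(x)
    tgt <- rep_len(target_climatology, ncol(x))
  } else {
    mu <- mean(x)
    tgt <- target_climatology[1]
  }
  zero <- mu == 0
  flagged <- which(zero & tgt > 0)
  if (length(flagged)) {
    warn(sprintf(
      "%d series with zero climatology but nonzero target left uncorrected.",
      length(flagged)))
  }
  ratio <- ifelse(zero, 1, tgt / mu)
  corrected <- if (is.matrix(x)) sweep(x, 2, ratio, `*`) else x * ratio
  delta_finish(series, corrected,
               flagged = if (length(flagged)) flagged else NULL)
}

#' Additive delta-method bias correction
#'
#' Offsets a series so its mean equals a target climatology.  Negative
#' corrected values (impossible for strike densities) are clamped to
#' zero; the clamped mass is reported via the `clamp_mass` attribute (per
#' column, as a mean over time steps) and a warning.
#'
#' @inheritParams delta_correct_multiplicative
#' @return The corrected series in the same shape, with attribute
#'   `clamp_mass` when clamping occurred.
#' @examples
#' delta_correct_additive(c(0, 1, 2), 3)  # +2 offset everywhere
#' @export
delta_correct_additive <- function(series, target_climatology) {
  x <- delta_prepare(series)
  if (is.matrix(x)) {
    mu <- colMeans(x)
    tgt <- rep_len(target_climatology, ncol(x))
    shifted <- sweep(x, 2, tgt - mu, `+`)
  } else {
    mu <- mean(x)
    tgt <- target_climatology[1]
    shifted <- x + (tgt - mu)
  }
  corrected <- pmax(shifted, 0)
  clamp <- corrected - shifted
  mass <- if (is.matrix(x)) colMeans(clamp) else mean(clamp)
  if (any(mass > 0)) {
    warn("Negative corrected values clamped to zero; see `clamp_mass`.")
  }
  delta_finish(series, corrected,
               clamp_mass = if (any(mass > 0)) mass else NULL)
}

# ---------------------------------------------------------------------------
# Fuel build-up: logistic-style relaxation toward carrying capacity

#' Post-fire biomass update with regrowth
#'
#' Removes the burned fraction from each pool and relaxes the remainder
#' exponentially toward its carrying capacity at the given e-folding
#' rate; a fully burned pool recovers to 63% of capacity after one
#' e-folding time, and a rate of zero freezes the post-fire pools.  This
#' minimal fuel dynamic closes the fire-fuel feedback so the biomass
#' probability responds to fire history; it does not emulate succession
#' or competition.
#'
#' @param pools Numeric vector/matrix of pool carbon densities, or a data
#'   frame whose numeric columns are pools.
#' @param burned_fraction Fraction of the extent burned this step,
#'   in \[0, 1\].
#' @param capacity Carrying capacity, same shape as `pools` (or scalar).
#' @param rate_per_yr Regrowth e-folding rate (yr-1, >= 0).
#' @param dt_yr Time step (years).
#' @return Updated pools, same shape as the input, never negative.
#' @examples
#' step_biomass(0, capacity = 1, rate_per_yr = 1, dt_yr = 1)  # ~0.632
#' @export
step_biomass <- function(pools, burned_fraction = 0, capacity,
                         rate_per_yr, dt_yr = 1) {
  check_range(burned_fraction, 0, 1, "burned_fraction")
  check_nonneg(rate_per_yr, "rate_per_yr")
  if (is.data.frame(pools)) {
    out <- as_tibble(pools)
    num <- vapply(out, is.numeric, logical(1))
    for (nm in names(out)[num]) {
      cap <- if (is.data.frame(capacity)) capacity[[nm]] else capacity
      out[[nm]] <- step_biomass(out[[nm]], burned_fraction, cap,
                                rate_per_yr, dt_yr)
    }
    return(out)
  }
  check_nonneg(pools, "pools")
  after <- pools * (1 - burned_fraction)
  fac <- exp(-rate_per_yr * dt_yr)
  pmax(capacity - (capacity - after) * fac, 0)
}
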