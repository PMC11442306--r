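# The daily fire simulation: FWI codes -> occurrence probabilities ->
# PFT spread and burned area -> carbon fluxes -> fuel regrowth, looped
# over days with all grid cells advanced together.

#' Fire-module parameter set
#'
#' Bundles the tunable parameters of the fire module with their default
#' values: occurrence thresholds, spread/geometry constants, the
#' combustion table, and the initial FWI codes.
#'
#' @param occurrence List of occurrence parameters (`biomass_low`,
#'   `biomass_high` kg C m-2; `lightning_low`, `lightning_high`
#'   strikes km-2 yr-1; `pop_threshold` persons km-2; `pop_exponent`).
#' @param spread List of spread parameters (`vu_frac` upwind fraction of
#'   the downwind rate, `lb_max_elong` and `lb_decay` of the
#'   length-to-breadth formula, representative area `a_rep` km2,
#'   extinction thresholds `pdmin`/`pdmax` persons km-2, fire-day length
#'   `dt_h` hours).
#' @param combustion Combustion table, see [default_combustion()].
#' @param init Initial FWI codes, see [fwi_initial()].
#' @return A `fire_params` list.
#' @export
fire_params <- function(occurrence = list(), spread = list(),
                        combustion = default_combustion(),
                        init = fwi_initial()) {
  occ <- utils::modifyList(list(
    biomass_low = 0.2, biomass_high = 1.0,
    lightning_low = 0.25, lightning_high = 10,
    pop_threshold = 300, pop_exponent = 0.43
  ), occurrence)
  spr <- utils::modifyList(list(
    vu_frac = 0.2, lb_max_elong = 10, lb_decay = 0.06,
    a_rep = 800, pdmin = 0.001, pdmax = 0.1, dt_h = 24
  ), spread)
  structure(list(occurrence = occ, spread = spr,
                 combustion = validate_combustion(combustion),
                 init = init),
            class = "fire_params")
}

# Fail fast on non-finite forcing, reporting the first offending cell-day.
check_forcing_finite <- function(forcing) {
  nd <- nrow(forcing$dates)
  for (nm in names(forcing$met)) {
    bad <- which(!is.finite(forcing$met[[nm]]))
    if (length(bad)) {
      i <- bad[1]
      abort(sprintf("Non-finite `%s` forcing at day %d, cell %d.",
                    nm, (i - 1) %% nd + 1, (i - 1) %/% nd + 1))
    }
  }
  invisible(forcing)
}

# Per-PFT parameter rows matched against the combustion table; returns
# npft-length vectors per pool.
combustion_vectors <- function(pft_tbl, combustion) {
  get <- function(pool, col) {
    idx <- match(paste(pft_tbl$pft, pool),
                 paste(combustion$pft, combustion$pool))
    if (anyNA(idx)) {
      abort(sprintf("Combustion table lacks pool '%s' for pft(s): %s.",
                    pool,
                    paste(pft_tbl$pft[is.na(idx)], collapse = ", ")))
    }
    combustion[[col]][idx]
  }
  list(
    emis = lapply(setNames(ALL_POOLS, ALL_POOLS),
                  function(p) get(p, "emission_frac")),
    mort = lapply(setNames(LIVE_POOLS, LIVE_POOLS),
                  function(p) get(p, "mortality_frac"))
  )
}

#' Run the daily fire simulation
#'
#' Spins the model up by looping the first years of forcing, then runs
#' the transient simulation, accumulating domain-wide annual burned area
#' and fire CO2 emissions plus per-cell annual fields.  Deterministic
#' given the scenario seed.
#'
#' @param scenario A [scenario_config()] (forcing is generated on the
#'   fly) or a ready-made `fire_forcing` object.
#' @param params Fire-module parameters, see [fire_params()].
#' @param fixed Drivers held at their reference-year level (passed to
#'   [generate_forcing()] when `scenario` is a config).
#' @param spinup_years Years of forcing (from the start) looped during
#'   spin-up.
#' @param spinup_loops Number of spin-up loops over those years.
#' @return A `fire_run` object: `annual` (tibble of domain-wide annual
#'   diagnostics), `ba_cell_year` and `co2_cell_year` (year x cell
#'   matrices, km2 and kg CO2), `cells`, `config`, `params`, `fixed`.
#' @examples
#' run <- run_simulation(scenario_config(nx = 2, ny = 2, years = 2),
#'                       spinup_years = 1)
#' run$annual
#' @export
run_simulation <- function(scenario, params = fire_params(),
                           fixed = character(),
                           spinup_years = 5, spinup_loops = 1) {
  forcing <- if (inherits(scenario, "scenario_config")) {
    generate_forcing(scenario, fixed = fixed)
  } else if (inherits(scenario, "fire_forcing")) {
    scenario
  } else {
    abort("`scenario` must be a `scenario_config` or `fire_forcing`.")
  }
  check_forcing_finite(forcing)
  cfg <- forcing$config
  pftt <- cfg$pft
  npft <- nrow(pftt)
  nc <- nrow(forcing$cells)
  nd <- nrow(forcing$dates)
  nyr <- cfg$years
  dt_yr <- 1 / DAYS_PER_YEAR

  occ <- params$occurrence
  spr <- params$spread
  cmb <- combustion_vectors(pftt, params$combustion)
  torow <- function(v) matrix(v, nc, npft, byrow = TRUE)
  emisM <- lapply(cmb$emis, torow)
  mortM <- lapply(cmb$mort, torow)

  covers <- forcing$covers
  area <- forcing$cells$area_km2
  extent <- covers * area                      # km2 per cell-PFT
  extent_m2 <- extent * 1e6
  popdens0 <- forcing$cells$popdens_km2
  inv_extent <- ifelse(extent > 0, 1 / extent, 0)

  # carrying capacities (kg C m-2) per cell-PFT, before the k multiplier
  k0 <- lapply(setNames(ALL_POOLS, ALL_POOLS),
               function(p) torow(pftt[[paste0("k_", p)]]))
  regrow_fac <- list(
    live = exp(-torow(pftt$regrowth_live_per_yr) * dt_yr),
    litter = exp(-torow(pftt$regrowth_litter_per_yr) * dt_yr),
    soil = exp(-torow(pftt$regrowth_soil_per_yr) * dt_yr)
  )
  pool_fac <- list(leaf = regrow_fac$live, stem = regrow_fac$live,
                   root = regrow_fac$live, litter = regrow_fac$litter,
                   soil = regrow_fac$soil)

  pools <- lapply(k0, identity)
  state <- list(ffmc = rep_len(params$init$ffmc, nc),
                dmc = rep_len(params$init$dmc, nc),
                dc = rep_len(params$init$dc, nc))

  met <- forcing$met
  month <- forcing$dates$month
  yr_index <- rep(seq_len(nyr), each = DAYS_PER_YEAR)

  # spread-rate scalars are shared within a class; compute each class once
  classes <- unique(pftt$spread_class)
  class_of <- match(pftt$spread_class, classes)
  # extinction exponent is a constant of (pdmin, pdmax)
  q_v <- log(-log(1 - exp(-pi)) / pi) / log(spr$pdmin / spr$pdmax)

  step_day <- function(t, record) {
    ffmc <- .ffmc_core(state$ffmc, met$tmax[t, ], met$rh[t, ],
                       met$wind[t, ], met$rain[t, ])
    dmc <- .dmc_core(state$dmc, met$tmax[t, ], met$rh[t, ], met$rain[t, ],
                     month[t])
    dc <- .dc_core(state$dc, met$tmax[t, ], met$rain[t, ], month[t])
    state <<- list(ffmc = ffmc, dmc = dmc, dc = dc)
    isi <- .isi_core(ffmc, met$wind[t, ])
    bui <- .bui_core(dmc, dc)

    popd <- popdens0 * forcing$pop_mult[t]
    agb <- rowSums(covers * (pools$leaf + pools$stem))
    p_b <- clamp01((agb - occ$biomass_low) /
                     (occ$biomass_high - occ$biomass_low))
    p_m <- plogis(-25.2 + 0.34 * ffmc)
    p_nat <- clamp01((met$lightning[t, ] * DAYS_PER_YEAR -
                        occ$lightning_low) /
                       (occ$lightning_high - occ$lightning_low))
    p_hum <- clamp01((popd / occ$pop_threshold)^occ$pop_exponent)
    p_f <- p_b * (p_nat + (1 - p_nat) * p_hum) * p_m

    vd_class <- lapply(classes, function(cl) {
      if (cl == "grass") {
        cfg$r_green * (1 - exp(-0.031 * isi))^1.4 +
          1.3 * (1 - cfg$r_green) * (1 - exp(-0.035 * isi))^1.7
      } else {
        isi_scalar(isi, cl) * bui_scalar(bui, cl)
      }
    })
    vd <- matrix(0, nc, npft)
    for (j in seq_len(npft)) {
      vd[, j] <- pftt$vdmax_kmh[j] * vd_class[[class_of[j]]]
    }
    lb <- 1 + spr$lb_max_elong * (1 - exp(-spr$lb_decay * met$wind[t, ]))
    len <- (1 + spr$vu_frac) * vd * spr$dt_h
    a1 <- (pi / 4) * len * len / lb
    q <- 0.5 + 0.5 * (1 - exp(-pi * (popd / spr$pdmax)^q_v))
    ar <- a1 * (1 - q) * (2 - q) / q^2
    ba <- p_f * ar * extent / spr$a_rep
    over <- ba > extent
    ba[over] <- extent[over]
    bf <- ba * inv_extent

    emitted_total <- matrix(0, nc, npft)
    transfer <- matrix(0, nc, npft)
    kmul <- forcing$k_mult[t]
    for (p in ALL_POOLS) {
      em <- pools[[p]] * bf * emisM[[p]]
      loss <- em
      if (p %in% LIVE_POOLS) {
        mo <- pools[[p]] * bf * mortM[[p]]
        transfer <- transfer + mo
        loss <- loss + mo
      }
      emitted_total <- emitted_total + em
      kp <- k0[[p]] * kmul
      after <- pools[[p]] - loss
      after[after < 0] <- 0
      if (p == "litter") after <- after + transfer
      nxt <- kp - (kp - after) * pool_fac[[p]]
      nxt[nxt < 0] <- 0
      pools[[p]] <<- nxt
    }
    co2 <- rowSums(emitted_total * extent_m2) * CO2_PER_C   # kg CO2 per cell

    if (record) list(ba = rowSums(ba), co2 = co2) else NULL
  }

  # --- spin-up ------------------------------------------------------------
  n_spin <- min(spinup_years, nyr) * DAYS_PER_YEAR
  if (spinup_loops > 0 && n_spin > 0) {
    for (l in seq_len(spinup_loops)) {
      for (t in seq_len(n_spin)) step_day(t, record = FALSE)
    }
  }

  # --- transient ----------------------------------------------------------
  ba_cy <- matrix(0, nyr, nc)
  co2_cy <- matrix(0, nyr, nc)
  for (t in seq_len(nd)) {
    res <- step_day(t, record = TRUE)
    y <- yr_index[t]
    ba_cy[y, ] <- ba_cy[y, ] + res$ba
    co2_cy[y, ] <- co2_cy[y, ] + res$co2
  }

  years <- cfg$start_year + seq_len(nyr) - 1L
  day_year <- forcing$dates$year
  ann_mean <- function(m) {
    as.numeric(tapply(rowMeans(m), day_year, mean))
  }
  annual <- tibble(
    year = years,
    burned_area_km2 = rowSums(ba_cy),
    burned_area_mha = rowSums(ba_cy) * 1e-4,
    co2_kg = rowSums(co2_cy),
    co2_pg = rowSums(co2_cy) * 1e-12,
    tmax_mean = ann_mean(met$tmax),
    rh_mean = ann_mean(met$rh),
    wind_mean = ann_mean(met$wind),
    rain_mm_day = ann_mean(met$rain),
    lightning_strikes_km2_yr = ann_mean(met$lightning) * DAYS_PER_YEAR,
    popdens_mean = mean(popdens0) *
      as.numeric(tapply(forcing$pop_mult, day_year, mean))
  )
  annual$emission_intensity_kg_m2 <- ifelse(
    annual$burned_area_km2 > 0,
    annual$co2_kg / (annual$burned_area_km2 * 1e6), NA_real_)

  structure(list(annual = annual, ba_cell_year = ba_cy,
                 co2_cell_year = co2_cy, cells = forcing$cells,
                 config = cfg, params = params, fixed = forcing$fixed),
            class = "fire_run")
}

#' @export
print.fire_run <- function(x, ...) {
  cat(sprintf(
    "<fire_run> %d x %d cells, years %d-%d%s\n",
    x$config$nx, x$config$ny, min(x$annual$year), max(x$annual$year),
    if (length(x$fixed)) paste0(" (fixed: ", paste(x$fixed, collapse = ", "),
                                ")") else ""))
  cat(sprintf("  mean annual burned area: %.4g Mha;  mean fire CO2: %.4g Pg\n",
              mean(x$annual$burned_area_mha), mean(x$annual$co2_pg)))
  invisible(x)
}
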