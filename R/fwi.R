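# Canadian Forest Fire Weather Index (FWI) system: daily moisture codes
# (FFMC, DMC, DC) and the derived indices (ISI, BUI).  The equations are
# the standard published FWI equation chain (Van Wagner & Pickett lineage,
# as carried in the current reference code release), driven here by daily
# maximum temperature, relative humidity, wind speed, and 24-h rainfall.

# Monthly day-length factors for DMC drying (Canadian standard table) and
# monthly day-length adjustments for DC.
DMC_DAY_LENGTH <- c(6.5, 7.5, 9.0, 12.8, 13.9, 13.9, 12.4, 10.9, 9.4, 8.0, 7.0, 6.0)
DC_DAY_LENGTH  <- c(-1.6, -1.6, -1.6, 0.9, 3.8, 5.8, 6.4, 5.0, 2.4, 0.4, -1.6, -1.6)

#' Conventional FWI start-up state
#'
#' Standard initial values of the three moisture codes used to start an
#' FWI sequence in spring (FFMC 85, DMC 6, DC 15).  No overwintering
#' adjustment of the drought code is applied.
#'
#' @param ffmc,dmc,dc Initial fine fuel moisture code, duff moisture code,
#'   and drought code.
#' @return A named list with elements `ffmc`, `dmc`, `dc`.
#' @examples
#' fwi_initial()
#' @export
fwi_initial <- function(ffmc = 85, dmc = 6, dc = 15) {
  check_range(ffmc, 0, 101, "ffmc")
  check_nonneg(dmc, "dmc")
  check_nonneg(dc, "dc")
  list(ffmc = ffmc, dmc = dmc, dc = dc)
}

# Unchecked vectorized cores of the update equations.  The exported
# wrappers validate inputs and delegate here; the simulation engine,
# which validates its forcing once up front, calls these directly.

.ffmc_core <- function(ffmc, t, h, w, r) {
  mo <- 147.27723 * (101 - ffmc) / (59.5 + ffmc)
  wet <- r > 0.5
  if (any(wet)) {
    rw <- r[wet] - 0.5
    mw <- mo[wet]
    mr <- mw + 42.5 * rw * exp(-100 / (251 - mw)) * (1 - exp(-6.93 / rw))
    hi <- mw > 150
    if (any(hi)) {
      mr[hi] <- mr[hi] + 0.0015 * (mw[hi] - 150)^2 * sqrt(rw[hi])
    }
    mo[wet] <- pmin(mr, 250)
  }
  ed <- 0.942 * h^0.679 + 11 * exp((h - 100) / 10) +
    0.18 * (21.1 - t) * (1 - exp(-0.115 * h))
  m <- mo
  dry <- mo > ed
  if (any(dry)) {
    hd <- h[dry]
    ko <- 0.424 * (1 - (hd / 100)^1.7) +
      0.0694 * sqrt(w[dry]) * (1 - (hd / 100)^8)
    kd <- ko * 0.581 * exp(0.0365 * t[dry])
    m[dry] <- ed[dry] + (mo[dry] - ed[dry]) * 10^(-kd)
  }
  if (!all(dry)) {
    ew <- 0.618 * h^0.753 + 10 * exp((h - 100) / 10) +
      0.18 * (21.1 - t) * (1 - exp(-0.115 * h))
    wt <- !dry & mo < ew
    if (any(wt)) {
      hw <- h[wt]
      kl <- 0.424 * (1 - ((100 - hw) / 100)^1.7) +
        0.0694 * sqrt(w[wt]) * (1 - ((100 - hw) / 100)^8)
      kw <- kl * 0.581 * exp(0.0365 * t[wt])
      m[wt] <- ew[wt] - (ew[wt] - mo[wt]) * 10^(-kw)
    }
  }
  out <- 59.5 * (250 - m) / (147.27723 + m)
  out[out < 0] <- 0
  out[out > 101] <- 101
  out
}

.dmc_core <- function(dmc, t, h, r, month) {
  p0 <- dmc
  wet <- r > 1.5
  if (any(wet)) {
    pw <- p0[wet]
    re <- 0.92 * r[wet] - 1.27
    mo <- 20 + exp(5.6348 - pw / 43.43)
    b <- 6.2 * log(pmax(pw, 1e-12)) - 17.2
    mid <- pw <= 65
    b[mid] <- 14 - 1.3 * log(pmax(pw[mid], 1e-12))
    lo <- pw <= 33
    b[lo] <- 100 / (0.5 + 0.3 * pw[lo])
    mr <- mo + 1000 * re / (48.77 + b * re)
    p0[wet] <- pmax(43.43 * (5.6348 - log(pmax(mr - 20, 1e-12))), 0)
  }
  t[t < -1.1] <- -1.1
  k <- 1.894 * (t + 1.1) * (100 - h) * DMC_DAY_LENGTH[month] * 1e-6
  p0 + 100 * k
}

.dc_core <- function(dc, t, r, month) {
  d0 <- dc
  wet <- r > 2.8
  if (any(wet)) {
    rd <- 0.83 * r[wet] - 1.27
    qr <- 800 * exp(-d0[wet] / 400) + 3.937 * rd
    d0[wet] <- pmax(400 * log(800 / qr), 0)
  }
  t[t < -2.8] <- -2.8
  v <- 0.36 * (t + 2.8) + DC_DAY_LENGTH[month]
  v[v < 0] <- 0
  d0 + 0.5 * v
}

.isi_core <- function(ffmc, wind) {
  m <- 147.27723 * (101 - ffmc) / (59.5 + ffmc)
  0.208 * exp(0.05039 * wind) *
    (91.9 * exp(-0.1386 * m) * (1 + m^5.31 / 4.93e7))
}

.bui_core <- function(p, d) {
  denom <- p + 0.4 * d
  u <- numeric(length(denom))
  pos <- denom > 0
  low <- pos & (p <= 0.4 * d)
  hi <- pos & !low
  u[low] <- 0.8 * p[low] * d[low] / denom[low]
  u[hi] <- p[hi] - (1 - 0.8 * d[hi] / denom[hi]) *
    (0.92 + (0.0114 * p[hi])^1.7)
  u[u < 0] <- 0
  u
}

#' Daily fine fuel moisture code (FFMC) update
#'
#' One step of the kinetic drying/wetting model for surface fine litter
#' moisture, with a one-day time lag.  Rainfall above the 0.5 mm canopy
#' interception threshold first wets the fuel; the fuel then dries (or
#' wets) exponentially toward the humidity- and temperature-dependent
#' equilibrium moisture content.  Higher FFMC means drier, more ignitable
#' fine fuel.
#'
#' @param ffmc Previous day's FFMC, in \[0, 101\].
#' @param tmax_c Daily maximum air temperature (deg C).
#' @param rh_pct Relative humidity (%, 0-100).
#' @param wind_kmh Wind speed (km/h, >= 0).
#' @param rain_mm 24-h rainfall (mm, >= 0).
#' @return Updated FFMC in \[0, 101\].  Vectorized over all arguments.
#' @examples
#' ffmc_update(85, tmax_c = 30, rh_pct = 20, wind_kmh = 15, rain_mm = 0)
#' @export
ffmc_update <- function(ffmc, tmax_c, rh_pct, wind_kmh, rain_mm) {
  check_range(ffmc, 0, 101, "ffmc")
  check_range(rh_pct, 0, 100, "rh_pct")
  check_nonneg(wind_kmh, "wind_kmh")
  check_nonneg(rain_mm, "rain_mm")
  a <- recycle_common(ffmc = ffmc, t = tmax_c, h = rh_pct, w = wind_kmh,
                      r = rain_mm)
  .ffmc_core(a$ffmc, a$t, a$h, a$w, a$r)
}

#' Daily duff moisture code (DMC) update
#'
#' Moisture code of the loosely compacted organic (duff) layer.  Rainfall
#' above 1.5 mm wets the layer through a moisture-content transform;
#' drying follows temperature, humidity, and a monthly day-length factor.
#'
#' @inheritParams ffmc_update
#' @param dmc Previous day's DMC (>= 0).
#' @param month Calendar month 1-12, selecting the day-length factor.
#' @return Updated DMC (>= 0).  Vectorized.
#' @export
dmc_update <- function(dmc, tmax_c, rh_pct, rain_mm, month) {
  check_nonneg(dmc, "dmc")
  check_range(rh_pct, 0, 100, "rh_pct")
  check_nonneg(rain_mm, "rain_mm")
  month <- check_month(month)
  a <- recycle_common(p0 = dmc, t = tmax_c, h = rh_pct, r = rain_mm,
                      month = month)
  .dmc_core(a$p0, a$t, a$h, a$r, a$month)
}

#' Daily drought code (DC) update
#'
#' Moisture code of the deep, compact organic layer.  Rainfall above
#' 2.8 mm recharges the layer's moisture equivalent; drying follows
#' temperature plus a monthly day-length adjustment.
#'
#' @inheritParams dmc_update
#' @param dc Previous day's DC (>= 0).
#' @return Updated DC (>= 0).  Vectorized.
#' @export
dc_update <- function(dc, tmax_c, rain_mm, month) {
  check_nonneg(dc, "dc")
  check_nonneg(rain_mm, "rain_mm")
  month <- check_month(month)
  a <- recycle_common(d0 = dc, t = tmax_c, r = rain_mm, month = month)
  .dc_core(a$d0, a$t, a$r, a$month)
}

#' Initial spread index (ISI)
#'
#' Combines fine fuel moisture and wind speed into a relative expected
#' rate of fire spread.  Strictly increasing in wind at fixed FFMC and
#' increasing in FFMC at fixed wind.
#'
#' @param ffmc Fine fuel moisture code, in \[0, 101\].
#' @param wind_kmh Wind speed (km/h, >= 0).
#' @return ISI (>= 0).  Vectorized.
#' @examples
#' isi_index(90, 20)
#' @export
isi_index <- function(ffmc, wind_kmh) {
  check_range(ffmc, 0, 101, "ffmc")
  check_nonneg(wind_kmh, "wind_kmh")
  a <- recycle_common(ffmc = ffmc, wind = wind_kmh)
  .isi_core(a$ffmc, a$wind)
}

#' Buildup index (BUI)
#'
#' Combines the duff moisture code and drought code into a measure of
#' total fuel available for combustion.  Zero when DMC is zero,
#' nondecreasing in both codes.
#'
#' @param dmc Duff moisture code (>= 0).
#' @param dc Drought code (>= 0).
#' @return BUI (>= 0).  Vectorized.
#' @examples
#' bui_index(50, 300)
#' @export
bui_index <- function(dmc, dc) {
  check_nonneg(dmc, "dmc")
  check_nonneg(dc, "dc")
  a <- recycle_common(p = dmc, d = dc)
  .bui_core(a$p, a$d)
}

#' One daily FWI step
#'
#' Advances the three moisture codes by one day and computes the derived
#' indices from the updated codes, in the standard order (codes first,
#' then ISI from the new FFMC and BUI from the new DMC/DC).
#'
#' @param state A list with `ffmc`, `dmc`, `dc` (see [fwi_initial()]);
#'   elements may be vectors (e.g., one entry per grid cell).
#' @inheritParams ffmc_update
#' @inheritParams dmc_update
#' @return A list with updated `ffmc`, `dmc`, `dc` and the indices
#'   `isi`, `bui`.
#' @examples
#' fwi_step(fwi_initial(), tmax_c = 25, rh_pct = 40, wind_kmh = 10,
#'          rain_mm = 0, month = 7)
#' @export
fwi_step <- function(state, tmax_c, rh_pct, wind_kmh, rain_mm, month) {
  ffmc <- ffmc_update(state$ffmc, tmax_c, rh_pct, wind_kmh, rain_mm)
  dmc <- dmc_update(state$dmc, tmax_c, rh_pct, rain_mm, month)
  dc <- dc_update(state$dc, tmax_c, rain_mm, month)
  list(ffmc = ffmc, dmc = dmc, dc = dc,
       isi = isi_index(ffmc, wind_kmh), bui = bui_index(dmc, dc))
}

#' Run the FWI system over a daily weather table
#'
#' Steps the FWI moisture codes through a daily weather record and
#' appends the codes and indices as columns.  If a `cell` column is
#' present, each cell is treated as an independent series (all cells must
#' have the same number of days, in day order); the update is vectorized
#' across cells within each day.
#'
#' @param met A data frame with columns `tmax_c`, `rh_pct`, `wind_kmh`,
#'   `rain_mm`, `month` (integer 1-12) and optionally `cell`.  Rows must
#'   be in chronological order within each cell.
#' @param init Initial code values, see [fwi_initial()].
#' @return The input as a tibble with columns `ffmc`, `dmc`, `dc`,
#'   `isi`, `bui` appended.
#' @examples
#' met <- tibble::tibble(tmax_c = c(20, 25, 30), rh_pct = c(60, 40, 30),
#'                       wind_kmh = 10, rain_mm = 0, month = 7L)
#' fwi_run(met)
#' @export
fwi_run <- function(met, init = fwi_initial()) {
  check_cols(met, c("tmax_c", "rh_pct", "wind_kmh", "rain_mm", "month"), "met")
  met <- as_tibble(met)
  if (!"cell" %in% names(met)) {
    cells <- rep(1L, nrow(met))
  } else {
    cells <- met$cell
  }
  ucell <- unique(cells)
  nc <- length(ucell)
  nt <- nrow(met) / nc
  if (nt != as.integer(nt)) {
    abort("`met` must be a balanced panel: equal number of days per cell.")
  }
  nt <- as.integer(nt)
  # stable sort by cell keeps each cell's rows in their chronological order
  ord <- order(match(cells, ucell))
  cols <- c("tmax_c", "rh_pct", "wind_kmh", "rain_mm", "month")
  mats <- lapply(cols, function(cl) matrix(met[[cl]][ord], nrow = nt))
  names(mats) <- cols

  state <- list(ffmc = rep_len(init$ffmc, nc), dmc = rep_len(init$dmc, nc),
                dc = rep_len(init$dc, nc))
  out <- list(ffmc = matrix(0, nt, nc), dmc = matrix(0, nt, nc),
              dc = matrix(0, nt, nc), isi = matrix(0, nt, nc),
              bui = matrix(0, nt, nc))
  for (t in seq_len(nt)) {
    st <- fwi_step(state, mats$tmax_c[t, ], mats$rh_pct[t, ],
                   mats$wind_kmh[t, ], mats$rain_mm[t, ], mats$month[t, ])
    state <- st[c("ffmc", "dmc", "dc")]
    for (nm in names(out)) out[[nm]][t, ] <- st[[nm]]
  }
  res <- met[ord, ]
  for (nm in names(out)) res[[nm]] <- as.vector(out[[nm]])
  res[order(ord), ] %>% as_tibble()
}
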