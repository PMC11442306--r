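# Fire spread and burned area: plant functional type (PFT) specific
# downwind spread rates from ISI and BUI, elliptical daily fire growth,
# same-day extinction probability from population density, and expected
# burned area per PFT for a representative area.

#' Default PFT spread parameter table
#'
#' Maximum downwind spread rates (km/h) by PFT, each mapped to one of the
#' three spread-rate formula classes (`needleleaf`, `broadleaf`,
#' `grass`).
#'
#' @return A tibble with columns `pft`, `spread_class`, `vdmax_kmh`.
#' @examples
#' default_spread_params()
#' @export
default_spread_params <- function() {
  tibble(
    pft = c("needleleaf_evergreen", "needleleaf_continental",
            "broadleaf_deciduous", "grass"),
    spread_class = c("needleleaf", "needleleaf", "broadleaf", "grass"),
    vdmax_kmh = c(2.3, 3.8, 0.92, 4.97)
  )
}

# BUI-dependence of the tree spread-rate branches, normalized so the
# scalar tends to 1 as BUI tends to infinity (coefficients 0.7568 and
# 0.8482 are the normalized values at the reference BUIs 64 and 32,
# where the exponential term is exactly 1).
bui_scalar <- function(bui, spread_class) {
  switch(spread_class,
    needleleaf = ifelse(bui <= 0, 0,
                        0.7568 * exp(-17.8337 * (1 / bui - 1 / 64))),
    broadleaf = ifelse(bui <= 0, 0,
                       0.8482 * exp(-5.2680 * (1 / bui - 1 / 32))),
    abort(sprintf("No BUI scalar for spread class '%s'.", spread_class))
  )
}

isi_scalar <- function(isi, spread_class) {
  switch(spread_class,
    needleleaf = (1 - exp(-0.0232 * isi))^1.6,
    broadleaf = (1 - exp(-0.0282 * isi))^1.5,
    abort(sprintf("No ISI scalar for spread class '%s'.", spread_class))
  )
}

#' Downwind fire spread rate
#'
#' PFT-class-specific spread rate (km/h).  For the tree classes the rate
#' is the class maximum times an ISI scalar and a BUI scalar, each
#' normalized to approach 1 as the index grows without bound.  For grass
#' the rate depends on ISI alone, with green and cured (brown) fractions
#' weighted by `r_green`; fully cured grass approaches `1.3 * vdmax_kmh`.
#'
#' @param isi Initial spread index (>= 0).
#' @param bui Buildup index (>= 0); ignored for grass.
#' @param spread_class One of `"needleleaf"`, `"broadleaf"`, `"grass"`.
#' @param vdmax_kmh Maximum downwind spread rate for the PFT (km/h).
#' @param r_green Green (uncured) fraction of grass leaf biomass in
#'   \[0, 1\]; required for the grass class.
#' @return Spread rate `v_d` (km/h).  Vectorized over `isi`, `bui`,
#'   `r_green`.
#' @examples
#' spread_rate(10, 64, "needleleaf", 2.3)
#' spread_rate(10, 0, "grass", 4.97, r_green = 0.5)
#' @export
spread_rate <- function(isi, bui, spread_class, vdmax_kmh, r_green = NULL) {
  check_nonneg(isi, "isi")
  check_nonneg(vdmax_kmh, "vdmax_kmh")
  if (length(spread_class) != 1L ||
      !spread_class %in% c("needleleaf", "broadleaf", "grass")) {
    abort("`spread_class` must be one of 'needleleaf', 'broadleaf', 'grass'.")
  }
  if (spread_class == "grass") {
    if (is.null(r_green)) {
      abort("The grass spread class requires `r_green`.")
    }
    check_range(r_green, 0, 1, "r_green")
    return(vdmax_kmh * r_green * (1 - exp(-0.031 * isi))^1.4 +
             1.3 * vdmax_kmh * (1 - r_green) * (1 - exp(-0.035 * isi))^1.7)
  }
  check_nonneg(bui, "bui")
  vdmax_kmh * isi_scalar(isi, spread_class) * bui_scalar(bui, spread_class)
}

#' Ellipse length-to-breadth ratio
#'
#' Wind-speed dependence of the fire ellipse's elongation:
#' `1 + 10 (1 - exp(-0.06 w))`, equal to 1 (a circular fire) in calm air
#' and saturating at 11 in strong wind.
#'
#' @param wind_kmh Wind speed (km/h, >= 0).
#' @param max_elong,decay Shape constants of the saturating form.
#' @return Length-to-breadth ratio (>= 1).  Vectorized.
#' @examples
#' length_to_breadth(c(0, 10, 50))
#' @export
length_to_breadth <- function(wind_kmh, max_elong = 10, decay = 0.06) {
  check_nonneg(wind_kmh, "wind_kmh")
  1 + max_elong * (1 - exp(-decay * wind_kmh))
}

#' Area burned by one fire in one day
#'
#' Elliptical fire growth: the major axis is the distance covered
#' downwind plus upwind in `dt_h` hours, the breadth is the major axis
#' divided by the length-to-breadth ratio, and the area is
#' `pi/4 * length * breadth`.
#'
#' @param v_d,v_u Downwind and upwind spread rates (km/h), with
#'   `0 <= v_u <= v_d`.
#' @param lb_ratio Length-to-breadth ratio (>= 1).
#' @param dt_h Fire-day duration (hours).
#' @return Area burned in one day (km2).  Vectorized.
#' @examples
#' daily_area(1, 0, 1)  # (pi/4) * 24^2
#' @export
daily_area <- function(v_d, v_u, lb_ratio, dt_h = 24) {
  check_nonneg(v_u, "v_u")
  if (any(v_u > v_d + 1e-12)) {
    abort("`v_u` must not exceed `v_d`.")
  }
  len <- (v_d + v_u) * dt_h
  (pi / 4) * len * (len / lb_ratio)
}

#' Same-day fire extinction probability
#'
#' Probability `q` that a fire is extinguished on the day it starts, as a
#' saturating function of population density `p_d`:
#' `q = 0.5 + 0.5 (1 - exp(-pi (p_d / p_dmax)^v))`, with the exponent
#' `v = ln(-ln(1 - exp(-pi)) / pi) / ln(p_dmin / p_dmax)` chosen so that
#' q is approximately 0.5 at the minimum population-density threshold and
#' approximately 1 at the maximum.
#'
#' @param popdens_km2 Population density (persons km-2, >= 0).
#' @param pdmin,pdmax Minimum and maximum population density thresholds
#'   (persons km-2), `0 < pdmin < pdmax`.
#' @return Extinction probability in \[0.5, 1).  Vectorized over
#'   `popdens_km2`.
#' @examples
#' extinguish_prob(c(0.001, 0.1))
#' @export
extinguish_prob <- function(popdens_km2, pdmin = 0.001, pdmax = 0.1) {
  check_nonneg(popdens_km2, "popdens_km2")
  if (!(pdmin > 0 && pdmin < pdmax)) {
    abort("`pdmin` must be positive and strictly less than `pdmax`.")
  }
  v <- log(-log(1 - exp(-pi)) / pi) / log(pdmin / pdmax)
  0.5 + 0.5 * (1 - exp(-pi * (popdens_km2 / pdmax)^v))
}

#' Area burned over the duration of a fire
#'
#' Expected total burned area assuming an exponentially distributed fire
#' duration governed by the daily extinction probability `q`:
#' `a_r = a_1 (1 - q)(2 - q) / q^2`.
#'
#' @param a1_km2 Area burned in one day (km2, >= 0).
#' @param q Daily extinction probability in (0, 1\].
#' @return Expected burned area per fire (km2).  Vectorized.
#' @examples
#' area_per_fire(1, 0.5)  # 3
#' @export
area_per_fire <- function(a1_km2, q) {
  check_nonneg(a1_km2, "a1_km2")
  if (any(q <= 0) || any(q > 1)) {
    abort("`q` must lie in (0, 1].")
  }
  a1_km2 * (1 - q) * (2 - q) / q^2
}

#' Expected burned area for one PFT
#'
#' Scales the per-fire burned area by the fire-occurrence probability and
#' by the PFT's extent relative to the representative area:
#' `A_b = P_f * a_r * (A_g * f_alpha) / a_rep`, capped at the PFT extent
#' `A_g * f_alpha` (a PFT cannot burn more than its own area in a day).
#'
#' @param p_f Fire occurrence probability in \[0, 1\].
#' @param ar_km2 Area burned over the fire's duration (km2).
#' @param cell_area_km2 Grid-cell area `A_g` (km2).
#' @param f_alpha Fractional cover of the PFT in \[0, 1\].
#' @param a_rep Representative area (km2), 800 by default.
#' @return Burned area for the PFT (km2).  Vectorized.
#' @examples
#' burned_area_pft(0.5, 10, 800, 1)
#' @export
burned_area_pft <- function(p_f, ar_km2, cell_area_km2, f_alpha,
                            a_rep = 800) {
  check_range(p_f, 0, 1, "p_f")
  check_nonneg(ar_km2, "ar_km2")
  check_nonneg(cell_area_km2, "cell_area_km2")
  check_range(f_alpha, 0, 1, "f_alpha")
  extent <- cell_area_km2 * f_alpha
  pmin(p_f * ar_km2 * extent / a_rep, extent)
}

#' Full fire-geometry chain for a cell-day table
#'
#' Data-frame interface composing spread rate, ellipse geometry,
#' extinction, and per-fire area.  Expects columns `isi`, `bui`,
#' `wind_kmh`, `popdens_km2` plus the PFT parameters as arguments, and
#' appends `v_d`, `v_u`, `lb_ratio`, `a1_km2`, `q`, `ar_km2`.
#'
#' @param data Cell-day table with the columns named above.
#' @param spread_class,vdmax_kmh PFT spread parameters (see
#'   [default_spread_params()]).
#' @param r_green Green fraction of grass leaf biomass (grass class only).
#' @param vu_frac Upwind spread rate as a fraction of the downwind rate.
#' @param pdmin,pdmax Extinction thresholds, see [extinguish_prob()].
#' @param dt_h Fire-day duration (hours).
#' @return `data` as a tibble with the geometry columns appended.
#' @export
fire_geometry <- function(data, spread_class, vdmax_kmh, r_green = NULL,
                          vu_frac = 0.2, pdmin = 0.001, pdmax = 0.1,
                          dt_h = 24) {
  check_cols(data, c("isi", "bui", "wind_kmh", "popdens_km2"), "data")
  data %>%
    as_tibble() %>%
    mutate(
      v_d = spread_rate(.data$isi, .data$bui, spread_class, vdmax_kmh,
                        r_green = r_green),
      v_u = vu_frac * .data$v_d,
      lb_ratio = length_to_breadth(.data$wind_kmh),
      a1_km2 = daily_area(.data$v_d, .data$v_u, .data$lb_ratio, dt_h = dt_h),
      q = extinguish_prob(.data$popdens_km2, pdmin = pdmin, pdmax = pdmax),
      ar_km2 = area_per_fire(.data$a1_km2, .data$q)
    )
}
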