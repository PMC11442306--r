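# Daily probability of fire occurrence for a representative area:
# the product of conditional probabilities given aboveground biomass
# (fuel availability), ignition sources (lightning + people), and fine
# fuel moisture (FFMC).

#' Probability of fire conditional on aboveground biomass
#'
#' Piecewise-linear ramp in aboveground biomass: 0 at or below
#' 0.2 kg C m-2, 1 at or above 1.0 kg C m-2, linear between.
#'
#' @param agb_kgC_m2 Aboveground biomass (kg C m-2, >= 0).
#' @param low,high Ramp thresholds (kg C m-2).
#' @return Probability in \[0, 1\].  Vectorized.
#' @examples
#' prob_biomass(c(0.2, 0.6, 1.0))
#' @export
prob_biomass <- function(agb_kgC_m2, low = 0.2, high = 1.0) {
  check_nonneg(agb_kgC_m2, "agb_kgC_m2")
  pmin(pmax((agb_kgC_m2 - low) / (high - low), 0), 1)
}

#' Probability of fire conditional on fuel moisture
#'
#' Logistic function of the fine fuel moisture code,
#' `exp(-25.2 + 0.34 FFMC) / (1 + exp(-25.2 + 0.34 FFMC))`: under the
#' standard FWI convention high FFMC means dry, ignitable surface litter,
#' so the probability rises steeply between FFMC ~ 67 and ~ 79.
#'
#' @param ffmc Fine fuel moisture code, in \[0, 101\].
#' @param intercept,slope Logit coefficients.
#' @return Probability in \[0, 1\].  Vectorized.
#' @examples
#' prob_moisture(c(60, 74.1, 85))
#' @export
prob_moisture <- function(ffmc, intercept = -25.2, slope = 0.34) {
  check_range(ffmc, 0, 101, "ffmc")
  plogis(intercept + slope * ffmc)
}

#' Annualize a daily lightning strike density
#'
#' Converts strikes km-2 day-1 to strikes km-2 yr-1 so the annual-rate
#' ignition thresholds apply directly.
#'
#' @param strikes_km2_day Daily cloud-to-ground strike density.
#' @param days_per_year Days in the year (365.25 by default; the
#'   simulator's no-leap calendar uses 365).
#' @return Annualized strike rate (strikes km-2 yr-1).
#' @export
annualize_strikes <- function(strikes_km2_day, days_per_year = 365.25) {
  check_nonneg(strikes_km2_day, "strikes_km2_day")
  strikes_km2_day * days_per_year
}

#' Probability of fire conditional on an ignition source
#'
#' Cumulative contribution of natural (lightning) and anthropogenic
#' ignition.  The natural component ramps linearly from 0 at
#' `lightning_low` to 1 at `lightning_high` strikes km-2 yr-1; the human
#' component is `min(1, (popdens / pop_threshold)^pop_exponent)`, reaching
#' one at the population-density threshold.  The two are combined as
#' complementary probabilities, `p_nat + (1 - p_nat) * p_hum`.
#'
#' @param lightning_strikes_km2_yr Annualized cloud-to-ground strike rate
#'   (strikes km-2 yr-1, >= 0).
#' @param popdens_km2 Population density (persons km-2, >= 0).
#' @param lightning_low,lightning_high Natural-ignition ramp thresholds
#'   (strikes km-2 yr-1).
#' @param pop_threshold Population density at which the human component
#'   saturates (persons km-2).
#' @param pop_exponent Exponent of the human-ignition power law.
#' @return Probability in \[0, 1\].  Vectorized.
#' @examples
#' prob_ignition(10, 0)    # lightning saturates the natural component
#' prob_ignition(0, 300)   # human component saturates
#' @export
prob_ignition <- function(lightning_strikes_km2_yr, popdens_km2,
                          lightning_low = 0.25, lightning_high = 10,
                          pop_threshold = 300, pop_exponent = 0.43) {
  check_nonneg(lightning_strikes_km2_yr, "lightning_strikes_km2_yr")
  check_nonneg(popdens_km2, "popdens_km2")
  p_nat <- pmin(pmax((lightning_strikes_km2_yr - lightning_low) /
                       (lightning_high - lightning_low), 0), 1)
  p_hum <- pmin((popdens_km2 / pop_threshold)^pop_exponent, 1)
  p_nat + (1 - p_nat) * p_hum
}

#' Probability of fire occurrence
#'
#' The product of the biomass, ignition, and moisture conditional
#' probabilities.
#'
#' @param p_b,p_i,p_m Conditional probabilities in \[0, 1\].
#' @return `p_b * p_i * p_m`.  Vectorized.
#' @examples
#' prob_fire(0.5, 0.5, 0.5)
#' @export
prob_fire <- function(p_b, p_i, p_m) {
  check_range(p_b, 0, 1, "p_b")
  check_range(p_i, 0, 1, "p_i")
  check_range(p_m, 0, 1, "p_m")
  p_b * p_i * p_m
}

#' Add fire-occurrence probabilities to a cell-day table
#'
#' Data-frame interface to the occurrence chain: expects columns
#' `agb_kgC_m2`, `lightning_strikes_km2_yr`, `popdens_km2`, `ffmc`, and
#' appends `p_b`, `p_i`, `p_m`, `p_f`.
#'
#' @param data A data frame with the columns named above.
#' @param ... Passed on to [prob_ignition()] (thresholds, exponent) and
#'   ignored by the other components.
#' @return `data` as a tibble with probability columns appended.
#' @export
fire_probabilities <- function(data, ...) {
  check_cols(data, c("agb_kgC_m2", "lightning_strikes_km2_yr",
                     "popdens_km2", "ffmc"), "data")
  data %>%
    as_tibble() %>%
    mutate(
      p_b = prob_biomass(.data$agb_kgC_m2),
      p_i = prob_ignition(.data$lightning_strikes_km2_yr,
                          .data$popdens_km2, ...),
      p_m = prob_moisture(.data$ffmc),
      p_f = prob_fire(.data$p_b, .data$p_i, .data$p_m)
    )
}
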