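# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fire simulation run
#'
#' @param x A `fire_run` object.
#' @param ... Unused.
#' @return The annual diagnostics tibble.
#' @exportS3Method
tidy.fire_run <- function(x, ...) {
  x$annual
}

#' One-row summary of a fire simulation run
#'
#' @param x A `fire_run` object.
#' @param ... Unused.
#' @return A one-row tibble with the simulated period, mean annual
#'   burned area (Mha), mean annual fire CO2 (Pg), and the overall
#'   emission intensity (kg CO2 per m2 burned).
#' @exportS3Method
glance.fire_run <- function(x, ...) {
  tot_ba_m2 <- sum(x$annual$burned_area_km2) * 1e6
  tibble(
    years = nrow(x$annual),
    year_start = min(x$annual$year),
    year_end = max(x$annual$year),
    mean_burned_area_mha = mean(x$annual$burned_area_mha),
    mean_co2_pg = mean(x$annual$co2_pg),
    emission_intensity_kg_m2 = if (tot_ba_m2 > 0) {
      sum(x$annual$co2_kg) / tot_ba_m2
    } else {
      NA_real_
    }
  )
}

#' Tidy a factorial attribution result
#'
#' @param x A `fire_attribution` object.
#' @param ... Unused.
#' @return The per-driver contribution tibble.
#' @exportS3Method
tidy.fire_attribution <- function(x, ...) {
  x$table
}

#' One-row summary of a factorial attribution
#'
#' @param x A `fire_attribution` object.
#' @param ... Unused.
#' @return A one-row tibble with the full-run change and window sizes.
#' @exportS3Method
glance.fire_attribution <- function(x, ...) {
  tibble(measure = x$measure, delta_full = x$delta_full,
         ref_window = x$ref_window, end_window = x$end_window,
         undefined = x$undefined)
}

#' Tidy a sensitivity analysis
#'
#' @param x A `fire_sensitivity` object.
#' @param ... Unused.
#' @return The per-driver slope tibble (with confidence bounds).
#' @exportS3Method
tidy.fire_sensitivity <- function(x, ...) {
  x$slopes
}

#' One-row summary of a sensitivity analysis
#'
#' @param x A `fire_sensitivity` object.
#' @param ... Unused.
#' @return A one-row tibble with the response, span, and point count.
#' @exportS3Method
glance.fire_sensitivity <- function(x, ...) {
  tibble(response = x$response, span = x$span, n_points = x$n_points,
         n_drivers = nrow(x$slopes))
}

#' Tidy an ensemble change test
#'
#' @param x A `fire_change_test` object.
#' @param ... Unused.
#' @return The per-cell test tibble.
#' @exportS3Method
tidy.fire_change_test <- function(x, ...) {
  as_tibble(x)
}
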