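# ggplot2 graphics for the result objects.

#' Plot annual burned area and fire CO2 emissions
#'
#' @param object A `fire_run` object.
#' @param ... Unused.
#' @return A ggplot with one facet per quantity.
#' @exportS3Method
autoplot.fire_run <- function(object, ...) {
  object$annual %>%
    select("year", "burned_area_mha", "co2_pg") %>%
    tidyr::pivot_longer(-"year") %>%
    mutate(name = dplyr::recode(.data$name,
                                burned_area_mha = "Burned area (Mha)",
                                co2_pg = "Fire CO2 (Pg)")) %>%
    ggplot(aes(x = .data$year, y = .data$value)) +
    geom_line(colour = "firebrick") +
    facet_wrap(~name, scales = "free_y", ncol = 1) +
    labs(x = "Year", y = NULL, title = "Simulated annual fire activity") +
    theme_minimal()
}

#' Map mean annual burned fraction
#'
#' @param run A `fire_run` object.
#' @param years Optional subset of years to average over.
#' @return A ggplot raster map of the mean annual fraction of each cell
#'   burned.
#' @export
plot_burned_area_map <- function(run, years = NULL) {
  m <- run$ba_cell_year
  keep <- if (is.null(years)) seq_len(nrow(m)) else
    which(run$annual$year %in% years)
  frac <- colMeans(m[keep, , drop = FALSE]) / run$cells$area_km2
  run$cells %>%
    mutate(burned_fraction = frac) %>%
    ggplot(aes(x = .data$ix, y = .data$iy, fill = .data$burned_fraction)) +
    geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    labs(x = NULL, y = NULL, fill = "Mean annual\nburned fraction") +
    theme_minimal()
}

#' Plot factorial attribution contributions
#'
#' @param object A `fire_attribution` object.
#' @param ... Unused.
#' @return A ggplot bar chart of normalized contributions per driver.
#' @exportS3Method
autoplot.fire_attribution <- function(object, ...) {
  object$table %>%
    ggplot(aes(x = stats::reorder(.data$driver, -.data$contribution),
               y = .data$contribution)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "Normalized contribution",
         title = sprintf("Drivers of the %s trend", object$measure)) +
    theme_minimal()
}

#' Plot driver-sensitivity scatter with smoothed curves
#'
#' @param object A `fire_sensitivity` object.
#' @param ... Unused.
#' @return A ggplot with one facet per driver: annual points plus the
#'   locally weighted smooth.
#' @exportS3Method
autoplot.fire_sensitivity <- function(object, ...) {
  ggplot(object$points,
         aes(x = .data$driver_value, y = .data$response_value)) +
    geom_point(alpha = 0.25, size = 0.6) +
    geom_line(data = object$curves,
              aes(x = .data$driver_value, y = .data$smoothed),
              colour = "firebrick", linewidth = 1) +
    facet_wrap(~driver, scales = "free_x") +
    labs(x = "Annual driver mean", y = object$response) +
    theme_minimal()
}

#' Map an ensemble change test
#'
#' @param object A `fire_change_test` object.
#' @param cells Optional cell table (with `ix`, `iy`) for map layout;
#'   defaults to a square grid inferred from the cell count.
#' @param ... Unused.
#' @return A ggplot map of the end-minus-reference change with points
#'   stippling cells showing no significant change.
#' @exportS3Method
autoplot.fire_change_test <- function(object, cells = NULL, ...) {
  df <- as_tibble(object)
  if (is.null(cells)) {
    nx <- round(sqrt(nrow(df)))
    df$ix <- (df$cell - 1) %% nx + 1
    df$iy <- (df$cell - 1) %/% nx + 1
  } else {
    df <- left_join(df, select(cells, "cell", "ix", "iy"), by = "cell")
  }
  df$change <- df$mean_end - df$mean_reference
  ggplot(df, aes(x = .data$ix, y = .data$iy)) +
    geom_raster(aes(fill = .data$change)) +
    geom_point(data = df[df$no_change, ], shape = 20, size = 0.4,
               colour = "grey20") +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick") +
    labs(x = NULL, y = NULL, fill = "Change",
         caption = "Stippled cells: no significant change") +
    theme_minimal()
}
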