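# Factorial driver attribution, driver-sensitivity analysis, and
# ensemble significance testing over fire_run objects.

run_measure <- function(run, measure) {
  check_cols(run$annual, measure, "annual")
  run$annual[[measure]]
}

window_delta <- function(x, ref_window, end_window) {
  if (length(x) < ref_window + end_window) {
    abort("Run is shorter than the reference plus end windows.")
  }
  mean(x[seq.int(length(x) - end_window + 1, length(x))]) -
    mean(x[seq_len(ref_window)])
}

#' Factorial attribution of a simulated trend to its drivers
#'
#' Compares a full transient run against factorial runs in which one
#' driver at a time was held at its reference-year level.  The change
#' `Delta` of each run is the end-window mean minus the reference-window
#' mean of the chosen annual measure; driver `d` contributes
#' `Delta_full - Delta_fixed(d)`, normalized by the sum over drivers so
#' contributions add to 1 when the drivers cover the trend.
#'
#' @param full A `fire_run` with all drivers transient.
#' @param fixed A named list of `fire_run`s, one per driver, each run
#'   with that driver fixed; all runs must share the scenario seed.
#' @param measure Column of `annual` to attribute
#'   (default `"burned_area_mha"`).
#' @param ref_window,end_window Lengths (years) of the reference and end
#'   averaging windows (11 by default, mirroring decade-plus-one
#'   windows).
#' @return A `fire_attribution` object; its `table` is a tibble with
#'   `driver`, `delta_fixed`, `contribution_raw`, `contribution`.  When
#'   the summed contributions are ~ 0 the normalized contributions are
#'   flagged undefined (`NA`) with a warning.
#' @export
factorial_attribution <- function(full, fixed,
                                  measure = "burned_area_mha",
                                  ref_window = 11, end_window = 11) {
  if (!inherits(full, "fire_run")) abort("`full` must be a `fire_run`.")
  if (!length(fixed) || is.null(names(fixed)) || any(names(fixed) == "")) {
    abort("`fixed` must be a named list of `fire_run` objects.")
  }
  seeds <- vapply(c(list(full), fixed), function(r) r$config$seed, numeric(1))
  if (length(unique(seeds)) != 1L) {
    abort("All runs must share the scenario seed.")
  }
  d_full <- window_delta(run_measure(full, measure), ref_window, end_window)
  d_fix <- vapply(fixed, function(r) {
    window_delta(run_measure(r, measure), ref_window, end_window)
  }, numeric(1))
  raw <- d_full - d_fix
  denom <- sum(raw)
  undefined <- abs(denom) < 1e-9 * max(abs(d_full), 1e-12)
  if (undefined) {
    warn("Total attributable change is ~0; normalized contributions are undefined.")
  }
  tbl <- tibble(
    driver = names(fixed),
    delta_fixed = unname(d_fix),
    contribution_raw = unname(raw),
    contribution = if (undefined) NA_real_ else unname(raw) / denom
  )
  structure(list(table = tbl, delta_full = d_full, measure = measure,
                 ref_window = ref_window, end_window = end_window,
                 undefined = undefined),
            class = "fire_attribution")
}

#' @export
print.fire_attribution <- function(x, ...) {
  cat(sprintf("<fire_attribution> of %s (delta_full = %.4g)\n",
              x$measure, x$delta_full))
  print(x$table)
  invisible(x)
}

#' Pool annual diagnostics from several runs
#'
#' @param runs A (optionally named) list of `fire_run` objects.
#' @return A tibble of all runs' annual tables with a `run` identifier.
#' @export
collect_annual <- function(runs) {
  if (inherits(runs, "fire_run")) runs <- list(runs)
  nm <- names(runs) %||% as.character(seq_along(runs))
  nm[nm == ""] <- as.character(seq_along(runs))[nm == ""]
  purrr::map2(runs, nm, function(r, n) mutate(r$annual, run = n)) %>%
    bind_rows() %>%
    select("run", dplyr::everything())
}

#' Driver-sensitivity scatter and smoothed response curves
#'
#' Pools annual values across runs and, for each driver column, emits the
#' (driver, response) point set, a locally weighted (tri-cube, default
#' span 0.75) smooth, and a linear slope with its confidence interval.
#' Constant drivers yield a flagged `NA` slope.
#'
#' @param data A data frame of pooled annual values (see
#'   [collect_annual()]) or a list of `fire_run`s.
#' @param drivers Character vector of driver columns (defaults to mean
#'   temperature, lightning, relative humidity, population density).
#' @param response Response column (default `"burned_area_mha"`).
#' @param span Span of the loess smooth.
#' @param conf_level Confidence level of the slope interval.
#' @return A `fire_sensitivity` object with `points`, `curves` (loess
#'   predictions on a 100-point grid per driver), and `slopes` tibbles.
#' @export
sensitivity_curves <- function(data,
                               drivers = c("tmax_mean",
                                           "lightning_strikes_km2_yr",
                                           "rh_mean", "popdens_mean"),
                               response = "burned_area_mha",
                               span = 0.75, conf_level = 0.95) {
  if (is.list(data) && !is.data.frame(data)) data <- collect_annual(data)
  check_cols(data, c(drivers, response), "data")
  data <- as_tibble(data)

  keep <- intersect(c("run", "year"), names(data))
  points <- data %>%
    select(all_of(c(keep, drivers, response))) %>%
    tidyr::pivot_longer(all_of(drivers), names_to = "driver",
                        values_to = "driver_value") %>%
    rename(response_value = !!rlang::sym(response))

  fit_one <- function(d) {
    x <- data[[d]]
    y <- data[[response]]
    if (diff(range(x)) <= 0) {
      return(list(
        slope = tibble(driver = d, slope = NA_real_, conf_low = NA_real_,
                       conf_high = NA_real_, constant = TRUE),
        curve = tibble(driver = d, driver_value = numeric(0),
                       smoothed = numeric(0))
      ))
    }
    fit <- lm(y ~ x)
    se <- summary(fit)$coefficients["x", "Std. Error"]
    tq <- qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
    lo <- loess(y ~ x, span = span, degree = 2,
                family = "gaussian")
    grid <- seq(min(x), max(x), length.out = 100)
    list(
      slope = tibble(driver = d, slope = unname(coef(fit)["x"]),
                     conf_low = unname(coef(fit)["x"]) - tq * se,
                     conf_high = unname(coef(fit)["x"]) + tq * se,
                     constant = FALSE),
      curve = tibble(driver = d, driver_value = grid,
                     smoothed = predict(lo, newdata = data.frame(x = grid)))
    )
  }
  fits <- lapply(drivers, fit_one)
  structure(list(
    points = points,
    curves = bind_rows(lapply(fits, `[[`, "curve")),
    slopes = bind_rows(lapply(fits, `[[`, "slope")),
    response = response, span = span, n_points = nrow(data)
  ), class = "fire_sensitivity")
}

#' @export
print.fire_sensitivity <- function(x, ...) {
  cat(sprintf("<fire_sensitivity> %s vs %d driver(s), %d annual points\n",
              x$response, nrow(x$slopes), x$n_points))
  print(x$slopes)
  invisible(x)
}

#' Per-cell ensemble change test
#'
#' Two-sided, unpaired two-sample t-test per grid cell comparing
#' reference-period means against end-period means across ensemble
#' members.  Cells with `p > alpha` are flagged as showing no change
#' (a stippling mask for map displays); cells where both periods are
#' constant and identical carry no evidence of change and are also
#' flagged.
#'
#' @param reference,end Member x cell matrices of period-mean values
#'   (one row per ensemble member).
#' @param alpha Significance level.
#' @return A `fire_change_test` tibble with `cell`, `mean_reference`,
#'   `mean_end`, `statistic`, `p_value`, `no_change`.
#' @export
ensemble_change_test <- function(reference, end, alpha = 0.05) {
  reference <- as.matrix(reference)
  end <- as.matrix(end)
  if (ncol(reference) != ncol(end)) {
    abort("`reference` and `end` must have the same number of cells.")
  }
  if (nrow(reference) < 2 || nrow(end) < 2) {
    abort("At least 2 ensemble members are required per period.")
  }
  nc <- ncol(reference)
  stat <- p <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    tt <- tryCatch(t.test(end[, j], reference[, j]),
                   error = function(e) NULL)
    if (!is.null(tt)) {
      stat[j] <- unname(tt$statistic)
      p[j] <- tt$p.value
    }
  }
  out <- tibble(
    cell = seq_len(nc),
    mean_reference = colMeans(reference),
    mean_end = colMeans(end),
    statistic = stat,
    p_value = p,
    no_change = is.na(p) | p > alpha
  )
  class(out) <- c("fire_change_test", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Period-mean burned-area maps from a run
#'
#' Convenience extractor: per-cell means of annual burned area over the
#' first `ref_window` and last `end_window` years of a run, for use with
#' [ensemble_change_test()].
#'
#' @param run A `fire_run`.
#' @param ref_window,end_window Window lengths in years.
#' @param what `"ba"` (burned area, km2) or `"co2"` (kg).
#' @return A list with numeric vectors `reference` and `end` (per cell).
#' @export
period_means <- function(run, ref_window = 11, end_window = 11,
                         what = c("ba", "co2")) {
  what <- match.arg(what)
  m <- if (what == "ba") run$ba_cell_year else run$co2_cell_year
  ny <- nrow(m)
  if (ny < ref_window + end_window) {
    abort("Run is shorter than the reference plus end windows.")
  }
  list(reference = colMeans(m[seq_len(ref_window), , drop = FALSE]),
       end = colMeans(m[seq.int(ny - end_window + 1, ny), , drop = FALSE]))
}

#' Partition projection variance across two factors
#'
#' ANOVA-style sum-of-squares split of an outcome over a run matrix
#' crossing two factors (e.g., climate model by lightning scenario):
#' main-effect shares for each factor plus an interaction/residual share.
#'
#' @param data Data frame with the outcome and two factor columns.
#' @param outcome Name of the outcome column.
#' @param factors Character vector of the two factor column names.
#' @return A tibble with `term` and `share` (fractions of total sum of
#'   squares, summing to 1).
#' @export
partition_uncertainty <- function(data, outcome, factors) {
  if (length(factors) != 2L) abort("`factors` must name exactly two columns.")
  check_cols(data, c(outcome, factors), "data")
  df <- data.frame(y = data[[outcome]],
                   a = factor(data[[factors[1]]]),
                   b = factor(data[[factors[2]]]))
  fit <- stats::aov(y ~ a + b + a:b, data = df)
  tab <- summary(fit)[[1]]
  labels <- trimws(rownames(tab))
  term <- dplyr::recode(labels, a = factors[1], b = factors[2],
                        `a:b` = "interaction", Residuals = "residual")
  tibble(term = term, share = tab[, "Sum Sq"] / sum(tab[, "Sum Sq"]))
}
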