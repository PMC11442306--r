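# File formats and run manifests.  Gridded forcing and outputs are
# exchanged as long-format CSV tables (one row per cell-day or
# cell-year) with an explicit variable map and unit converters;
# configuration is YAML; manifests are JSON with per-file checksums.

UNIT_CONVERTERS <- list(
  tmax_c = list(native = c("degC", "C", "celsius"),
                K = function(x) x - 273.15),
  rh_pct = list(native = c("%", "percent"),
                fraction = function(x) 100 * x,
                `1` = function(x) 100 * x),
  wind_kmh = list(native = c("km/h", "km h-1"),
                  `m/s` = function(x) 3.6 * x,
                  `m s-1` = function(x) 3.6 * x),
  rain_mm = list(native = c("mm", "mm/day", "mm day-1"),
                 `kg m-2 s-1` = function(x) 86400 * x),
  lightning_km2_day = list(native = c("km-2 day-1", "strikes km-2 day-1"),
                           `km-2 yr-1` = function(x) x / 365.25)
)

FORCING_VARS <- c("tmax_c", "rh_pct", "wind_kmh", "rain_mm",
                  "lightning_km2_day")

convert_units <- function(x, var, unit) {
  conv <- UNIT_CONVERTERS[[var]]
  if (is.null(unit) || unit %in% conv$native) return(x)
  f <- conv[[unit]]
  if (is.null(f)) {
    abort(sprintf("No unit converter from '%s' for variable `%s`.",
                  unit, var))
  }
  f(x)
}

#' Read a daily gridded forcing table
#'
#' Reads a long-format CSV with one row per cell-day.  Source column
#' names are translated through `var_map` (e.g., CF-style `tasmax` ->
#' `tmax_c`), units are converted to the module-internal conventions
#' (degC, %, km/h, mm/day, strikes km-2 day-1), and rows are normalized
#' to (cell, day) order regardless of how the file is sorted.
#'
#' @param path CSV file with columns `cell`, `day` (or `date`), and the
#'   forcing variables.
#' @param var_map Named character vector mapping internal names to
#'   source column names, e.g. `c(tmax_c = "tasmax")`.
#' @param units Named character vector of source units by internal name,
#'   e.g. `c(tmax_c = "K", wind_kmh = "m/s")`.  Unmapped variables are
#'   assumed to be in native units.
#' @return A tibble ordered by cell then day with the internal variable
#'   names, plus `month` when a `date` or `doy` column is available.
#' @export
read_forcing_csv <- function(path, var_map = NULL, units = NULL) {
  raw <- as_tibble(read.csv(path, check.names = FALSE))
  for (nm in names(var_map)) {
    src <- var_map[[nm]]
    if (!src %in% names(raw)) {
      abort(sprintf("Forcing file lacks mapped column `%s` (for `%s`).",
                    src, nm))
    }
    raw[[nm]] <- raw[[src]]
    if (!nm %in% var_map[[nm]]) raw[[src]] <- NULL
  }
  check_cols(raw, c("cell", "day", FORCING_VARS), "forcing file")
  for (v in FORCING_VARS) {
    raw[[v]] <- convert_units(raw[[v]], v, units[[v]])
  }
  check_range(raw$rh_pct, 0, 100, "rh_pct")
  check_nonneg(raw$rain_mm, "rain_mm")
  arrange(raw, .data$cell, .data$day)
}

#' Write a forcing object to CSV
#'
#' Long-format companion to [read_forcing_csv()]: one row per cell-day
#' in native units.  Round-trips exactly (to numeric print precision).
#'
#' @param forcing A `fire_forcing` object.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_forcing_csv <- function(forcing, path) {
  tbl <- forcing_tbl(forcing) %>%
    select("cell", "day", "year", "month", "doy", all_of(FORCING_VARS))
  write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' Write simulation outputs with a manifest
#'
#' Writes the annual domain-wide diagnostics, per-cell annual burned
#' area (km2) and fire CO2 (kg) in long format, the cell table, the
#' scenario configuration (YAML), and a JSON manifest recording the
#' seed, a configuration checksum, timestamps, and an md5 checksum for
#' every output file.  Burned area is carried in km2 with an Mha
#' aggregate column (1 Mha = 1e4 km2); emissions in kg with a Pg
#' aggregate (1 Pg = 1e12 kg).
#'
#' @param run A `fire_run` object.
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(run, dir) {
  if (!inherits(run, "fire_run")) abort("`run` must be a `fire_run`.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  years <- run$annual$year
  long <- function(m, value_name) {
    tibble(
      year = rep(years, times = ncol(m)),
      cell = rep(seq_len(ncol(m)), each = length(years)),
      value = as.vector(m)
    ) %>% rename(!!value_name := "value")
  }
  files <- list(
    "annual.csv" = run$annual,
    "cell_year_burned_area.csv" = long(run$ba_cell_year, "burned_area_km2"),
    "cell_year_co2.csv" = long(run$co2_cell_year, "co2_kg"),
    "cells.csv" = run$cells
  )
  for (nm in names(files)) {
    write.csv(files[[nm]], file.path(dir, nm), row.names = FALSE)
  }
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- run$config
  cfg$pft <- as.list(as.data.frame(cfg$pft))
  yaml::write_yaml(cfg, cfg_path)

  out_files <- c(names(files), "config.yaml")
  checksums <- unname(tools::md5sum(file.path(dir, out_files)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("borealfire")),
    seed = run$config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    fixed_drivers = run$fixed,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameter_provenance = paste(
      "Occurrence/spread thresholds follow the published fire-module",
      "defaults; combustion fractions are synthetic placeholders",
      "(see combustion.yaml)."),
    files = purrr::map2(out_files, checksums,
                        function(f, s) list(file = f, md5 = s))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Verify a run manifest
#'
#' Recomputes the md5 checksum of every file listed in a manifest.
#'
#' @param dir Directory containing `manifest.json` and the outputs.
#' @return A tibble with `file`, `recorded`, `actual`, `ok`; errors if
#'   a listed file is missing.
#' @export
verify_manifest <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  files <- vapply(manifest$files, `[[`, character(1), "file")
  recorded <- vapply(manifest$files, `[[`, character(1), "md5")
  paths <- file.path(dir, files)
  if (!all(file.exists(paths))) {
    abort(sprintf("Missing output file(s): %s.",
                  paste(files[!file.exists(paths)], collapse = ", ")))
  }
  actual <- unname(tools::md5sum(paths))
  tibble(file = files, recorded = recorded, actual = actual,
         ok = recorded == actual)
}

#' Assemble the full configuration as one list
#'
#' Bundles the scenario, occurrence, spread, combustion, and experiment
#' settings into a single YAML-serializable structure with sections
#' `grid`, `occurrence`, `spread`, `combustion`, `scenario`,
#' `experiment`.
#'
#' @param scenario A [scenario_config()].
#' @param params A [fire_params()].
#' @param experiment List of experiment settings (windows, alpha).
#' @return A nested list.
#' @export
fire_config <- function(scenario = scenario_config(),
                        params = fire_params(),
                        experiment = list(ref_window = 11, end_window = 11,
                                          alpha = 0.05)) {
  sc <- unclass(scenario)
  sc$pft <- as.list(as.data.frame(sc$pft))
  list(
    grid = sc[c("nx", "ny", "cell_area_km2")],
    occurrence = params$occurrence,
    spread = params$spread,
    combustion = as.list(as.data.frame(params$combustion)),
    scenario = sc,
    experiment = experiment
  )
}

#' Write / read the full configuration as YAML
#'
#' @param config A list from [fire_config()].
#' @param path YAML file path.
#' @return `write_fire_config()` returns the path invisibly;
#'   `read_fire_config()` returns the configuration list with the
#'   scenario section restored to a `scenario_config`.
#' @export
write_fire_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_fire_config
#' @export
read_fire_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$scenario)) {
    sc <- cfg$scenario
    sc$pft <- as_tibble(as.data.frame(sc$pft))
    cfg$scenario <- do.call(scenario_config, sc)
  }
  cfg
}
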