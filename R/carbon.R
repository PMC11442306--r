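# Fire carbon fluxes: combustion (CO2 emission) from live vegetation,
# litter, and soil pools, and fire-related mortality transfers from live
# pools to litter, driven by the fraction of a PFT's extent that burned.

CO2_PER_C <- 44 / 12
LIVE_POOLS <- c("leaf", "stem", "root")
ALL_POOLS <- c("leaf", "stem", "root", "litter", "soil")

#' Read a combustion parameter table from YAML
#'
#' The file maps PFT -> pool -> `emission_frac` (all pools) and
#' `mortality_frac` (live pools only).  See the packaged
#' `combustion.yaml` for the expected layout; its numeric values are
#' documented synthetic placeholders, not calibrated constants.
#'
#' @param path Path to a YAML parameter file.
#' @return A tibble with columns `pft`, `pool`, `emission_frac`,
#'   `mortality_frac` (NA for litter and soil).
#' @export
read_combustion <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- purrr::imap(raw, function(pools, pft) {
    purrr::imap(pools, function(v, pool) {
      tibble(pft = pft, pool = pool,
             emission_frac = v$emission_frac,
             mortality_frac = v$mortality_frac %||% NA_real_)
    }) %>% bind_rows()
  }) %>% bind_rows()
  validate_combustion(out)
}

#' Default combustion parameter table
#'
#' Loads the packaged placeholder table (see [read_combustion()]).
#'
#' @return A tibble with columns `pft`, `pool`, `emission_frac`,
#'   `mortality_frac`.
#' @examples
#' default_combustion()
#' @export
default_combustion <- function() {
  read_combustion(system.file("extdata", "combustion.yaml",
                              package = "borealfire"))
}

validate_combustion <- function(params) {
  check_cols(params, c("pft", "pool", "emission_frac", "mortality_frac"),
             "params")
  if (any(!params$pool %in% ALL_POOLS)) {
    abort(sprintf("Unknown pool(s): %s.",
                  paste(setdiff(params$pool, ALL_POOLS), collapse = ", ")))
  }
  check_range(params$emission_frac, 0, 1, "emission_frac")
  live <- params[params$pool %in% LIVE_POOLS, ]
  if (anyNA(live$mortality_frac)) {
    abort("Live pools (leaf, stem, root) require `mortality_frac`.")
  }
  check_range(live$mortality_frac, 0, 1, "mortality_frac")
  tot <- live$emission_frac + live$mortality_frac
  if (any(tot > 1 + 1e-12)) {
    abort("emission_frac + mortality_frac must not exceed 1 for live pools.")
  }
  as_tibble(params)
}

#' Apply fire to carbon pools
#'
#' For each row (one PFT, or one cell-PFT) with pool carbon densities and
#' a burned fraction, combusts `pool * burned_fraction * emission_frac`
#' from every pool (including litter and soil), transfers
#' `pool * burned_fraction * mortality_frac` from each live pool to
#' litter, and converts emitted carbon to CO2 mass with the 44/12
#' stoichiometric factor.
#'
#' @param pools A data frame with a `pft` column and pool columns `leaf`,
#'   `stem`, `root`, `litter`, `soil` (kg C m-2).
#' @param burned_fraction Fraction of each row's PFT extent burned, in
#'   \[0, 1\] (scalar or one value per row).
#' @param params Combustion parameter table, see [default_combustion()].
#' @return A list with `fluxes` (tibble: `pft`, per-pool emitted carbon
#'   columns `emitted_<pool>` in kg C m-2, `emitted_c`, `co2_kg_m2`,
#'   `litter_transfer` in kg C m-2) and `pools` (updated pool tibble).
#' @examples
#' pools <- tibble::tibble(pft = "grass", leaf = 2, stem = 0.1, root = 0.5,
#'                         litter = 0.3, soil = 10)
#' apply_fire(pools, burned_fraction = 0.5)
#' @export
apply_fire <- function(pools, burned_fraction,
                       params = default_combustion()) {
  check_cols(pools, c("pft", ALL_POOLS), "pools")
  check_range(burned_fraction, 0, 1, "burned_fraction")
  params <- validate_combustion(params)
  pools <- as_tibble(pools)
  n <- nrow(pools)
  bf <- rep_len(burned_fraction, n)

  getpar <- function(pool, col) {
    idx <- match(paste(pools$pft, pool), paste(params$pft, params$pool))
    if (anyNA(idx)) {
      abort(sprintf("No combustion parameters for pft(s): %s (pool %s).",
                    paste(unique(pools$pft[is.na(idx)]), collapse = ", "),
                    pool))
    }
    params[[col]][idx]
  }

  out_pools <- pools
  emitted <- matrix(0, n, length(ALL_POOLS),
                    dimnames = list(NULL, ALL_POOLS))
  transfer <- numeric(n)
  for (pool in ALL_POOLS) {
    check_nonneg(pools[[pool]], pool)
    em <- pools[[pool]] * bf * getpar(pool, "emission_frac")
    emitted[, pool] <- em
    loss <- em
    if (pool %in% LIVE_POOLS) {
      mort <- pools[[pool]] * bf * getpar(pool, "mortality_frac")
      transfer <- transfer + mort
      loss <- loss + mort
    }
    out_pools[[pool]] <- pmax(pools[[pool]] - loss, 0)
  }
  out_pools$litter <- out_pools$litter + transfer

  fluxes <- tibble(
    pft = pools$pft,
    burned_fraction = bf,
    emitted_c = unname(rowSums(emitted)),
    co2_kg_m2 = unname(rowSums(emitted)) * CO2_PER_C,
    litter_transfer = unname(transfer)
  )
  for (pool in ALL_POOLS) {
    fluxes[[paste0("emitted_", pool)]] <- unname(emitted[, pool])
  }
  list(fluxes = fluxes, pools = out_pools)
}

#' Fire emission intensity
#'
#' Total CO2 emitted per unit burned area (kg CO2 m-2 of burned area), a
#' summary diagnostic of combustion completeness.
#'
#' @param total_co2_kg Total emitted CO2 (kg).
#' @param total_burned_m2 Total burned area (m2).
#' @return Intensity in kg CO2 m-2; `NA` (with a warning) when the burned
#'   area is zero or negative.
#' @examples
#' emission_intensity(5, 1)
#' @export
emission_intensity <- function(total_co2_kg, total_burned_m2) {
  check_nonneg(total_co2_kg, "total_co2_kg")
  if (total_burned_m2 <= 0) {
    warn("Zero burned area: emission intensity undefined, returning NA.")
    return(NA_real_)
  }
  total_co2_kg / total_burned_m2
}
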