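#' Registry of the daily factors driving the flux models
#'
#' The registry fixes the identity, units, group and ordering of every factor
#' (covariate) used throughout the pipeline. Distance vectors and the
#' coefficients of the R2-simulation model index into this ordering, so it is
#' built once and passed along unchanged.
#'
#' Factor groups:
#' * `meteorological` — air temperature, dew point, vapour pressure deficit,
#'   downward shortwave radiation; available in both scenarios.
#' * `remote_sensing` — fPAR, EVI, LSWI and seven surface-reflectance bands;
#'   only used in the RS scenario.
#' * `static` — terrain and soil properties, constant in time.
#'
#' @return A tibble with columns `name`, `label`, `units`, `group`
#'   (`"meteorological"`, `"remote_sensing"` or `"static"`).
#' @examples
#' factor_registry()
#' @export
factor_registry <- function() {
  tibble::tribble(
    ~name,    ~label,                          ~units,          ~group,
    "ta",     "Air temperature",               "degC",          "meteorological",
    "td",     "Dew-point temperature",         "degC",          "meteorological",
    "vpd",    "Vapour pressure deficit",       "kPa",           "meteorological",
    "dsr",    "Downward shortwave radiation",  "W m-2",         "meteorological",
    "fpar",   "Fraction of absorbed PAR",      "dimensionless", "remote_sensing",
    "evi",    "Enhanced vegetation index",     "dimensionless", "remote_sensing",
    "lswi",   "Land surface water index",      "dimensionless", "remote_sensing",
    "b1",     "Reflectance band 1",            "dimensionless", "remote_sensing",
    "b2",     "Reflectance band 2",            "dimensionless", "remote_sensing",
    "b3",     "Reflectance band 3",            "dimensionless", "remote_sensing",
    "b4",     "Reflectance band 4",            "dimensionless", "remote_sensing",
    "b5",     "Reflectance band 5",            "dimensionless", "remote_sensing",
    "b6",     "Reflectance band 6",            "dimensionless", "remote_sensing",
    "b7",     "Reflectance band 7",            "dimensionless", "remote_sensing",
    "elev",   "Elevation",                     "m",             "static",
    "slope",  "Terrain slope",                 "degrees",       "static",
    "sand",   "Soil sand fraction",            "fraction",      "static",
    "clay",   "Soil clay fraction",            "fraction",      "static"
  )
}

#' Factor names available under a modelling scenario
#'
#' The RS scenario uses every registered factor; the WRS scenario drops the
#' remote-sensing group.
#'
#' @param registry A factor registry, see [factor_registry()].
#' @param scenario `"RS"` or `"WRS"`.
#' @return Character vector of factor names in registry order.
#' @export
scenario_factors <- function(registry = factor_registry(), scenario = c("RS", "WRS")) {
  scenario <- match.arg(scenario)
  if (scenario == "WRS") {
    registry <- dplyr::filter(registry, .data$group != "remote_sensing")
  }
  registry$name
}

#' Canonical station category names
#'
#' The nine categories used to partition stations: four landscape groups, two
#' continents, two aridity classes and the all-station pool.
#'
#' @return Character vector of length 9 in canonical order.
#' @export
category_levels <- function() {
  c("Wetland", "Cropland", "Grassland", "Forest",
    "Asia", "Europe", "Arid", "NonArid", "Overall")
}

#' Quality class of a determination coefficient
#'
#' Bins an R2 value into the three dataset quality classes:
#' class 1 (low, R2 < 0.5), class 2 (moderate, 0.5 <= R2 < 0.7) and
#' class 3 (high, R2 >= 0.7). Both upper boundaries are inclusive upward.
#'
#' @param r2 Numeric vector of determination coefficients. Values above 1 are
#'   treated as class 3; `NA` stays `NA`.
#' @return Integer vector of classes 1, 2 or 3.
#' @examples
#' quality_class(c(0.49, 0.5, 0.69, 0.7, 1.2))
#' @export
quality_class <- function(r2) {
  out <- ifelse(r2 >= 0.7, 3L, ifelse(r2 >= 0.5, 2L, 1L))
  as.integer(out)
}
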