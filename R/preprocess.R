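#' Vapour pressure deficit from air and dew-point temperature
#'
#' Computes VPD as the difference between saturation vapour pressure at air
#' temperature and at dew-point temperature, using the FAO-56 Magnus form
#' \eqn{e_s(T) = 0.6108 \exp(17.27 T / (T + 237.3))} (kPa). When the dew point
#' exceeds the air temperature (supersaturation, usually instrument noise) the
#' deficit is clamped at zero and a warning is issued.
#'
#' @param air_temp Air temperature, degrees C. Finite, in \[-60, 60\].
#' @param dewpoint Dew-point temperature, degrees C. Finite, in \[-60, 60\].
#' @return Vapour pressure deficit in kPa, same length as the inputs.
#' @examples
#' compute_vpd(25, 15)
#' @export
compute_vpd <- function(air_temp, dewpoint) {
  if (any(!is.finite(air_temp) | !is.finite(dewpoint))) {
    abort_bad_arg("`air_temp` and `dewpoint` must be finite")
  }
  if (any(abs(air_temp) > 60) || any(abs(dewpoint) > 60)) {
    abort_bad_arg("temperatures outside [-60, 60] degC")
  }
  es <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  vpd <- es(air_temp) - es(dewpoint)
  neg <- vpd < 0
  if (any(neg)) {
    warning(sum(neg), " record(s) with dew point above air temperature; VPD clamped at 0")
    vpd[neg] <- 0
  }
  vpd
}

#' Convert daily-mean latent heat flux to water flux
#'
#' Converts a daily mean latent heat flux density (W m-2) to an equivalent
#' water flux (mm d-1) via the daily energy total and the conversion factor
#' 0.408e-6 mm per J m-2 (the reciprocal of the latent heat of vaporisation,
#' about 2.45 MJ kg-1): `wf = le * 86400 * 0.408e-6`. Negative fluxes
#' (condensation) are preserved.
#'
#' @param le_daily_mean Daily-mean latent heat flux, W m-2. Finite.
#' @return Water flux in mm d-1.
#' @examples
#' le_to_wf(100) # 3.52512
#' @export
le_to_wf <- function(le_daily_mean) {
  if (any(!is.finite(le_daily_mean))) abort_bad_arg("`le_daily_mean` must be finite")
  le_daily_mean * 86400 * 0.408e-6
}

#' Mask flux values that fail quality control
#'
#' Sets `nee` to missing where `qc_nee < threshold` and `wf` to missing where
#' `qc_le < threshold`; the threshold is inclusive (a flag exactly equal to the
#' threshold passes). Records without a QC flag pass unchanged, and covariates
#' are never touched.
#'
#' @param records Daily records with optional `qc_nee`, `qc_le`, `nee`, `wf`
#'   columns.
#' @param threshold QC threshold in \[0, 1\]; default 0.8.
#' @return The records tibble with failing flux values set to `NA`. The number
#'   of masked values is attached as attribute `"n_masked"`.
#' @export
qc_filter <- function(records, threshold = 0.8) {
  if (threshold < 0 || threshold > 1) abort_bad_arg("`threshold` must be in [0, 1]")
  records <- tibble::as_tibble(records)
  n_masked <- 0L
  mask_one <- function(flux, qc) {
    bad <- !is.na(records[[qc]]) & records[[qc]] < threshold & !is.na(records[[flux]])
    n_masked <<- n_masked + sum(bad)
    records[[flux]][bad] <<- NA_real_
  }
  if (all(c("qc_nee", "nee") %in% names(records))) mask_one("nee", "qc_nee")
  if (all(c("qc_le", "wf") %in% names(records))) mask_one("wf", "qc_le")
  attr(records, "n_masked") <- n_masked
  records
}

#' Gap-limited linear interpolation of a daily series
#'
#' Fills interior runs of missing values of length `<= max_gap` by linear
#' interpolation between the flanking observations. Longer runs and runs
#' touching either end of the series are left missing. Observed values are
#' never altered. With the default `max_gap = 7` this implements the rule of
#' interpolating only gaps of fewer than 8 consecutive missing days.
#'
#' @param series Numeric vector, one value per consecutive day (may contain
#'   `NA`).
#' @param max_gap Longest run of missing days that is filled; default 7.
#' @return The series with eligible gaps filled.
#' @examples
#' interpolate_rs(c(1, rep(NA, 7), 9)) # filled 2..8
#' interpolate_rs(c(1, rep(NA, 8), 10)) # left missing
#' @export
interpolate_rs <- function(series, max_gap = 7) {
  if (max_gap < 1) abort_bad_arg("`max_gap` must be >= 1")
  if (all(is.na(series))) return(series)
  zoo::na.approx(series, maxgap = max_gap, na.rm = FALSE)
}

#' Apply the full record-level preprocessing to a daily table
#'
#' Runs, in order: VPD derivation from `ta`/`td` (rows where both are present),
#' QC masking of fluxes at `qc_threshold`, and gap-limited linear interpolation
#' of each remote-sensing factor within each station. Idempotent: a second
#' application leaves the table unchanged.
#'
#' @param records Daily records in the network schema (see
#'   [generate_network()]).
#' @param registry Factor registry; remote-sensing group members are the
#'   interpolated columns.
#' @param qc_threshold QC threshold passed to [qc_filter()].
#' @param max_gap Interpolation gap limit passed to [interpolate_rs()].
#' @return Preprocessed records tibble, with attribute `"preprocess_log"`
#'   (counts of derived, masked and filled values).
#' @export
preprocess_records <- function(records, registry = factor_registry(),
                               qc_threshold = 0.8, max_gap = 7) {
  records <- tibble::as_tibble(records)
  n_vpd <- 0L
  if (all(c("ta", "td") %in% names(records))) {
    ok <- !is.na(records$ta) & !is.na(records$td)
    if (!"vpd" %in% names(records)) records$vpd <- NA_real_
    if (any(ok)) {
      records$vpd[ok] <- compute_vpd(records$ta[ok], records$td[ok])
      n_vpd <- sum(ok)
    }
  }
  records <- qc_filter(records, qc_threshold)
  n_masked <- attr(records, "n_masked")
  rs_cols <- intersect(registry$name[registry$group == "remote_sensing"], names(records))
  n_filled <- 0L
  if (length(rs_cols)) {
    records <- records |>
      dplyr::arrange(.data$station_id, .data$year, .data$doy) |>
      dplyr::group_by(.data$station_id) |>
      dplyr::mutate(dplyr::across(dplyr::all_of(rs_cols), \(x) {
        filled <- interpolate_rs(x, max_gap = max_gap)
        n_filled <<- n_filled + sum(is.na(x) & !is.na(filled))
        filled
      })) |>
      dplyr::ungroup()
  }
  attr(records, "preprocess_log") <-
    list(vpd_derived = n_vpd, flux_masked = n_masked, rs_filled = n_filled)
  records
}
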