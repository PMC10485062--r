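#' Configuration for a synthetic station network
#'
#' Bundles and validates every knob of the synthetic network generator. The
#' defaults describe a moderately heterogeneous Eurasian-style network: daily
#' covariates follow seasonal harmonics with first-order autocorrelated noise,
#' fluxes are generated from a known covariate-driven truth with station-level
#' parameter heterogeneity, and stations carry landscape / continent / aridity
#' labels drawn from `category_mix`.
#'
#' @param n_flux_stations Number of eddy-covariance flux stations (>= 1).
#' @param n_met_stations Number of meteorological stations (>= 1).
#' @param years Integer vector of calendar years to simulate (non-empty).
#' @param category_mix Tibble with columns `landscape`, `continent`, `arid`
#'   (logical) and `prop`; proportions must sum to 1. Default: uniform over
#'   the 4 x 2 x 2 cells.
#' @param noise_sd_nee Daily NEE observation noise sd, g C m-2 d-1.
#' @param noise_sd_wf Daily WF observation noise sd, mm d-1.
#' @param ood_shift Climatology shift, in between-station standard deviations,
#'   applied to met stations flagged out-of-distribution.
#' @param ood_frac_met Fraction of met stations flagged out-of-distribution.
#' @param missing_rate Target fraction of missing remote-sensing factor values
#'   in \[0, 1).
#' @param max_gap_days Maximum length of an injected missing run (days).
#' @param long_gap_frac Fraction of injected gaps allowed to exceed
#'   `max_gap_days` (up to three times its length); 0 disables long gaps.
#' @param heterogeneity Log-scale sd of station-level response parameters
#'   around their climate-gradient expectation.
#' @param seed Integer seed; the same seed reproduces the network exactly.
#' @return A `network_config` list.
#' @export
network_config <- function(n_flux_stations = 30,
                           n_met_stations = 20,
                           years = 2018:2020,
                           category_mix = NULL,
                           noise_sd_nee = 0.4,
                           noise_sd_wf = 0.15,
                           ood_shift = 0,
                           ood_frac_met = 0,
                           missing_rate = 0.05,
                           max_gap_days = 7,
                           long_gap_frac = 0,
                           heterogeneity = 0.04,
                           seed = 1L) {
  if (is.null(category_mix)) {
    category_mix <- tidyr::expand_grid(
      landscape = c("Wetland", "Cropland", "Grassland", "Forest"),
      continent = c("Asia", "Europe"),
      arid = c(TRUE, FALSE)
    )
    category_mix$prop <- 1 / nrow(category_mix)
  }
  stopifnot(all(c("landscape", "continent", "arid", "prop") %in% names(category_mix)))
  if (abs(sum(category_mix$prop) - 1) > 1e-9) {
    abort_bad_arg("`category_mix$prop` must sum to 1")
  }
  if (length(years) == 0) abort_bad_arg("`years` must be non-empty")
  if (n_flux_stations < 1 || n_met_stations < 1) abort_bad_arg("station counts must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1) abort_bad_arg("`missing_rate` must be in [0, 1)")
  if (max_gap_days < 1) abort_bad_arg("`max_gap_days` must be >= 1")
  structure(
    list(
      n_flux_stations = as.integer(n_flux_stations),
      n_met_stations = as.integer(n_met_stations),
      years = sort(as.integer(years)),
      category_mix = tibble::as_tibble(category_mix),
      noise_sd_nee = noise_sd_nee,
      noise_sd_wf = noise_sd_wf,
      ood_shift = ood_shift,
      ood_frac_met = ood_frac_met,
      missing_rate = missing_rate,
      max_gap_days = as.integer(max_gap_days),
      long_gap_frac = long_gap_frac,
      heterogeneity = heterogeneity,
      seed = as.integer(seed)
    ),
    class = "network_config"
  )
}

# largest-remainder allocation of n stations to category cells
allocate_cells <- function(n, mix) {
  raw <- n * mix$prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  rep(seq_len(nrow(mix)), times = base)
}

igbp_within_group <- list(
  Wetland   = "permanent wetlands",
  Cropland  = c("croplands", "cropland/natural vegetation mosaics"),
  Grassland = c("grasslands", "savannas", "woody savannas"),
  Forest    = c("evergreen needleleaf forests", "evergreen broadleaf forests",
                "deciduous needleleaf forests", "deciduous broadleaf forests",
                "mixed forests")
)

# per-landscape bases for the flux-generating truth
landscape_base <- tibble::tribble(
  ~landscape,  ~gpp_base, ~r0_base, ~f_base, ~elev_lo, ~elev_hi,
  "Wetland",   12.6,      1.5,      0.42,    0,        300,
  "Cropland",  13.5,      1.6,      0.45,    50,       600,
  "Grassland", 10.5,      1.25,     0.35,    300,      1500,
  "Forest",    16.5,      2.0,      0.55,    100,      1200
)

# draw station metadata + latent parameters; `u` is the station's position on
# the within-category climate gradient (sd 1); OOD stations get u += ood_shift
draw_station <- function(id, role, cell, cfg, ood) {
  ls <- cell$landscape
  base <- landscape_base[landscape_base$landscape == ls, ]
  u <- rnorm(1)
  # an OOD station is displaced in either direction along the climate axes
  shift <- if (ood) cfg$ood_shift * sample(c(-1, 1), 1) else 0
  # every covariate family follows the shared climate gradient, so an OOD
  # station is displaced along the axis the in-distribution stations span;
  # per-factor idiosyncratic draws below keep the factors from being redundant
  g <- u + shift
  # response gradient: strongly coupled to the observable climate gradient,
  # with an unobservable share that no flux model can absorb from covariates
  # alone -- transfer skill therefore decays with climate distance
  v <- 0.85 * (u + shift) + sqrt(1 - 0.85^2) * rnorm(1)
  arid <- cell$arid
  het <- cfg$heterogeneity
  ta_mean <- 8 + (cell$continent == "Asia") * 2 + arid * 3 +
    c(Wetland = -1, Cropland = 1, Grassland = 1, Forest = 0)[[ls]] +
    2.5 * g + rnorm(1, 0, 0.5)
  tibble::tibble(
    station_id = id,
    name = paste0("synthetic-", id),
    lon = if (cell$continent == "Europe") runif(1, -10, 40) else runif(1, 60, 140),
    lat = if (cell$continent == "Europe") runif(1, 38, 62) else runif(1, 20, 55),
    continent = cell$continent,
    aridity_index = if (arid) runif(1, 0.15, 0.60) else runif(1, 0.65, 1.8),
    igbp = sample(igbp_within_group[[ls]], 1),
    role = role,
    ood = ood,
    u = u,
    v = v,
    ta_mean = ta_mean,
    ta_amp = 10 + rnorm(1, 0, 1),
    dep = pmax(0.8, (if (arid) 6 else 3) + 0.8 * g + rnorm(1, 0, 0.3)),
    dsr_mean = 170 + 10 * g + rnorm(1, 0, 5),
    dsr_amp = 90 + rnorm(1, 0, 5),
    f_base = clamp(base$f_base - arid * 0.10 + 0.05 * g + rnorm(1, 0, 0.02), 0.1, 0.85),
    f_amp = 0.25 + rnorm(1, 0, 0.02),
    gppmax = base$gpp_base * (1 + 0.05 * v) * exp(rnorm(1, 0, het)),
    r0 = base$r0_base * (1 + 0.05 * v) * exp(rnorm(1, 0, het)),
    q10 = clamp(2 + 0.05 * v + rnorm(1, 0, 0.05), 1.3, 3.5),
    k_i = 120 + rnorm(1, 0, 5),
    k_v = 0.12 + rnorm(1, 0, 0.01),
    c_r = 1.6e-2 * (1 + 0.3 * v) * exp(rnorm(1, 0, het)),
    c_v = pmax(0.05, 0.70 * (1 - 0.6 * v)) * exp(rnorm(1, 0, het)),
    elev = runif(1, base$elev_lo, base$elev_hi),
    slope = runif(1, 0, 15),
    sand = if (arid) runif(1, 0.5, 0.8) else runif(1, 0.2, 0.5),
    clay = runif(1, 0.10, 0.35)
  )
}

# reflectance bands as linear transforms of EVI/LSWI plus independent noise
band_coefs <- tibble::tribble(
  ~band, ~int,  ~c_evi, ~c_lswi, ~sd,
  "b1",  0.35,  -0.25,   0.00,   0.02,
  "b2",  0.25,   0.35,   0.05,   0.02,
  "b3",  0.30,  -0.20,  -0.05,   0.02,
  "b4",  0.32,  -0.22,   0.02,   0.02,
  "b5",  0.40,   0.10,  -0.20,   0.02,
  "b6",  0.35,   0.05,  -0.25,   0.02,
  "b7",  0.30,  -0.05,  -0.20,   0.02
)

# one station's daily table over the configured years
simulate_station_days <- function(st, cfg) {
  dates <- seq(as.Date(paste0(min(cfg$years), "-01-01")),
               as.Date(paste0(max(cfg$years), "-12-31")), by = "day")
  dates <- dates[as.integer(format(dates, "%Y")) %in% cfg$years]
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  s <- cos(2 * pi * (doy - 200) / 365.25)

  ta <- st$ta_mean + st$ta_amp * s + ar1_noise(n, 2, 0.7)
  td <- ta - pmax(0.2, st$dep + ar1_noise(n, 1.2, 0.5))
  vpd <- compute_vpd(ta, td)
  dsr <- pmax(20, st$dsr_mean + st$dsr_amp * s + ar1_noise(n, 25, 0.5))
  fpar <- clamp(st$f_base + st$f_amp * s + ar1_noise(n, 0.04, 0.8), 0.02, 0.98)
  evi <- clamp(0.05 + 0.85 * fpar + ar1_noise(n, 0.03, 0.6), 0, 1)
  lswi <- clamp(0.10 + 0.50 * fpar - 0.15 * vpd / (1 + vpd) + ar1_noise(n, 0.04, 0.6), -0.2, 1)
  bands <- purrr::map(seq_len(nrow(band_coefs)), function(i) {
    bc <- band_coefs[i, ]
    clamp(bc$int + bc$c_evi * evi + bc$c_lswi * lswi + rnorm(n, 0, bc$sd), 0, 1)
  })
  names(bands) <- band_coefs$band

  rec <- tibble::tibble(
    station_id = st$station_id,
    year = as.integer(format(dates, "%Y")),
    month = as.integer(format(dates, "%m")),
    day = as.integer(format(dates, "%d")),
    doy = doy,
    ta = ta, td = td, vpd = vpd, dsr = dsr,
    fpar = fpar, evi = evi, lswi = lswi
  )
  rec <- dplyr::bind_cols(rec, tibble::as_tibble(bands))
  rec$elev <- st$elev
  rec$slope <- st$slope
  rec$sand <- st$sand
  rec$clay <- st$clay

  if (st$role == "flux") {
    gpp <- st$gppmax * dsr / (dsr + st$k_i) * fpar * exp(-st$k_v * vpd)
    resp <- st$r0 * st$q10^((ta - 10) / 10)
    nee_sig <- -gpp + resp
    wf_sig <- st$c_r * dsr * fpar + st$c_v * vpd
    rec$qc_nee <- sample(c(1, 0.9, 0.7, 0.4), n, replace = TRUE,
                         prob = c(0.60, 0.25, 0.10, 0.05))
    rec$qc_le <- sample(c(1, 0.9, 0.7, 0.4), n, replace = TRUE,
                        prob = c(0.60, 0.25, 0.10, 0.05))
    # eddy-covariance random error scales with flux magnitude: the configured
    # sd is nominal for a station of reference variability (sd 2 g C / 0.8 mm)
    rec$nee <- nee_sig + rnorm(n, 0, cfg$noise_sd_nee * sd(nee_sig) / 2.0)
    rec$wf <- pmax(0, wf_sig + rnorm(n, 0, cfg$noise_sd_wf * sd(wf_sig) / 0.8))
  } else {
    rec$qc_nee <- NA_real_
    rec$qc_le <- NA_real_
    rec$nee <- NA_real_
    rec$wf <- NA_real_
  }
  rec
}

#' Generate a synthetic flux- and meteorological-station network
#'
#' Draws station metadata and latent response parameters from
#' category-conditional distributions (so stations within a category resemble
#' each other more than stations across categories), simulates daily covariates
#' as seasonal harmonics plus AR(1) noise, and generates fluxes at flux
#' stations from a known truth:
#' \deqn{NEE = -GPP_{max} \frac{DSR}{DSR + k_I} fPAR\, e^{-k_V VPD}
#'       + R_0 Q_{10}^{(T_a - 10)/10} + \epsilon}
#' \deqn{WF = \max(0,\; c_R\, DSR\, fPAR + c_V\, VPD + \epsilon)}
#' Station response parameters drift along a within-category climate gradient
#' `u`, so stations with similar covariate climatologies also have similar flux
#' responses — the coupling that makes transfer distance informative.
#' Met stations flagged out-of-distribution have `u` shifted by
#' `ood_shift` standard deviations. Missing runs are injected into the
#' remote-sensing factors per `missing_rate` / `max_gap_days`
#' (see [inject_missing()]). Leap days (DOY 366) are generated.
#'
#' Identical configurations (including seed) produce identical networks.
#'
#' @param config A [network_config()].
#' @return A `flux_network` list with elements `meta` (station metadata),
#'   `records` (daily table: station_id, date parts, one column per registered
#'   factor, qc flags, `nee`, `wf` — fluxes `NA` at met stations), `truth`
#'   (per-station latent parameters) and `config`.
#' @export
generate_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  mix <- config$category_mix
  cells_flux <- allocate_cells(config$n_flux_stations, mix)
  cells_met <- allocate_cells(config$n_met_stations, mix)
  n_ood <- round(config$ood_frac_met * config$n_met_stations)
  ood_met <- c(rep(FALSE, config$n_met_stations - n_ood), rep(TRUE, n_ood))

  stations <- dplyr::bind_rows(
    purrr::map(seq_along(cells_flux), function(i) {
      draw_station(sprintf("FS%03d", i), "flux", mix[cells_flux[i], ], config, FALSE)
    }),
    purrr::map(seq_along(cells_met), function(i) {
      draw_station(sprintf("MS%03d", i), "met", mix[cells_met[i], ], config, ood_met[i])
    })
  )

  day_seeds <- derive_seeds(config$seed, nrow(stations), salt = 17L)
  records <- purrr::map(seq_len(nrow(stations)), function(i) {
    set.seed(day_seeds[i])
    simulate_station_days(stations[i, ], config)
  }) |> dplyr::bind_rows()

  if (config$missing_rate > 0) {
    records <- inject_missing(records,
      missing_rate = config$missing_rate,
      max_gap_days = config$max_gap_days,
      seed = derive_seeds(config$seed, 1, salt = 91L),
      long_gap_frac = config$long_gap_frac
    )
  }

  meta_cols <- c("station_id", "name", "lon", "lat", "elev", "continent",
                 "aridity_index", "igbp", "role", "ood")
  truth_cols <- c("station_id", "role", "u", "v", "gppmax", "r0", "q10", "k_i", "k_v",
                  "c_r", "c_v", "ta_mean", "ta_amp", "dep", "dsr_mean",
                  "dsr_amp", "f_base", "f_amp")
  structure(
    list(
      meta = dplyr::rename(stations[meta_cols], elevation = "elev"),
      records = records,
      truth = stations[truth_cols],
      config = config
    ),
    class = "flux_network"
  )
}

#' @export
print.flux_network <- function(x, ...) {
  cat("<flux_network> ", sum(x$meta$role == "flux"), " flux + ",
      sum(x$meta$role == "met"), " met stations, years ",
      paste(range(x$config$years), collapse = "-"), ", ",
      nrow(x$records), " station-days\n", sep = "")
  invisible(x)
}

#' Inject bounded runs of missing values into remote-sensing factors
#'
#' Removes approximately `missing_rate` of each remote-sensing factor series
#' at each station, as runs of consecutive days no longer than `max_gap_days`
#' (unless `long_gap_frac > 0`, in which case that fraction of runs may extend
#' to three times the limit). Runs are separated by at least one observed day
#' so they never merge into longer gaps. Flux values and non-RS covariates are
#' never removed.
#'
#' @param records Daily records (network schema).
#' @param missing_rate Target missing fraction in \[0, 1).
#' @param max_gap_days Maximum run length in days.
#' @param seed Integer seed.
#' @param long_gap_frac Fraction of runs allowed to exceed `max_gap_days`.
#' @param registry Factor registry; its remote-sensing group defines the
#'   affected columns.
#' @return Records with `NA` gaps injected.
#' @export
inject_missing <- function(records, missing_rate, max_gap_days = 7, seed = 1L,
                           long_gap_frac = 0, registry = factor_registry()) {
  if (missing_rate < 0 || missing_rate >= 1) abort_bad_arg("`missing_rate` must be in [0, 1)")
  records <- tibble::as_tibble(records)
  if (missing_rate == 0) return(records)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  rs_cols <- intersect(registry$name[registry$group == "remote_sensing"], names(records))
  records <- dplyr::arrange(records, .data$station_id, .data$year, .data$doy)
  idx_by_station <- split(seq_len(nrow(records)), records$station_id)

  for (rows in idx_by_station) {
    len <- length(rows)
    for (col in rs_cols) {
      miss <- place_missing_runs(len, missing_rate, max_gap_days, long_gap_frac)
      if (any(miss)) records[rows[miss], col] <- NA_real_
    }
  }
  records
}

# place runs of missing days totalling round(rate*len), each run <= max_gap
# (or up to 3*max_gap for a long_gap_frac share), separated by >= 1 observed day
place_missing_runs <- function(len, rate, max_gap, long_gap_frac = 0) {
  target <- round(rate * len)
  miss <- logical(len)
  placed <- 0L
  while (placed < target) {
    remaining <- target - placed
    long <- long_gap_frac > 0 && remaining > max_gap && runif(1) < long_gap_frac
    L <- if (long) {
      sample(seq(max_gap + 1, min(3 * max_gap, remaining)), 1)
    } else {
      sample.int(min(max_gap, remaining), 1)
    }
    repeat {
      cs0 <- c(0, cumsum(miss))
      starts <- seq_len(len - L + 1)
      a <- pmax(starts - 1, 1)
      b <- pmin(starts + L, len)
      valid <- which(cs0[b + 1] - cs0[a] == 0)
      if (length(valid)) {
        s <- valid[sample.int(length(valid), 1)]
        miss[s:(s + L - 1)] <- TRUE
        placed <- placed + L
        break
      }
      L <- L - 1L
      if (L < 1L) return(miss)
    }
  }
  miss
}

#' Noise-free fluxes implied by a station's latent truth
#'
#' Recomputes the closed-form NEE and WF truth from the emitted covariates and
#' the latent per-station parameters — useful as a quasi-observation benchmark
#' at met stations, where no flux was emitted.
#'
#' @param records Daily records containing `ta`, `vpd`, `dsr`, `fpar`.
#' @param truth The `truth` table of a [generate_network()] result.
#' @return `records` with added `nee_true` and `wf_true` columns.
#' @export
latent_fluxes <- function(records, truth) {
  records |>
    dplyr::inner_join(
      truth[, c("station_id", "gppmax", "r0", "q10", "k_i", "k_v", "c_r", "c_v")],
      by = "station_id"
    ) |>
    dplyr::mutate(
      nee_true = -.data$gppmax * .data$dsr / (.data$dsr + .data$k_i) * .data$fpar *
        exp(-.data$k_v * .data$vpd) +
        .data$r0 * .data$q10^((.data$ta - 10) / 10),
      wf_true = pmax(0, .data$c_r * .data$dsr * .data$fpar + .data$c_v * .data$vpd)
    ) |>
    dplyr::select(-dplyr::all_of(c("gppmax", "r0", "q10", "k_i", "k_v", "c_r", "c_v")))
}

#' Write a synthetic network to disk as plain CSV
#'
#' Writes one daily CSV per station (named by station id), a station-metadata
#' CSV, and the generator configuration as YAML.
#'
#' @param network A `flux_network`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, dir) {
  stopifnot(inherits(network, "flux_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta_path <- file.path(dir, "station_meta.csv")
  readr::write_csv(network$meta, meta_path)
  paths <- purrr::map_chr(split(network$records, network$records$station_id), function(df) {
    p <- file.path(dir, paste0(df$station_id[1], ".csv"))
    readr::write_csv(df, p)
    p
  })
  cfg <- network$config
  cfg$category_mix <- as.data.frame(cfg$category_mix)
  yaml::write_yaml(unclass(cfg), file.path(dir, "network_config.yml"))
  invisible(c(meta_path, paths))
}

#' Read a network generator configuration from YAML
#'
#' @param path Path to a YAML file whose keys match [network_config()]
#'   arguments.
#' @return A `network_config`.
#' @export
read_network_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$category_mix)) {
    raw$category_mix <- tibble::as_tibble(as.data.frame(raw$category_mix))
  }
  do.call(network_config, raw)
}
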