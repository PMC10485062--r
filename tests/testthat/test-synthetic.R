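test_that("every station gets one record per calendar day and roles carry the right columns", {
  net <- generate_network(network_config(n_flux_stations = 6, n_met_stations = 4,
                                         years = 2010, missing_rate = 0, seed = 1))
  expect_equal(nrow(net$records), 10 * 365)
  counts <- table(net$records$station_id)
  expect_true(all(counts == 365))
  flux <- dplyr::filter(net$records, startsWith(station_id, "FS"))
  met <- dplyr::filter(net$records, startsWith(station_id, "MS"))
  expect_true(all(!is.na(flux$nee)) && all(!is.na(flux$wf)))
  expect_true(all(is.na(met$nee)) && all(is.na(met$wf)))
  # leap day generated when the year has one
  leap <- generate_network(network_config(n_flux_stations = 1, n_met_stations = 1,
                                          years = 2020, missing_rate = 0, seed = 1))
  expect_equal(max(leap$records$doy), 366)
  expect_equal(nrow(leap$records), 2 * 366)
})

test_that("identical configurations reproduce byte-identical networks, different seeds differ", {
  cfg <- network_config(n_flux_stations = 3, n_met_stations = 2, years = 2019,
                        missing_rate = 0.05, seed = 42)
  a <- generate_network(cfg)
  b <- generate_network(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$meta, b$meta)
  c <- generate_network(network_config(n_flux_stations = 3, n_met_stations = 2,
                                       years = 2019, missing_rate = 0.05, seed = 43))
  expect_false(identical(a$records$ta, c$records$ta))
})

test_that("with zero noise the emitted fluxes equal the closed-form truth of the emitted covariates", {
  net <- generate_network(network_config(n_flux_stations = 4, n_met_stations = 1,
                                         years = 2019, noise_sd_nee = 0, noise_sd_wf = 0,
                                         missing_rate = 0, seed = 7))
  rec <- latent_fluxes(net$records, net$truth)
  flux <- dplyr::filter(rec, startsWith(station_id, "FS"))
  expect_equal(flux$nee, flux$nee_true, tolerance = 1e-12)
  expect_equal(flux$wf, flux$wf_true, tolerance = 1e-12)
})

test_that("a noiseless per-station nonlinear fit recovers the light-response and respiration parameters", {
  skip_if_not_installed("minpack.lm")
  net <- generate_network(network_config(n_flux_stations = 4, n_met_stations = 1,
                                         years = 2018:2019, noise_sd_nee = 0,
                                         noise_sd_wf = 0, missing_rate = 0, seed = 11))
  for (st in net$meta$station_id[net$meta$role == "flux"]) {
    d <- dplyr::filter(net$records, station_id == st)
    tr <- dplyr::filter(net$truth, station_id == st)
    fit <- minpack.lm::nlsLM(
      nee ~ -g * dsr / (dsr + ki) * fpar * exp(-kv * vpd) + r0 * q10^((ta - 10) / 10),
      data = d, start = list(g = 12, ki = 100, kv = 0.15, r0 = 1.5, q10 = 2)
    )
    cf <- coef(fit)
    expect_lt(abs(cf[["g"]] - tr$gppmax) / tr$gppmax, 0.01)
    expect_lt(abs(cf[["r0"]] - tr$r0) / tr$r0, 0.01)
  }
})

test_that("injected missingness hits the target rate, respects the gap cap and spares fluxes", {
  net <- generate_network(network_config(n_flux_stations = 1, n_met_stations = 1,
                                         years = 2010:2019, missing_rate = 0, seed = 5))
  rec <- inject_missing(net$records, missing_rate = 0.1, max_gap_days = 7, seed = 9)
  for (st in unique(rec$station_id)) {
    x <- rec$fpar[rec$station_id == st]
    expect_equal(mean(is.na(x)), 0.1, tolerance = 0.02)
    runs <- rle(is.na(x))
    expect_lte(max(runs$lengths[runs$values]), 7)
  }
  expect_identical(rec$nee, net$records$nee)
  expect_identical(rec$ta, net$records$ta)
  # rate zero leaves records untouched
  expect_identical(inject_missing(net$records, 0), net$records)
})

test_that("out-of-distribution met stations are farther from the flux pool than in-distribution ones", {
  wins <- 0
  for (sd in 1:20) {
    net <- generate_network(network_config(
      n_flux_stations = 12, n_met_stations = 16, years = 2018:2019,
      ood_shift = 2, ood_frac_met = 0.5, missing_rate = 0, seed = 400 + sd
    ))
    clim <- doy_climatology(net$records)
    flux_ids <- net$meta$station_id[net$meta$role == "flux"]
    met <- net$meta[net$meta$role == "met", ]
    dmats <- distance_matrices(clim, met$station_id, flux_ids, t_min = 30)
    dv <- as.matrix(distance_vectors_from_matrices(dmats, met$station_id, flux_ids)[, -1])
    md <- rowMeans(scale(dv))
    wins <- wins + (mean(md[met$ood]) > mean(md[!met$ood]))
  }
  expect_gte(wins, 19)
})

test_that("network CSV round trip preserves the daily table and config", {
  net <- generate_network(network_config(n_flux_stations = 2, n_met_stations = 1,
                                         years = 2019, missing_rate = 0, seed = 3))
  dir <- withr::local_tempdir()
  write_network(net, dir)
  expect_true(file.exists(file.path(dir, "station_meta.csv")))
  expect_true(file.exists(file.path(dir, "FS001.csv")))
  back <- readr::read_csv(file.path(dir, "FS001.csv"), show_col_types = FALSE)
  orig <- dplyr::filter(net$records, station_id == "FS001")
  expect_equal(back$ta, orig$ta, tolerance = 1e-9)
  cfg <- read_network_config(file.path(dir, "network_config.yml"))
  expect_equal(cfg$seed, net$config$seed)
  expect_equal(cfg$years, net$config$years)
})
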