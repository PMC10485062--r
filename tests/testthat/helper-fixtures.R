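# shared fixtures, built once per test run and cached

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# small clean network: 8 flux + 4 met stations, one year, no gaps
small_network <- function() {
  cached("small_network", function() {
    generate_network(network_config(
      n_flux_stations = 8, n_met_stations = 4, years = 2019,
      missing_rate = 0, seed = 301
    ))
  })
}

# its climatology (flux + met stations together)
small_clim <- function() {
  cached("small_clim", function() doy_climatology(small_network()$records))
}

# a fast trained forest on 5 noiseless stations x 2 years
tiny_rfm <- function() {
  cached("tiny_rfm", function() {
    net <- generate_network(network_config(
      n_flux_stations = 5, n_met_stations = 1, years = 2018:2019,
      noise_sd_nee = 0, noise_sd_wf = 0, missing_rate = 0, seed = 302
    ))
    rec <- dplyr::filter(net$records, station_id %in%
                           net$meta$station_id[net$meta$role == "flux"])
    list(
      rfm = train_rfm(rec, scenario_factors(), "NEE",
                      hyper_config(n_draws = 1, trees = c(60, 60),
                                   max_depth = c(15, 15), p_unlimited = 0),
                      seed = 302),
      records = rec,
      network = net
    )
  })
}

# a mini end-to-end pipeline run (Overall category, WRS, WF)
mini_run <- function() {
  cached("mini_run", function() {
    cfg <- pipeline_config(
      network = network_config(n_flux_stations = 12, n_met_stations = 4,
                               years = 2019, seed = 303),
      k = 3, p = 2, scenarios = "WRS", targets = "WF", categories = "Overall",
      hyper = hyper_config(n_draws = 1, trees = c(20, 20),
                           max_depth = c(10, 10), p_unlimited = 0),
      seed = 303
    )
    list(config = cfg, run = run_flux_pipeline(cfg))
  })
}

# constant-prediction stand-in for a fitted forest, for arithmetic checks
fake_rfm <- function(predictions, features = "x", target = "NEE",
                     training_ids = "TRAIN") {
  structure(
    list(model = structure(list(values = predictions), class = "fake_model"),
         features = features, target = target,
         training_station_ids = training_ids,
         hyper = NULL, oob_r2 = NA, n_rows = NA, n_dropped = 0, seed = 0L),
    class = "rfm"
  )
}

predict.fake_model <- function(object, data, ...) {
  list(predictions = object$values[seq_len(nrow(data))])
}
registerS3method("predict", "fake_model", predict.fake_model,
                 envir = asNamespace("stats"))
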