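test_that("station evaluation reproduces the determination coefficient by hand", {
  rec <- tibble::tibble(station_id = "S", year = 2019, doy = 1:3,
                        x = c(0, 0, 0), nee = c(1, 2, 3))
  # predictions equal observations
  ev <- evaluate_station(fake_rfm(c(1, 2, 3)), rec)
  expect_equal(ev$r2, 1)
  expect_equal(ev$rmse, 0)
  # predictions equal the observed mean
  ev <- evaluate_station(fake_rfm(c(2, 2, 2)), rec)
  expect_equal(ev$r2, 0)
  # obs (1,2,3) vs pred (1,2,4): SSres 1, SStot 2
  ev <- evaluate_station(fake_rfm(c(1, 2, 4)), rec)
  expect_equal(ev$r2, 0.5)
  expect_equal(ev$rmse, sqrt(1 / 3))
  expect_equal(ev$n_days, 3)
  # zero-variance observations are flagged, not scored
  rec0 <- dplyr::mutate(rec, nee = 5)
  ev <- evaluate_station(fake_rfm(c(4, 5, 6)), rec0)
  expect_true(ev$zero_variance)
  expect_true(is.na(ev$r2))
  # a training station may not be evaluated
  expect_error(evaluate_station(fake_rfm(1:3, training_ids = "S"), rec), "train")
})

test_that("a forest fits smooth noiseless truth on its own training stations", {
  fx <- tiny_rfm()
  preds <- predict_rfm(fx$rfm, fx$records)
  obs <- fx$records$nee
  r2 <- 1 - sum((obs - preds)^2) / sum((obs - mean(obs))^2)
  expect_gte(r2, 0.95)
  expect_gte(fx$rfm$oob_r2, 0.9)
})

test_that("training is deterministic given a seed and honours the scenario feature set", {
  fx <- tiny_rfm()
  h <- hyper_config(n_draws = 2, trees = c(30, 60), max_depth = c(8, 15))
  m1 <- train_rfm(fx$records, scenario_factors(scenario = "WRS"), "NEE", h, seed = 99)
  m2 <- train_rfm(fx$records, scenario_factors(scenario = "WRS"), "NEE", h, seed = 99)
  newdata <- fx$records[1:50, ]
  expect_identical(predict_rfm(m1, newdata), predict_rfm(m2, newdata))
  expect_identical(m1$hyper, m2$hyper)
  # WRS excludes every remote-sensing factor
  rs <- factor_registry()$name[factor_registry()$group == "remote_sensing"]
  expect_length(intersect(m1$features, rs), 0)
})

test_that("grouped CV yields n x p evaluations with disjoint train/test stations", {
  net <- small_network()
  flux_ids <- net$meta$station_id[net$meta$role == "flux"]
  rec <- dplyr::filter(net$records, station_id %in% flux_ids)
  plan <- make_cv_plan(flux_ids, k = 4, p = 2, seed = 8)
  res <- run_cv(rec, plan, "Overall", "RS", "NEE",
                hyper = hyper_config(n_draws = 1, trees = c(5, 5),
                                     max_depth = c(8, 8), p_unlimited = 0),
                seed = 8)
  expect_equal(nrow(res$evaluations), length(flux_ids) * 2)
  expect_length(res$models, 4 * 2)
  for (id in names(res$models)) {
    m <- res$models[[id]]
    tested <- res$evaluations$station_id[res$evaluations$rfm_id == id]
    expect_length(intersect(m$training_station_ids, tested), 0)
  }
  # p = 1: each station evaluated exactly once
  res1 <- run_cv(rec, make_cv_plan(flux_ids, k = 4, p = 1, seed = 9),
                 "Overall", "RS", "NEE",
                 hyper = hyper_config(n_draws = 1, trees = c(5, 5),
                                      max_depth = c(8, 8), p_unlimited = 0),
                 seed = 9)
  expect_setequal(res1$evaluations$station_id, flux_ids)
  expect_equal(anyDuplicated(res1$evaluations$station_id), 0)
})

test_that("CV summaries count inclusive 0.5 thresholds per evaluation and per station maximum", {
  ev <- tibble::tibble(
    station_id = c("A", "A", "B", "C", "C", "C"),
    r2 = c(0.4, 0.5, 0.9, 0.2, 0.45, 0.1)
  )
  s <- summarize_cv(ev)
  expect_equal(s$frac_eval_ge_05, 2 / 6)
  expect_equal(s$station_max$max_r2[s$station_max$station_id == "A"], 0.5)
  expect_equal(s$frac_station_max_ge_05, 2 / 3)
  # all below 0.5
  expect_equal(summarize_cv(dplyr::mutate(ev, r2 = r2 - 0.6))$frac_station_max_ge_05, 0)
})

test_that("remote-sensing covariates help when the truth depends on fPAR", {
  h <- hyper_config(n_draws = 1, trees = c(30, 30), max_depth = c(10, 10),
                    p_unlimited = 0)
  diffs <- sapply(1:10, function(sd) {
    net <- generate_network(network_config(n_flux_stations = 10, n_met_stations = 1,
                                           years = 2019, noise_sd_nee = 0.2,
                                           missing_rate = 0, seed = 500 + sd))
    flux_ids <- net$meta$station_id[net$meta$role == "flux"]
    rec <- dplyr::filter(net$records, station_id %in% flux_ids)
    plan <- make_cv_plan(flux_ids, k = 2, p = 1, seed = 600 + sd)
    r2s <- sapply(c("RS", "WRS"), function(sc) {
      mean(run_cv(rec, plan, "Overall", sc, "NEE", hyper = h,
                  seed = 700 + sd)$evaluations$r2)
    })
    r2s["RS"] - r2s["WRS"]
  })
  expect_gte(mean(diffs), 0)
})

test_that("shuffling a held-out station's fluxes destroys its apparent skill", {
  fx <- tiny_rfm()
  net <- generate_network(network_config(n_flux_stations = 2, n_met_stations = 1,
                                         years = 2018:2019, noise_sd_nee = 0,
                                         missing_rate = 0, seed = 310))
  r2s <- sapply(net$meta$station_id[net$meta$role == "flux"], function(st) {
    d <- dplyr::filter(net$records, station_id == st)
    d$station_id <- paste0("X", d$station_id) # avoid id collision with training
    set.seed(1); d$nee <- sample(d$nee)
    evaluate_station(fx$rfm, d)$r2
  })
  expect_lte(mean(r2s), 0.1)
})
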