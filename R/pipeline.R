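#' Candidate models for one meteorological station
#'
#' A model is a candidate when its scenario and target match and its category
#' is one of the station's four memberships (landscape, continent, aridity
#' class, Overall). A station is never scored against a category it does not
#' belong to.
#'
#' @param station_categories Character vector (or factor) of the station's
#'   category memberships.
#' @param model_index Tibble of the model store index with columns `rfm_id`,
#'   `category`, `scenario`, `target` (see [train_model_store()]).
#' @param scenario,target Scenario and target to filter on.
#' @return Character vector of candidate `rfm_id`s, ordered by category
#'   (registry order of [category_levels()]) then rfm_id.
#' @export
candidate_rfms <- function(station_categories, model_index, scenario, target) {
  idx <- dplyr::filter(
    model_index,
    .data$scenario == .env$scenario,
    .data$target == .env$target,
    as.character(.data$category) %in% as.character(station_categories)
  )
  idx <- idx[order(match(as.character(idx$category), category_levels()), idx$rfm_id), ]
  idx$rfm_id
}

#' Screen the candidate models of one meteorological station
#'
#' Predicts the transfer R2 of every candidate model with its category's RSM
#' (from the station-to-training-set distance vectors) and picks the maximum.
#' If the maximum predicted R2 is below 0.5 no model is chosen (the station is
#' not transferable). The 0.5 boundary is inclusive. Ties are broken by
#' category order in [category_levels()], then by rfm_id (candidates arrive
#' in that order from [candidate_rfms()]).
#'
#' @param station_id Met station id.
#' @param candidates Candidate `rfm_id`s in tie-break order.
#' @param models Named list of `rfm` objects.
#' @param rsms Named list of `rsm` objects keyed by
#'   `paste(category, scenario, target, sep = "_")`.
#' @param dmats Precomputed distance matrices (met x flux) from
#'   [distance_matrices()].
#' @param scenario,target Labels recorded in the decision.
#' @return One-row tibble: `station_id, scenario, target, rfm_id` (`NA` when
#'   none chosen), `predicted_r2`, `quality_class` (predicted R2 clamped to 1
#'   for binning; class 1 when no model), `n_candidates`.
#' @export
screen_station <- function(station_id, candidates, models, rsms, dmats,
                           scenario, target) {
  preds <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    m <- models[[candidates[i]]]
    rsm <- rsms[[paste(strsplit(candidates[i], "_")[[1]][1], scenario, target, sep = "_")]]
    if (is.null(rsm)) next
    dv <- distance_vectors_from_matrices(dmats, station_id, m$training_station_ids)
    if (anyNA(dv[, -1])) next
    preds[i] <- predict_r2(rsm, dv[, -1])
  }
  scorable <- which(!is.na(preds))
  if (length(scorable) == 0 || max(preds[scorable]) < 0.5) {
    chosen <- NA_character_
    best_pred <- if (length(scorable)) max(preds[scorable]) else NA_real_
    qc <- 1L
  } else {
    best <- scorable[which.max(preds[scorable])] # which.max: first max wins ties
    chosen <- candidates[best]
    best_pred <- preds[best]
    qc <- quality_class(min(best_pred, 1))
  }
  tibble::tibble(
    station_id = station_id, scenario = scenario, target = target,
    rfm_id = chosen, predicted_r2 = best_pred, quality_class = qc,
    n_candidates = length(candidates), n_scorable = length(scorable)
  )
}

#' Simulate daily fluxes at a station with a chosen model
#'
#' One prediction per feature-complete day; days with any missing feature are
#' omitted (their count is attached as attribute `"n_omitted"`).
#'
#' @param rfm The chosen `rfm`.
#' @param records The station's daily records.
#' @return Tibble `(station_id, year, month, day, doy, prediction)`.
#' @export
simulate_fluxes <- function(rfm, records) {
  ok <- complete.cases(records[, rfm$features])
  if (!any(ok)) abort_bad_arg("no feature-complete days to simulate")
  out <- records[ok, c("station_id", "year", "month", "day", "doy")]
  out$prediction <- predict_rfm(rfm, records[ok, ])
  attr(out, "n_omitted") <- sum(!ok)
  out
}

#' Write per-station flux CSVs and the station-information table
#'
#' For each scenario, writes one CSV per met station that received at least
#' one transferred model, named by the station id, with columns
#' `id,lon,lat,year,month,day,doy,NEE,WF` (a target not transferred at that
#' station is `NA`). Also writes `station_info.csv` with the station metadata
#' and the four `Classification of simulated <target>-<scenario>` columns
#' using quality classes 1/2/3 (class 1 when no model was transferred).
#'
#' @param decisions Decisions tibble (rows from [screen_station()]).
#' @param predictions Tibble of simulated fluxes with columns `station_id`,
#'   `scenario`, `target`, `year`, `month`, `day`, `doy`, `prediction`.
#' @param meta Met-station metadata.
#' @param out_dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_station_outputs <- function(decisions, predictions, meta, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sc in unique(decisions$scenario)) {
    sc_dir <- file.path(out_dir, sc)
    dir.create(sc_dir, showWarnings = FALSE)
    dec_sc <- decisions[decisions$scenario == sc & !is.na(decisions$rfm_id), ]
    for (st in unique(dec_sc$station_id)) {
      preds <- predictions[predictions$station_id == st & predictions$scenario == sc, ]
      if (nrow(preds) == 0) next
      wide <- preds |>
        dplyr::select("station_id", "year", "month", "day", "doy", "target", "prediction") |>
        tidyr::pivot_wider(names_from = "target", values_from = "prediction")
      if (!"NEE" %in% names(wide)) wide$NEE <- NA_real_
      if (!"WF" %in% names(wide)) wide$WF <- NA_real_
      m <- meta[meta$station_id == st, ]
      out <- tibble::tibble(
        id = st, lon = m$lon, lat = m$lat,
        year = wide$year, month = wide$month, day = wide$day, doy = wide$doy,
        NEE = wide$NEE, WF = wide$WF
      )
      p <- file.path(sc_dir, paste0(st, ".csv"))
      readr::write_csv(out, p)
      paths <- c(paths, p)
    }
  }
  info <- meta |>
    dplyr::transmute(
      id = .data$station_id, station_name = .data$name,
      longitude = .data$lon, latitude = .data$lat,
      elevation = .data$elevation, continent = .data$continent,
      drought_situation = ifelse(.data$aridity_index < 0.65, "Arid", "NonArid"),
      landscape = igbp_landscape(.data$igbp), data_source = "synthetic"
    )
  for (tg in c("NEE", "WF")) {
    for (sc in c("RS", "WRS")) {
      col <- paste0("class_", tg, "_", sc)
      d <- decisions[decisions$target == tg & decisions$scenario == sc, ]
      cls <- d$quality_class[match(info$id, d$station_id)]
      info[[col]] <- ifelse(is.na(cls), 1L, cls)
    }
  }
  info_path <- file.path(out_dir, "station_info.csv")
  readr::write_csv(info, info_path)
  invisible(c(paths, info_path))
}

#' Train the full model store over every category / scenario / target
#'
#' Runs the grouped cross-validation of [run_cv()] for every combination in
#' the training plan, pooling models and evaluations.
#'
#' @param records Preprocessed flux-station daily records.
#' @param partitions Tibble `(category, station_id)` of flux-station
#'   memberships.
#' @param scenarios,targets Scenario / target sets.
#' @param k,p Folds and splits.
#' @param registry Factor registry.
#' @param hyper A [hyper_config()].
#' @param seed Integer seed.
#' @return List: `models` (named list), `model_index` (tibble), `evaluations`
#'   (tibble), `cv_plans` (named list of per-category plans).
#' @export
train_model_store <- function(records, partitions, scenarios = c("RS", "WRS"),
                              targets = c("NEE", "WF"), k = 10, p = 10,
                              registry = factor_registry(),
                              hyper = hyper_config(), seed = 1L) {
  cats <- intersect(category_levels(), unique(as.character(partitions$category)))
  plan_seeds <- derive_seeds(seed, length(cats), salt = 301L)
  cv_plans <- lapply(seq_along(cats), function(i) {
    ids <- partitions$station_id[as.character(partitions$category) == cats[i]]
    make_cv_plan(ids, k = k, p = p, seed = plan_seeds[i])
  })
  names(cv_plans) <- cats

  combos <- tidyr::expand_grid(category = cats, scenario = scenarios, target = targets)
  run_seeds <- derive_seeds(seed, nrow(combos), salt = 707L)
  models <- list()
  evaluations <- purrr::map(seq_len(nrow(combos)), function(i) {
    cc <- combos[i, ]
    res <- run_cv(records, cv_plans[[cc$category]], cc$category,
                  scenario = cc$scenario, target = cc$target,
                  registry = registry, hyper = hyper, seed = run_seeds[i])
    models <<- c(models, res$models)
    res$evaluations
  }) |> dplyr::bind_rows()

  model_index <- tibble::tibble(
    rfm_id = names(models),
    category = purrr::map_chr(names(models), \(id) strsplit(id, "_")[[1]][1]),
    scenario = purrr::map_chr(names(models), \(id) strsplit(id, "_")[[1]][2]),
    target = purrr::map_chr(names(models), \(id) strsplit(id, "_")[[1]][3])
  )
  list(models = models, model_index = model_index,
       evaluations = evaluations, cv_plans = cv_plans)
}

#' Configuration of a full pipeline run
#'
#' @param network A [network_config()].
#' @param k,p Folds per split and number of splits.
#' @param scenarios,targets Modelling scenarios and flux targets.
#' @param categories Categories to run; default all nine present in the data.
#' @param hyper A [hyper_config()].
#' @param qc_threshold QC threshold for flux masking.
#' @param max_gap Interpolation gap limit (days).
#' @param t_min Minimum common-DOY overlap for distances.
#' @param seed Master seed for CV plans and model training.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(network = network_config(), k = 10, p = 10,
                            scenarios = c("RS", "WRS"), targets = c("NEE", "WF"),
                            categories = NULL, hyper = hyper_config(),
                            qc_threshold = 0.8, max_gap = 7, t_min = 30,
                            seed = 1L) {
  structure(list(network = network, k = k, p = p, scenarios = scenarios,
                 targets = targets, categories = categories, hyper = hyper,
                 qc_threshold = qc_threshold, max_gap = max_gap, t_min = t_min,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the whole transfer framework end to end
#'
#' Generates (or accepts) a station network, preprocesses the records,
#' partitions the flux stations into categories, trains the grouped-CV model
#' store, assembles Dataset 1 and fits one RSM per (category, scenario,
#' target), screens every met station's candidate models, simulates daily
#' fluxes with the chosen models and, when `out_dir` is given, writes the
#' per-station CSV outputs. Fully reproducible from the configuration.
#'
#' @param config A [pipeline_config()].
#' @param network Optionally, a pre-generated `flux_network` (must match the
#'   config's network settings); default generates one from
#'   `config$network`.
#' @param out_dir Optional output directory for the station CSVs.
#' @return A `flux_transfer_run` list: `report` (counts, percentages and
#'   accuracies), `evaluations`, `dataset1`, `rsms`, `decisions`,
#'   `predictions`, `summaries`, `network`, `config`.
#' @export
run_flux_pipeline <- function(config = pipeline_config(), network = NULL,
                              out_dir = NULL) {
  registry <- factor_registry()
  if (is.null(network)) network <- generate_network(config$network)
  records <- preprocess_records(network$records, registry,
                                qc_threshold = config$qc_threshold,
                                max_gap = config$max_gap)

  memberships <- assign_categories(network$meta)
  flux_ids <- network$meta$station_id[network$meta$role == "flux"]
  met_ids <- network$meta$station_id[network$meta$role == "met"]
  partitions <- dplyr::filter(memberships, .data$station_id %in% flux_ids)
  if (!is.null(config$categories)) {
    partitions <- dplyr::filter(partitions,
                                as.character(.data$category) %in% config$categories)
  }

  flux_records <- dplyr::filter(records, .data$station_id %in% flux_ids)
  met_records <- dplyr::filter(records, .data$station_id %in% met_ids)

  store <- train_model_store(flux_records, partitions,
                             scenarios = config$scenarios, targets = config$targets,
                             k = config$k, p = config$p, registry = registry,
                             hyper = config$hyper, seed = config$seed)

  clim <- doy_climatology(records, registry)

  # Dataset 1 + RSM per (category, scenario, target)
  groups <- dplyr::distinct(store$evaluations, .data$category, .data$scenario,
                            .data$target)
  dataset1 <- list()
  rsms <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    ev <- dplyr::filter(store$evaluations,
                        .data$category == g$category,
                        .data$scenario == g$scenario, .data$target == g$target)
    d1 <- build_dataset1(ev, store$models, clim, registry, t_min = config$t_min)
    key <- paste(g$category, g$scenario, g$target, sep = "_")
    dataset1[[key]] <- d1
    rsms[[key]] <- fit_rsm(d1)
  }

  # screening + simulation at met stations
  met_memberships <- dplyr::filter(memberships, .data$station_id %in% met_ids)
  combos <- tidyr::expand_grid(scenario = config$scenarios, target = config$targets)
  decisions <- list()
  predictions <- list()
  for (i in seq_len(nrow(combos))) {
    sc <- combos$scenario[i]; tg <- combos$target[i]
    factors <- scenario_factors(registry, sc)
    dmats <- distance_matrices(clim, met_ids, flux_ids, factors, config$t_min)
    for (st in met_ids) {
      st_cats <- met_memberships$category[met_memberships$station_id == st]
      cand <- candidate_rfms(st_cats, store$model_index, sc, tg)
      dec <- screen_station(st, cand, store$models, rsms, dmats, sc, tg)
      decisions[[length(decisions) + 1]] <- dec
      if (!is.na(dec$rfm_id)) {
        sim <- simulate_fluxes(store$models[[dec$rfm_id]],
                               dplyr::filter(met_records, .data$station_id == st))
        sim$scenario <- sc
        sim$target <- tg
        predictions[[length(predictions) + 1]] <- sim
      }
    }
  }
  decisions <- dplyr::bind_rows(decisions)
  predictions <- if (length(predictions)) dplyr::bind_rows(predictions) else
    tibble::tibble(station_id = character(), year = integer(), month = integer(),
                   day = integer(), doy = integer(), prediction = numeric(),
                   scenario = character(), target = character())

  summaries <- store$evaluations |>
    dplyr::group_by(.data$scenario, .data$target) |>
    dplyr::group_map(function(g, key) {
      s <- summarize_cv(g)
      tibble::tibble(scenario = key$scenario, target = key$target,
                     frac_eval_ge_05 = s$frac_eval_ge_05,
                     frac_station_max_ge_05 = s$frac_station_max_ge_05)
    }) |> dplyr::bind_rows()

  # pooled (all-category) accuracy per scenario/target
  pooled_accuracy <- purrr::map(dataset1, function(d1) {
    key <- paste(d1$category[1], d1$scenario[1], d1$target[1], sep = "_")
    tibble::tibble(scenario = d1$scenario, target = d1$target, r2 = d1$r2,
                   pred = predict_r2(rsms[[key]], d1))
  }) |> dplyr::bind_rows() |>
    dplyr::group_by(.data$scenario, .data$target) |>
    dplyr::summarise(accuracy = classification_accuracy(.data$r2, .data$pred),
                     .groups = "drop")

  transfer_rates <- decisions |>
    dplyr::group_by(.data$scenario, .data$target) |>
    dplyr::summarise(frac_transferred = mean(!is.na(.data$rfm_id)), .groups = "drop")

  report <- list(
    model_count = length(store$models),
    evaluation_count = nrow(store$evaluations),
    dataset1_counts = purrr::map_int(dataset1, nrow),
    cv_summaries = summaries,
    rsm_accuracy = pooled_accuracy,
    transfer_rates = transfer_rates,
    n_met_stations = length(met_ids),
    n_flux_stations = length(flux_ids),
    seed = config$seed
  )

  out <- structure(
    list(report = report, evaluations = store$evaluations, models = store$models,
         model_index = store$model_index, cv_plans = store$cv_plans,
         dataset1 = dataset1, rsms = rsms, decisions = decisions,
         predictions = predictions, summaries = summaries, network = network,
         config = config),
    class = "flux_transfer_run"
  )
  if (!is.null(out_dir)) {
    write_station_outputs(decisions, predictions,
                          dplyr::filter(network$meta, .data$role == "met"), out_dir)
    jsonlite::write_json(report_json(out), file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# flat, serialisable view of a run report
report_json <- function(run) {
  rp <- run$report
  list(
    model_count = rp$model_count,
    evaluation_count = rp$evaluation_count,
    dataset1_counts = as.list(rp$dataset1_counts),
    cv_summaries = rp$cv_summaries,
    rsm_accuracy = rp$rsm_accuracy,
    transfer_rates = rp$transfer_rates,
    seed = rp$seed
  )
}

#' @export
print.flux_transfer_run <- function(x, ...) {
  rp <- x$report
  cat("<flux_transfer_run> ", rp$model_count, " models, ",
      rp$evaluation_count, " evaluations, ", rp$n_met_stations,
      " met stations\n", sep = "")
  cat("CV summaries:\n"); print(rp$cv_summaries)
  cat("RSM classification accuracy:\n"); print(rp$rsm_accuracy)
  cat("Transfer rates:\n"); print(rp$transfer_rates)
  invisible(x)
}
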