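#' Random-search hyperparameter configuration for the flux forests
#'
#' @param n_draws Number of random configurations scored per model (default
#'   20).
#' @param trees Range of `num.trees` (inclusive).
#' @param max_depth Range of tree depth; a draw of depth may also be
#'   "unlimited" with probability `p_unlimited`.
#' @param min_node Range of minimum terminal-node size.
#' @param mtry_frac Range of the fraction of features tried per split.
#' @param p_unlimited Probability that a draw uses unlimited depth.
#' @return A `hyper_config` list.
#' @export
hyper_config <- function(n_draws = 20, trees = c(100, 500), max_depth = c(5, 30),
                         min_node = c(1, 10), mtry_frac = c(0.3, 1.0),
                         p_unlimited = 1 / 6) {
  structure(list(n_draws = n_draws, trees = trees, max_depth = max_depth,
                 min_node = min_node, mtry_frac = mtry_frac,
                 p_unlimited = p_unlimited),
            class = "hyper_config")
}

draw_hyper <- function(config, n) {
  tibble::tibble(
    num_trees = sample(seq(config$trees[1], config$trees[2]), n, replace = TRUE),
    max_depth = ifelse(runif(n) < config$p_unlimited, 0L,
                       sample(seq(config$max_depth[1], config$max_depth[2]), n,
                              replace = TRUE)),
    min_node = sample(seq(config$min_node[1], config$min_node[2]), n, replace = TRUE),
    mtry_frac = runif(n, config$mtry_frac[1], config$mtry_frac[2])
  )
}

#' Train one random-forest flux model
#'
#' Fits a random-forest regression of the target flux on the scenario's
#' factors over the pooled daily rows of the training stations. `n_draws`
#' hyperparameter configurations are drawn at random from the configured
#' ranges, each is scored by out-of-bag R2, and the best configuration's
#' forest is kept. Rows with any missing feature or target are dropped (the
#' count is recorded). Deterministic given the seed.
#'
#' @param records Daily records of the training stations.
#' @param features Character vector of feature column names (registry order).
#' @param target `"NEE"` or `"WF"` (columns `nee` / `wf`).
#' @param hyper A [hyper_config()].
#' @param seed Integer seed.
#' @return An `rfm` object: the fitted ensemble plus the chosen
#'   hyperparameters, out-of-bag R2, feature list, training station ids and
#'   row counts.
#' @export
train_rfm <- function(records, features, target = c("NEE", "WF"),
                      hyper = hyper_config(), seed = 1L) {
  target <- match.arg(target)
  ycol <- if (target == "NEE") "nee" else "wf"
  records <- tibble::as_tibble(records)
  stopifnot(all(features %in% names(records)), ycol %in% names(records))
  keep <- complete.cases(records[, c(features, ycol)])
  n_dropped <- sum(!keep)
  data <- records[keep, ]
  if (nrow(data) == 0) abort_bad_arg("no complete training rows")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  draws <- draw_hyper(hyper, hyper$n_draws)
  fit_seeds <- derive_seeds(seed, hyper$n_draws, salt = 7L)

  x <- as.data.frame(data[, features])
  y <- data[[ycol]]
  fits <- purrr::map(seq_len(nrow(draws)), function(i) {
    d <- draws[i, ]
    ranger::ranger(
      x = x, y = y,
      num.trees = d$num_trees,
      max.depth = d$max_depth,
      min.node.size = d$min_node,
      mtry = max(1L, round(d$mtry_frac * length(features))),
      seed = fit_seeds[i],
      num.threads = 1
    )
  })
  oob <- purrr::map_dbl(fits, "r.squared")
  best <- which.max(oob)
  structure(
    list(
      model = fits[[best]],
      hyper = draws[best, ],
      oob_r2 = oob[best],
      features = features,
      target = target,
      training_station_ids = unique(data$station_id),
      n_rows = nrow(data),
      n_dropped = n_dropped,
      seed = as.integer(seed)
    ),
    class = "rfm"
  )
}

#' @export
print.rfm <- function(x, ...) {
  cat("<rfm> target ", x$target, ", ", length(x$features), " features, ",
      length(x$training_station_ids), " stations, ", x$n_rows, " rows, OOB R2 ",
      round(x$oob_r2, 3), "\n", sep = "")
  invisible(x)
}

#' Predict daily fluxes with a trained forest
#'
#' @param rfm An `rfm` object.
#' @param records Daily records; rows with a missing feature yield `NA`.
#' @return Numeric vector of predictions, one per row of `records`.
#' @export
predict_rfm <- function(rfm, records) {
  stopifnot(inherits(rfm, "rfm"))
  out <- rep(NA_real_, nrow(records))
  ok <- complete.cases(records[, rfm$features])
  if (any(ok)) {
    out[ok] <- predict(rfm$model, data = as.data.frame(records[ok, rfm$features]),
                       num.threads = 1)$predictions
  }
  out
}

#' Evaluate a trained model at one held-out station
#'
#' Computes, over the station's days with all features and the observed target
#' present, the determination coefficient `r2 = 1 - SSres/SStot` (SStot about
#' the station's own observed mean; may be negative) and
#' `rmse = sqrt(SSres/n)`. A station whose observations have zero variance
#' gets `r2 = NA` and is flagged for downstream exclusion.
#'
#' @param rfm An `rfm`.
#' @param records Daily records of a single station not used in training.
#' @return One-row tibble `(station_id, r2, rmse, n_days, zero_variance)`.
#' @export
evaluate_station <- function(rfm, records) {
  stopifnot(inherits(rfm, "rfm"), length(unique(records$station_id)) == 1)
  if (records$station_id[1] %in% rfm$training_station_ids) {
    abort_bad_arg("station was used to train this model")
  }
  ycol <- if (rfm$target == "NEE") "nee" else "wf"
  keep <- complete.cases(records[, c(rfm$features, ycol)])
  obs <- records[[ycol]][keep]
  if (length(obs) < 2) abort_bad_arg("need >= 2 valid days to evaluate")
  pred <- predict_rfm(rfm, records[keep, ])
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  zero_var <- ss_tot == 0
  tibble::tibble(
    station_id = records$station_id[1],
    r2 = if (zero_var) NA_real_ else 1 - ss_res / ss_tot,
    rmse = sqrt(ss_res / length(obs)),
    n_days = length(obs),
    zero_variance = zero_var
  )
}

rfm_id_of <- function(category, scenario, target, split, fold) {
  sprintf("%s_%s_%s_s%02d_f%02d", category, scenario, target, split, fold)
}

#' Run the grouped cross-validation for one category
#'
#' For every (split, fold) of the plan, trains a forest on the stations
#' outside the fold and evaluates it at each station inside the fold. With
#' `n` stations and `p` splits this yields `n * p` per-station evaluations
#' (zero-variance stations excluded and logged).
#'
#' @param records Preprocessed daily records of the category's flux stations.
#' @param plan CV plan from [make_cv_plan()].
#' @param category Category label stored with each model.
#' @param scenario `"RS"` or `"WRS"` (fixes the feature list).
#' @param target `"NEE"` or `"WF"`.
#' @param registry Factor registry.
#' @param hyper A [hyper_config()].
#' @param seed Integer seed; per-model training seeds are derived from it.
#' @return List with `evaluations` (tibble: rfm_id, category, scenario,
#'   target, split, fold, station_id, r2, rmse, n_days) and `models` (named
#'   list of `rfm` objects keyed by rfm_id).
#' @export
run_cv <- function(records, plan, category, scenario = c("RS", "WRS"),
                   target = c("NEE", "WF"), registry = factor_registry(),
                   hyper = hyper_config(), seed = 1L) {
  scenario <- match.arg(scenario)
  target <- match.arg(target)
  features <- scenario_factors(registry, scenario)
  stations <- unique(plan$station_id)
  recs <- dplyr::filter(records, .data$station_id %in% stations)
  by_station <- split(recs, recs$station_id)

  tasks <- dplyr::distinct(plan, .data$split, .data$fold)
  seeds <- derive_seeds(seed, nrow(tasks), salt = 23L)
  models <- list()
  evals <- purrr::map(seq_len(nrow(tasks)), function(i) {
    s <- tasks$split[i]; f <- tasks$fold[i]
    test_ids <- plan$station_id[plan$split == s & plan$fold == f]
    train_ids <- setdiff(stations, test_ids)
    rfm <- train_rfm(dplyr::bind_rows(by_station[train_ids]), features, target,
                     hyper = hyper, seed = seeds[i])
    id <- rfm_id_of(category, scenario, target, s, f)
    models[[id]] <<- rfm
    purrr::map(test_ids, function(st) {
      ev <- evaluate_station(rfm, by_station[[st]])
      ev$rfm_id <- id; ev$split <- s; ev$fold <- f
      ev
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  evals$category <- category
  evals$scenario <- scenario
  evals$target <- target
  excluded <- evals[evals$zero_variance, "station_id"]
  evals <- evals[, c("rfm_id", "category", "scenario", "target", "split",
                     "fold", "station_id", "r2", "rmse", "n_days", "zero_variance")]
  list(evaluations = evals, models = models, zero_variance_excluded = excluded)
}

#' Summarise a set of per-station cross-validation evaluations
#'
#' @param evaluations Evaluations tibble from [run_cv()].
#' @return A list with `frac_eval_ge_05` (fraction of evaluations with
#'   R2 >= 0.5), `station_max` (tibble of each station's maximum R2 over all
#'   splits) and `frac_station_max_ge_05` (fraction of stations whose maximum
#'   R2 reaches 0.5).
#' @export
summarize_cv <- function(evaluations) {
  ev <- dplyr::filter(evaluations, !is.na(.data$r2))
  if (nrow(ev) == 0) abort_bad_arg("no valid evaluations")
  station_max <- ev |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(max_r2 = max(.data$r2), .groups = "drop")
  list(
    frac_eval_ge_05 = mean(ev$r2 >= 0.5),
    station_max = station_max,
    frac_station_max_ge_05 = mean(station_max$max_r2 >= 0.5)
  )
}
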