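#' Multi-year day-of-year climatology of every factor at every station
#'
#' For each station and daily factor, averages the observed values falling on
#' the same day of year across all years (missing values excluded per DOY).
#' Leap days (DOY 366) are dropped so series are comparable on DOY 1..365.
#' Static factors are reduced to a single value per station.
#'
#' @param records Daily records (network schema), any mix of stations.
#' @param registry Factor registry.
#' @return A `doy_climatology` object: list with `daily` (named list of
#'   365 x n-daily-factor matrices per station, `NA` where a DOY was never
#'   observed), `static` (stations x static-factor matrix), `daily_factors`,
#'   `static_factors`.
#' @export
doy_climatology <- function(records, registry = factor_registry()) {
  records <- dplyr::filter(tibble::as_tibble(records), .data$doy <= 365)
  if (nrow(records) == 0) abort_bad_arg("no records with DOY <= 365")
  daily_f <- intersect(registry$name[registry$group != "static"], names(records))
  static_f <- intersect(registry$name[registry$group == "static"], names(records))

  means <- records |>
    dplyr::group_by(.data$station_id, .data$doy) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(daily_f), \(x) mean(x, na.rm = TRUE)),
                     .groups = "drop")
  stations <- unique(records$station_id)
  daily <- lapply(stations, function(st) {
    m <- matrix(NA_real_, nrow = 365, ncol = length(daily_f),
                dimnames = list(NULL, daily_f))
    sub <- means[means$station_id == st, ]
    m[sub$doy, ] <- as.matrix(sub[, daily_f])
    m[is.nan(m)] <- NA_real_
    m
  })
  names(daily) <- stations

  static <- records |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(static_f), \(x) mean(x, na.rm = TRUE)),
                     .groups = "drop")
  static_m <- as.matrix(static[, static_f])
  rownames(static_m) <- static$station_id

  structure(list(daily = daily, static = static_m[stations, , drop = FALSE],
                 daily_factors = daily_f, static_factors = static_f),
            class = "doy_climatology")
}

#' @export
print.doy_climatology <- function(x, ...) {
  cat("<doy_climatology> ", length(x$daily), " stations, ",
      length(x$daily_factors), " daily + ", length(x$static_factors),
      " static factors\n", sep = "")
  invisible(x)
}

#' Euclidean distance of one factor between two stations
#'
#' Root sum of squared differences of the two stations' DOY climatologies of
#' the factor, taken over the DOYs observed at both stations. Static factors
#' are length-1 series, so their distance is the absolute difference. Pairs
#' sharing fewer than `t_min` common DOYs have no defined distance (`NA`).
#'
#' @param clim A [doy_climatology()] covering both stations.
#' @param station_x,station_y Station ids.
#' @param factor Factor name.
#' @param t_min Minimum common-DOY overlap for daily factors (default 30).
#' @return Non-negative scalar distance, or `NA` if the overlap is too small.
#' @export
pairwise_ds <- function(clim, station_x, station_y, factor, t_min = 30) {
  stopifnot(inherits(clim, "doy_climatology"))
  if (factor %in% clim$static_factors) {
    return(abs(clim$static[station_x, factor] - clim$static[station_y, factor]))
  }
  x <- clim$daily[[station_x]][, factor]
  y <- clim$daily[[station_y]][, factor]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < t_min) return(NA_real_)
  sqrt(sum((x[ok] - y[ok])^2))
}

# all pairwise ds for one factor between two station sets, as a matrix
ds_matrix <- function(clim, factor, ids_x, ids_y = ids_x, t_min = 30) {
  if (factor %in% clim$static_factors) {
    vx <- clim$static[ids_x, factor]
    vy <- clim$static[ids_y, factor]
    return(abs(outer(vx, vy, "-")) |>
             `dimnames<-`(list(ids_x, ids_y)))
  }
  X <- vapply(ids_x, function(s) clim$daily[[s]][, factor], numeric(365))
  Y <- vapply(ids_y, function(s) clim$daily[[s]][, factor], numeric(365))
  out <- matrix(NA_real_, length(ids_x), length(ids_y),
                dimnames = list(ids_x, ids_y))
  for (i in seq_along(ids_x)) {
    xi <- X[, i]
    diff2 <- (Y - xi)^2
    ok <- !is.na(diff2)
    t_used <- colSums(ok)
    d <- sqrt(colSums(diff2, na.rm = TRUE))
    d[t_used < t_min] <- NA_real_
    out[i, ] <- d
  }
  out
}

#' Precompute per-factor distance matrices between two station sets
#'
#' @param clim A [doy_climatology()].
#' @param ids_x,ids_y Station id sets (rows / columns).
#' @param factors Factor names; default every factor in the climatology.
#' @param t_min Minimum common-DOY overlap.
#' @return Named list of `|ids_x| x |ids_y|` matrices, one per factor.
#' @export
distance_matrices <- function(clim, ids_x, ids_y = ids_x,
                              factors = c(clim$daily_factors, clim$static_factors),
                              t_min = 30) {
  out <- lapply(factors, function(f) ds_matrix(clim, f, ids_x, ids_y, t_min))
  names(out) <- factors
  out
}

#' Mean distance between a station and a model's training set
#'
#' The factor's final distance d_j is the arithmetic mean of the defined
#' pairwise station distances between the station and each training station;
#' pairs with undefined distance are excluded from both numerator and
#' denominator.
#'
#' @param clim A [doy_climatology()].
#' @param station Station id.
#' @param training_ids Training-station ids (>= 1).
#' @param factor Factor name.
#' @param t_min Minimum common-DOY overlap.
#' @return Mean distance, or `NA` when no pair is defined.
#' @export
training_set_distance <- function(clim, station, training_ids, factor, t_min = 30) {
  ds <- vapply(training_ids, function(tr) pairwise_ds(clim, station, tr, factor, t_min),
               numeric(1))
  if (all(is.na(ds))) return(NA_real_)
  mean(ds, na.rm = TRUE)
}

# distance vector(s): rows = stations, columns = d_<factor>, distances to one
# training set, computed from precomputed matrices
distance_vectors_from_matrices <- function(dmats, stations, training_ids) {
  cols <- lapply(dmats, function(D) {
    rowMeans(D[stations, training_ids, drop = FALSE], na.rm = TRUE)
  })
  out <- tibble::as_tibble(setNames(cols, paste0("d_", names(dmats))))
  out$station_id <- stations
  dplyr::relocate(out, "station_id")
}

#' Assemble Dataset 1: test-station R2 paired with distance vectors
#'
#' For every per-station cross-validation evaluation, computes the per-factor
#' mean Euclidean distances between the test station and the evaluated
#' model's training set, and pairs them with the realized R2. Per category
#' this yields `n * p` samples, minus logged exclusions (zero-variance
#' stations, undefined distances).
#'
#' @param evaluations Evaluations tibble from [run_cv()].
#' @param models Named list of `rfm` objects keyed by `rfm_id`.
#' @param clim A [doy_climatology()] of the flux stations.
#' @param registry Factor registry.
#' @param t_min Minimum common-DOY overlap.
#' @return Tibble `(station_id, rfm_id, category, scenario, target, r2,
#'   d_<factor>...)`; the distance columns follow registry order for the
#'   evaluations' scenario. Excluded sample counts are attached as attribute
#'   `"n_excluded"`.
#' @export
build_dataset1 <- function(evaluations, models, clim, registry = factor_registry(),
                           t_min = 30) {
  stopifnot(length(unique(evaluations$scenario)) == 1)
  factors <- scenario_factors(registry, evaluations$scenario[1])
  flux_ids <- unique(c(evaluations$station_id,
                       unlist(lapply(models, `[[`, "training_station_ids"))))
  dmats <- distance_matrices(clim, flux_ids, flux_ids, factors, t_min)

  n_in <- nrow(evaluations)
  ev <- dplyr::filter(evaluations, !is.na(.data$r2))
  samples <- ev |>
    dplyr::group_by(.data$rfm_id) |>
    dplyr::group_map(function(g, key) {
      train_ids <- models[[key$rfm_id]]$training_station_ids
      dv <- distance_vectors_from_matrices(dmats, g$station_id, train_ids)
      dplyr::bind_cols(
        tibble::tibble(station_id = g$station_id, rfm_id = key$rfm_id,
                       category = g$category, scenario = g$scenario,
                       target = g$target, r2 = g$r2),
        dv[, -1]
      )
    }) |>
    dplyr::bind_rows()
  dcols <- paste0("d_", factors)
  defined <- complete.cases(samples[, dcols])
  out <- samples[defined, ]
  attr(out, "n_excluded") <- n_in - nrow(out)
  out
}

#' Fit the R2-simulation model (MLR of R2 on factor distances)
#'
#' Ordinary least squares of realized test-station R2 on the per-factor
#' distances d_1..d_w with an intercept:
#' \deqn{R^2 = a_0 + a_1 d_1 + \cdots + a_w d_w}
#' Collinear (rank-deficient) distance columns are dropped with a message and
#' recorded in the fit.
#'
#' @param dataset1 Samples from [build_dataset1()] (needs `r2` and `d_*`
#'   columns; `n >= w + 2`).
#' @return An `rsm` object with the coefficient vector (named by factor), fit
#'   statistics (R2, adjusted R2, F statistic, p value), sample size and the
#'   labels (category/scenario/target) when present.
#' @export
fit_rsm <- function(dataset1) {
  dcols <- grep("^d_", names(dataset1), value = TRUE)
  if (nrow(dataset1) < length(dcols) + 2) {
    abort_bad_arg("need at least w + 2 samples to fit the RSM")
  }
  df <- as.data.frame(dataset1[, c("r2", dcols)])
  fit <- lm(r2 ~ ., data = df)
  dropped <- names(coef(fit))[is.na(coef(fit))]
  if (length(dropped)) {
    message("dropping collinear distance column(s): ", paste(dropped, collapse = ", "))
    df <- df[, !(names(df) %in% dropped)]
    fit <- lm(r2 ~ ., data = df)
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(
    list(
      coefficients = coef(fit),
      dropped = dropped,
      n = nrow(df),
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      f_statistic = unname(fstat["value"]),
      p_value = if (!is.null(fstat)) {
        unname(pf(fstat["value"], fstat["numdf"], fstat["dendf"], lower.tail = FALSE))
      } else NA_real_,
      category = if ("category" %in% names(dataset1)) as.character(dataset1$category[1]) else NA,
      scenario = if ("scenario" %in% names(dataset1)) dataset1$scenario[1] else NA,
      target = if ("target" %in% names(dataset1)) dataset1$target[1] else NA,
      fit = fit
    ),
    class = "rsm"
  )
}

#' @export
print.rsm <- function(x, ...) {
  cat("<rsm> ", x$category, " ", x$scenario, " ", x$target, ": n = ", x$n,
      ", R2 = ", round(x$r_squared, 3), ", adj R2 = ", round(x$adj_r_squared, 3),
      "\n", sep = "")
  invisible(x)
}

#' Predict transfer R2 from a distance vector
#'
#' Intercept plus dot product of the RSM coefficients with the station's
#' per-factor distances. The prediction is unclamped: it may exceed 1 or be
#' negative.
#'
#' @param rsm An `rsm` object.
#' @param d Named numeric vector (`d_<factor>` or factor names) or a one-row
#'   tibble of distance columns.
#' @return Predicted R2 (scalar, or vector for multi-row input).
#' @export
predict_r2 <- function(rsm, d) {
  stopifnot(inherits(rsm, "rsm"))
  cf <- rsm$coefficients
  terms <- setdiff(names(cf), "(Intercept)")
  if (is.data.frame(d)) {
    dm <- as.matrix(d[, terms, drop = FALSE])
  } else {
    nm <- names(d)
    if (is.null(nm)) abort_bad_arg("`d` must be named")
    if (!all(startsWith(nm, "d_"))) names(d) <- paste0("d_", nm)
    missing_terms <- setdiff(terms, names(d))
    if (length(missing_terms)) {
      abort_bad_arg(paste0("distance vector lacks: ", paste(missing_terms, collapse = ", ")))
    }
    dm <- matrix(d[terms], nrow = 1, dimnames = list(NULL, terms))
  }
  out <- drop(cf["(Intercept)"] + dm %*% cf[terms])
  unname(out)
}

#' Classification accuracy of predicted against realized R2
#'
#' Bins both vectors into the three quality classes (boundaries 0.5 and 0.7,
#' inclusive upward; see [quality_class()]) and returns the fraction of
#' matching classes.
#'
#' @param true_r2,predicted_r2 Equal-length numeric vectors.
#' @return Fraction in \[0, 1\].
#' @export
classification_accuracy <- function(true_r2, predicted_r2) {
  if (length(true_r2) != length(predicted_r2) || length(true_r2) < 1) {
    abort_bad_arg("inputs must have equal length >= 1")
  }
  mean(quality_class(true_r2) == quality_class(predicted_r2))
}
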