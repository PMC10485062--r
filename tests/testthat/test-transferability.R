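# build a climatology object directly from a records-shaped table
clim_of <- function(values_by_station, factor = "ta") {
  recs <- purrr::imap_dfr(values_by_station, function(v, st) {
    tibble::tibble(station_id = st, year = 2019, doy = seq_along(v), !!factor := v)
  })
  doy_climatology(recs)
}

test_that("day-of-year climatology averages years, drops leap days and keeps statics scalar", {
  recs <- tibble::tibble(
    station_id = "S", year = c(2019, 2020, 2020),
    doy = c(100, 100, 366), ta = c(2, 4, 99), elev = 120
  )
  cl <- doy_climatology(recs)
  expect_equal(cl$daily[["S"]][100, "ta"], c(ta = 3))
  expect_equal(sum(!is.na(cl$daily[["S"]][, "ta"])), 1) # leap-day record dropped
  expect_equal(unname(cl$static["S", "elev"]), 120)
  # single-year station: climatology is that year's series
  net <- small_network()
  cl1 <- small_clim()
  one <- dplyr::filter(net$records, station_id == "FS001", doy <= 365)
  expect_equal(unname(cl1$daily[["FS001"]][one$doy, "ta"]), one$ta)
})

test_that("pairwise distances match hand values: identity, 3-4-5, statics", {
  cl <- clim_of(list(A = c(1, 2), B = c(4, 6), C = c(1, 2)))
  expect_equal(pairwise_ds(cl, "A", "B", "ta", t_min = 2), 5)
  expect_equal(pairwise_ds(cl, "A", "C", "ta", t_min = 2), 0)
  expect_equal(pairwise_ds(cl, "A", "B", "ta", t_min = 2),
               pairwise_ds(cl, "B", "A", "ta", t_min = 2))
  # overlap below t_min is undefined
  expect_true(is.na(pairwise_ds(cl, "A", "B", "ta", t_min = 30)))
  # static factor: absolute difference of scalars
  recs <- tibble::tibble(station_id = c("X", "Y"), year = 2019, doy = 1,
                         ta = 0, elev = c(100, 130))
  cls <- doy_climatology(recs)
  expect_equal(pairwise_ds(cls, "X", "Y", "elev"), 30)
})

test_that("distances agree with a brute-force loop on 100 random station-factor pairs", {
  cl <- small_clim()
  ids <- names(cl$daily)
  factors <- c(cl$daily_factors, cl$static_factors)
  set.seed(99)
  dmats <- distance_matrices(cl, ids, ids, factors, t_min = 30)
  for (i in 1:100) {
    pair <- sample(ids, 2)
    f <- sample(factors, 1)
    if (f %in% cl$static_factors) {
      want <- abs(cl$static[pair[1], f] - cl$static[pair[2], f])
    } else {
      x <- cl$daily[[pair[1]]][, f]; y <- cl$daily[[pair[2]]][, f]
      ok <- !is.na(x) & !is.na(y)
      want <- sqrt(sum((x[ok] - y[ok])^2))
    }
    expect_equal(pairwise_ds(cl, pair[1], pair[2], f), want, tolerance = 1e-12)
    expect_equal(unname(dmats[[f]][pair[1], pair[2]]), want, tolerance = 1e-12)
  }
})

test_that("training-set distance is the mean over defined pairs, matching a brute-force oracle", {
  cl <- clim_of(list(T = rep(0, 40), A = rep(1, 40), B = rep(2, 40), C = rep(6, 40)))
  # ds values are sqrt(40)*c(1,2,6); mean = sqrt(40)*3
  expect_equal(training_set_distance(cl, "T", c("A", "B", "C"), "ta"),
               sqrt(40) * 3, tolerance = 1e-12)
  expect_equal(training_set_distance(cl, "T", "A", "ta"), sqrt(40))
  # random instance against an explicit loop
  cl2 <- small_clim()
  ids <- names(cl2$daily)
  brute <- mean(sapply(ids[2:6], function(y) pairwise_ds(cl2, ids[1], y, "dsr")))
  expect_equal(training_set_distance(cl2, ids[1], ids[2:6], "dsr"), brute,
               tolerance = 1e-12)
})

test_that("pairwise distance is a metric on shared-coverage climatologies", {
  cl <- small_clim()
  ids <- names(cl$daily)
  set.seed(4)
  for (i in 1:30) {
    tri <- sample(ids, 3)
    f <- sample(cl$daily_factors, 1)
    dxy <- pairwise_ds(cl, tri[1], tri[2], f)
    dyz <- pairwise_ds(cl, tri[2], tri[3], f)
    dxz <- pairwise_ds(cl, tri[1], tri[3], f)
    expect_lte(dxz, dxy + dyz + 1e-9)
    expect_gte(dxy, 0)
  }
})

test_that("the R2-simulation model recovers exact linear data and the OLS normal equations", {
  set.seed(12)
  d <- tibble::tibble(d_a = runif(60, 0, 4), d_b = runif(60, 0, 10))
  d$r2 <- 0.9 - 0.05 * d$d_a - 0.02 * d$d_b
  rsm <- suppressWarnings(fit_rsm(d))
  expect_equal(unname(rsm$coefficients), c(0.9, -0.05, -0.02), tolerance = 1e-8)
  expect_equal(rsm$r_squared, 1, tolerance = 1e-8)
  # constant response: zero slopes, intercept at the constant
  dc <- dplyr::mutate(d, r2 = 0.42)
  rsmc <- suppressWarnings(fit_rsm(dc))
  expect_equal(unname(rsmc$coefficients["(Intercept)"]), 0.42, tolerance = 1e-10)
  expect_equal(unname(rsmc$coefficients[-1]), c(0, 0), tolerance = 1e-10)
  # 50 random samples, 3 factors: match solve(X'X, X'y)
  set.seed(13)
  X <- cbind(1, matrix(runif(150), 50, 3))
  y <- runif(50)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  dd <- tibble::tibble(d_1 = X[, 2], d_2 = X[, 3], d_3 = X[, 4], r2 = y)
  expect_equal(unname(fit_rsm(dd)$coefficients), drop(beta), tolerance = 1e-8)
  # intercept model: mean of fitted values equals mean of observations
  rsm3 <- fit_rsm(dd)
  expect_equal(mean(rsm3$fit$fitted.values), mean(y), tolerance = 1e-9)
  # too few samples refused
  expect_error(fit_rsm(dd[1:4, ]), "w \\+ 2")
})

test_that("predicted R2 is the intercept plus dot product, unclamped", {
  d <- tibble::tibble(d_a = c(2, 0, 4), d_b = c(0, 0, 5))
  d$r2 <- 0.8 - 0.1 * d$d_a - 0.0 * d$d_b
  # build an rsm with known coefficients via exact data
  dn <- tibble::tibble(d_a = runif(30, 0, 4), d_b = runif(30, 0, 6))
  dn$r2 <- 0.9 - 0.05 * dn$d_a - 0.02 * dn$d_b
  rsm <- suppressWarnings(fit_rsm(dn))
  expect_equal(predict_r2(rsm, c(d_a = 0, d_b = 0)), 0.9, tolerance = 1e-8)
  expect_equal(predict_r2(rsm, c(d_a = 4, d_b = 5)), 0.9 - 0.2 - 0.1, tolerance = 1e-8)
  # names without the d_ prefix are accepted; missing terms error
  expect_equal(predict_r2(rsm, c(a = 4, b = 5)), 0.6, tolerance = 1e-8)
  expect_error(predict_r2(rsm, c(d_a = 1)), "lacks")
  # unclamped beyond [0, 1]
  expect_lt(predict_r2(rsm, c(d_a = 40, d_b = 40)), 0)
})

test_that("quality classes bin at 0.5 and 0.7 inclusively and accuracy counts matches", {
  expect_equal(quality_class(c(0.49, 0.5, 0.69, 0.7, 1.3)), c(1L, 2L, 2L, 3L, 3L))
  expect_equal(classification_accuracy(c(0.4, 0.6, 0.8), c(0.45, 0.65, 0.55)), 2 / 3)
  expect_equal(classification_accuracy(c(0.4, 0.6), c(0.4, 0.6)), 1)
  expect_error(classification_accuracy(1, numeric(0)), "equal length")
})

test_that("Dataset 1 pairs each evaluation with the distances to that model's training set", {
  fx <- mini_run()
  run <- fx$run
  d1 <- run$dataset1[["Overall_WRS_WF"]]
  n <- sum(run$network$meta$role == "flux")
  expect_equal(nrow(d1), n * fx$config$p - attr(d1, "n_excluded"))
  # spot-check one sample against direct recomputation
  clim <- doy_climatology(preprocess_records(run$network$records))
  row <- d1[7, ]
  m <- run$models[[row$rfm_id]]
  for (f in c("ta", "elev")) {
    expect_equal(unname(row[[paste0("d_", f)]]),
                 training_set_distance(clim, row$station_id,
                                       m$training_station_ids, f),
                 tolerance = 1e-9)
  }
})
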