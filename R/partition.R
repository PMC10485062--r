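#' Map IGBP land-cover classes to the four landscape groups
#'
#' Groups the International Geosphere-Biosphere Programme classes:
#' permanent wetlands -> Wetland; croplands and cropland/natural vegetation
#' mosaics -> Cropland; grasslands, savannas and woody savannas -> Grassland;
#' the five forest classes -> Forest.
#'
#' @param igbp Character vector of IGBP class names (case-insensitive).
#' @return Character vector of landscape groups.
#' @export
igbp_landscape <- function(igbp) {
  map <- c(
    "permanent wetlands" = "Wetland",
    "croplands" = "Cropland",
    "cropland/natural vegetation mosaics" = "Cropland",
    "grasslands" = "Grassland",
    "savannas" = "Grassland",
    "woody savannas" = "Grassland",
    "evergreen needleleaf forests" = "Forest",
    "evergreen broadleaf forests" = "Forest",
    "deciduous needleleaf forests" = "Forest",
    "deciduous broadleaf forests" = "Forest",
    "mixed forests" = "Forest"
  )
  key <- tolower(trimws(igbp))
  unknown <- setdiff(unique(key), names(map))
  if (length(unknown)) {
    abort_bad_arg(paste0("unknown IGBP class(es): ", paste(unknown, collapse = ", ")))
  }
  unname(map[key])
}

#' Assign each station to its four categories
#'
#' Every station belongs to exactly four of the nine categories: one landscape
#' group (from its IGBP class), one continent, one aridity class (Arid iff
#' aridity index < 0.65) and Overall.
#'
#' @param meta Station metadata with columns `station_id`, `igbp` (or a
#'   `landscape` column already holding a group name), `continent`,
#'   `aridity_index`.
#' @return A tibble `(station_id, category)` in long form, four rows per
#'   station, with `category` a factor over [category_levels()].
#' @examples
#' meta <- tibble::tibble(station_id = "S1", igbp = "woody savannas",
#'                        continent = "Asia", aridity_index = 0.30)
#' assign_categories(meta)
#' @export
assign_categories <- function(meta) {
  meta <- tibble::as_tibble(meta)
  landscape <- if ("landscape" %in% names(meta)) meta$landscape else igbp_landscape(meta$igbp)
  stopifnot(all(landscape %in% category_levels()[1:4]),
            all(meta$continent %in% c("Asia", "Europe")))
  aridity <- ifelse(meta$aridity_index < 0.65, "Arid", "NonArid")
  out <- tibble::tibble(
    station_id = rep(meta$station_id, 4),
    category = c(landscape, meta$continent, aridity, rep("Overall", nrow(meta)))
  )
  out$category <- factor(out$category, levels = category_levels())
  dplyr::arrange(out, .data$station_id, .data$category)
}

#' Build the grouped k-fold cross-validation plan for one category
#'
#' Whole stations (never station-days) are shuffled and partitioned into `k`
#' near-equal folds, independently for each of `p` splits. Within a split
#' every station sits in exactly one test fold; fold sizes differ by at most
#' one when `k` does not divide `n`.
#'
#' @param station_ids Character vector of the category's station ids.
#' @param k Folds per split (2 <= k <= n).
#' @param p Number of repeated splits (>= 1).
#' @param seed Integer seed fixing the plan.
#' @return A tibble `(split, fold, station_id)` with `p * n` rows.
#' @export
make_cv_plan <- function(station_ids, k = 10, p = 10, seed = 1L) {
  n <- length(station_ids)
  if (k < 2 || n < k) abort_bad_arg("need n >= k >= 2 stations")
  if (p < 1) abort_bad_arg("`p` must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  purrr::map_dfr(seq_len(p), function(s) {
    shuffled <- sample(station_ids)
    sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
    tibble::tibble(
      split = s,
      fold = rep(seq_len(k), times = sizes),
      station_id = shuffled
    )
  })
}

#' Enumerate every model-training task of the framework
#'
#' One task per (category, scenario, target, split, fold). With the nine
#' categories, p = k = 10, two scenarios and two targets this enumerates the
#' full design of 3,600 models (900 per scenario-target pair).
#'
#' @param partitions Tibble `(category, station_id)` of flux-station category
#'   membership (e.g. from [assign_categories()] filtered to flux stations).
#' @param scenarios Character vector among `"RS"`, `"WRS"`.
#' @param targets Character vector among `"NEE"`, `"WF"`.
#' @param k,p Folds per split and number of splits.
#' @return A tibble `(category, scenario, target, split, fold)`.
#' @export
enumerate_training_plan <- function(partitions, scenarios = c("RS", "WRS"),
                                    targets = c("NEE", "WF"), k = 10, p = 10) {
  cats <- unique(as.character(partitions$category))
  tidyr::expand_grid(
    category = cats,
    scenario = scenarios,
    target = targets,
    split = seq_len(p),
    fold = seq_len(k)
  )
}
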