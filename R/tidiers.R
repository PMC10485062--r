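#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy the coefficients of an R2-simulation model
#'
#' @param x An `rsm` object.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.rsm <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' One-row fit summary of an R2-simulation model
#'
#' @param x An `rsm` object.
#' @param ... Unused.
#' @return A tibble with `category`, `scenario`, `target`, `n`, `r.squared`,
#'   `adj.r.squared`, `statistic` (F), `p.value`, `n_dropped_terms`.
#' @export
glance.rsm <- function(x, ...) {
  tibble::tibble(
    category = x$category, scenario = x$scenario, target = x$target,
    n = x$n, r.squared = x$r_squared, adj.r.squared = x$adj_r_squared,
    statistic = x$f_statistic, p.value = x$p_value,
    n_dropped_terms = length(x$dropped)
  )
}

#' Box plot of per-station cross-validation R2 by split
#'
#' Mirrors the usual presentation of grouped-CV skill: one box per split,
#' each holding the test stations' R2 values of that split.
#'
#' @param evaluations Evaluations tibble from [run_cv()] or a full store.
#' @param floor_r2 Values below this are clipped for display (default -1).
#' @return A ggplot object.
#' @export
plot_cv_r2 <- function(evaluations, floor_r2 = -1) {
  ev <- dplyr::filter(evaluations, !is.na(.data$r2))
  ev$r2 <- pmax(ev$r2, floor_r2)
  ggplot2::ggplot(ev, ggplot2::aes(x = factor(.data$split), y = .data$r2)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey40") +
    ggplot2::facet_grid(target ~ scenario) +
    ggplot2::labs(x = "Split", y = expression(R^2)) +
    ggplot2::theme_bw()
}

#' Predicted versus realized R2 for an R2-simulation model
#'
#' @param object An `rsm` object.
#' @param ... Unused.
#' @return A ggplot object: fitted (predicted) against observed test-station
#'   R2, with the 1:1 line and the quality-class boundaries.
#' @export
autoplot.rsm <- function(object, ...) {
  df <- tibble::tibble(observed = object$fit$model$r2,
                       predicted = object$fit$fitted.values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(0.5, 0.7), linetype = "dotted") +
    ggplot2::geom_vline(xintercept = c(0.5, 0.7), linetype = "dotted") +
    ggplot2::labs(
      title = paste(object$category, object$scenario, object$target),
      x = expression("Realized test-station" ~ R^2),
      y = expression("RSM-predicted" ~ R^2)
    ) +
    ggplot2::theme_bw()
}

#' Transfer decisions overview
#'
#' Bar chart of the met-station quality classes per scenario and target.
#'
#' @param decisions Decisions tibble from a pipeline run.
#' @return A ggplot object.
#' @export
plot_transfer_decisions <- function(decisions) {
  ggplot2::ggplot(decisions,
                  ggplot2::aes(x = factor(.data$quality_class))) +
    ggplot2::geom_bar() +
    ggplot2::facet_grid(target ~ scenario) +
    ggplot2::labs(x = "Quality class (1 low, 2 moderate, 3 high)",
                  y = "Met stations") +
    ggplot2::theme_bw()
}
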