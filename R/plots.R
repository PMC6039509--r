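#' Plot a fitted detection curve over the observed detection rates
#'
#' @param object A `detection_glm`.
#' @param ... Unused.
#' @return A ggplot: observed per-cell detection rates against log
#'   standardized reads, with the pooled fitted curve (per-MOTU curves
#'   for per-MOTU forms).
#' @export
autoplot.detection_glm <- function(object, ...) {
  rec <- object$records
  grid <- seq(min(rec$log_reads), max(rec$log_reads), length.out = 200)
  cf <- detection_coefficients(object)
  curves <- tidyr::crossing(cf, log_reads = grid) |>
    dplyr::mutate(p = inv_logit(.data$intercept + .data$slope * .data$log_reads))
  p <- ggplot2::ggplot(rec, ggplot2::aes(x = .data$log_reads)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$k / .data$R),
                        shape = 3, alpha = 0.4, colour = "grey40") +
    ggplot2::labs(x = "standardized reads (ln)", y = "detection rate")
  if (object$model_form == "pooled") {
    p + ggplot2::geom_line(data = curves,
                           ggplot2::aes(y = .data$p), colour = "red")
  } else {
    p + ggplot2::geom_line(data = curves,
                           ggplot2::aes(y = .data$p, group = .data$motu),
                           colour = "steelblue", alpha = 0.7)
  }
}

#' Plot a Mantel correlogram
#'
#' @param object A `correlogram_result`.
#' @param ... Unused.
#' @return A ggplot of the per-class Mantel statistic against class
#'   midpoint, filled points for significant classes, with the
#'   autocorrelation extent marked.
#' @export
autoplot.correlogram_result <- function(object, ...) {
  cl <- dplyr::filter(object$classes, !is.na(.data$r))
  ggplot2::ggplot(cl, ggplot2::aes(x = .data$midpoint_km, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2.5) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white")) +
    ggplot2::geom_vline(xintercept = object$extent_km, linetype = 3) +
    ggplot2::labs(x = "distance class midpoint (km)", y = "Mantel r",
                  fill = paste0("p < ", object$alpha))
}

#' Plot co-inertia section scores of the two coupled tables
#'
#' @param object A `coinertia_result`.
#' @param axis Co-inertia axis to display (default 1).
#' @param ... Unused.
#' @return A ggplot of one table's section scores against the other's on
#'   the chosen co-inertia axis, with the identity line.
#' @export
autoplot.coinertia_result <- function(object, axis = 1, ...) {
  df <- tibble::tibble(site = rownames(object$scores_x),
                       x = scale(object$scores_x[, axis])[, 1],
                       y = scale(object$scores_y[, axis])[, 1])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste0("table X, co-inertia axis ", axis,
                             " (standardized)"),
                  y = paste0("table Y, co-inertia axis ", axis,
                             " (standardized)"))
}

#' Plot an observed and fitted distance-decay detection curve
#'
#' @param object A `distance_decay`.
#' @param ... Unused.
#' @return A ggplot: observed detection rates against distance, fitted
#'   curve with a +/- 1 SE prediction band.
#' @export
autoplot.distance_decay <- function(object, ...) {
  det <- object$detections
  grid <- data.frame(distance_km = seq(0, max(det$distance_km),
                                       length.out = 200))
  pr <- predict(object$fit, newdata = grid, se.fit = TRUE)
  grid$p <- inv_logit(pr$fit)
  grid$lo <- inv_logit(pr$fit - pr$se.fit)
  grid$hi <- inv_logit(pr$fit + pr$se.fit)
  ggplot2::ggplot(det, ggplot2::aes(x = .data$distance_km)) +
    ggplot2::geom_ribbon(data = grid,
                         ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$pcr_positive / .data$pcr_total)) +
    ggplot2::labs(x = "distance downstream (km)", y = "detection rate")
}

#' Plot predicted detection distances per reach
#'
#' @param predictions Tibble from [predict_detection_table()].
#' @return A ggplot of predicted distance (log scale) with interquartile
#'   bounds per reach.
#' @export
plot_detection_predictions <- function(predictions) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = stats::reorder(.data$label,
                                                  .data$predicted_km),
                               y = .data$predicted_km)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower_km,
                                          ymax = .data$upper_km)) +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "predicted detection distance (km)")
}
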