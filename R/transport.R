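#' Summarize literature deposition velocities
#'
#' Median and quartiles (linear-interpolation convention) of fine
#' particulate organic matter deposition velocities, the vertical
#' transfer rate from the water column to the riverbed that eDNA is
#' assumed to share.
#'
#' @param values Deposition velocities in mm/s, all positive.
#' @return One-row tibble: `n`, `q1`, `median`, `q3` (mm/s).
#' @export
vdep_summary <- function(values) {
  if (length(values) < 1) abort("need at least one deposition velocity")
  if (any(values <= 0)) abort("deposition velocities must be positive")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(n = length(values), q1 = q[1], median = q[2], q3 = q[3])
}

#' e-folding transport length of suspended particles
#'
#' The deposition velocity V_dep relates to the transport length Sp by
#' V_dep = u * h / Sp, with u the mean water velocity and h the mean
#' depth; Sp is the distance over which 63.2% of suspended particles
#' settle to the bed (the e-folding length of first-order loss). Under a
#' rectangular channel cross-section, u * h = Q / w, so discharge and
#' wetted width suffice.
#'
#' @param v_dep_mm_s Deposition velocity in mm/s.
#' @param discharge_q Mean discharge Q in m^3/s.
#' @param wetted_width_w Mean wetted width w in m.
#' @param velocity_u,depth_h Mean velocity (m/s) and depth (m); an
#'   alternative to (Q, w).
#' @return Transport length Sp in metres (vectorized over reaches).
#' @export
transport_length <- function(v_dep_mm_s, discharge_q = NULL,
                             wetted_width_w = NULL, velocity_u = NULL,
                             depth_h = NULL) {
  if (any(v_dep_mm_s <= 0)) abort("v_dep must be positive")
  uh <- if (!is.null(velocity_u) && !is.null(depth_h)) {
    velocity_u * depth_h
  } else if (!is.null(discharge_q) && !is.null(wetted_width_w)) {
    if (any(discharge_q <= 0) || any(wetted_width_w <= 0)) {
      abort("discharge and wetted width must be positive")
    }
    discharge_q / wetted_width_w
  } else {
    abort("supply either (velocity_u, depth_h) or (discharge_q, wetted_width_w)")
  }
  uh / (v_dep_mm_s / 1000)
}

#' Fraction of released eDNA still suspended after transport
#'
#' First-order loss: exp(-x / Sp). Over one transport length 36.8%
#' remains suspended, i.e. 63.2% has settled to the bed.
#'
#' @param distance_x Downstream distance in m (>= 0).
#' @param sp Transport length Sp in m (> 0).
#' @param decay_rate Additional first-order decay rate per metre
#'   (e.g. degradation); default 0 — degradation during transport is
#'   deliberately not modelled.
#' @return Proportion remaining in the water column.
#' @export
remaining_fraction <- function(distance_x, sp, decay_rate = 0) {
  if (any(sp <= 0)) abort("sp must be positive")
  if (any(distance_x < 0)) abort("distance must be non-negative")
  exp(-distance_x * (1 / sp + decay_rate))
}

#' Maximal downstream eDNA detection distance
#'
#' Distance at which an upstream release has decayed to the detection
#' threshold: with N0 = source concentration x sample volume copies in a
#' sample taken at the source, the copies at distance x are
#' N0 * exp(-x / Sp), so the last distance with at least `threshold`
#' copies is x* = Sp * ln(N0 / threshold).
#'
#' @inheritParams transport_length
#' @param source_concentration Released copies per litre (default 2000).
#' @param sample_volume Sampled volume in litres (default 2.5).
#' @param detection_threshold Copies needed for a detection (default 1).
#' @return Distance in km. If the initial copies do not exceed the
#'   threshold, 0 with a warning.
#' @export
max_detection_distance <- function(v_dep_mm_s, discharge_q = NULL,
                                   wetted_width_w = NULL, velocity_u = NULL,
                                   depth_h = NULL,
                                   source_concentration = 2000,
                                   sample_volume = 2.5,
                                   detection_threshold = 1) {
  copies <- source_concentration * sample_volume
  if (copies <= detection_threshold) {
    warn("initial copies do not exceed the detection threshold; distance is 0")
    return(0)
  }
  sp <- transport_length(v_dep_mm_s, discharge_q, wetted_width_w,
                         velocity_u, depth_h)
  sp * log(copies / detection_threshold) / 1000
}

#' Predicted detection distances for a set of reaches
#'
#' Applies [max_detection_distance()] to each reach at the median
#' literature deposition velocity and at its interquartile bounds. Note
#' the inversion: the upper quartile of V_dep (fast settling) gives the
#' LOWER distance bound.
#'
#' @param reaches Tibble with columns `label`, `discharge_q` (m^3/s),
#'   `wetted_width_w` (m); extra columns are carried through.
#' @param vdep One-row tibble from [vdep_summary()] (mm/s).
#' @param source_concentration,sample_volume,detection_threshold Release
#'   scenario, see [max_detection_distance()].
#' @return Tibble with per-reach `sp_m` (at the median V_dep),
#'   `predicted_km`, `lower_km`, `upper_km`, and a formatted
#'   `predicted` string (m below 1 km, km otherwise).
#' @export
predict_detection_table <- function(reaches, vdep,
                                    source_concentration = 2000,
                                    sample_volume = 2.5,
                                    detection_threshold = 1) {
  if (nrow(reaches) == 0) {
    return(tibble::tibble(label = character(), discharge_q = numeric(),
                          wetted_width_w = numeric(), sp_m = numeric(),
                          predicted_km = numeric(), lower_km = numeric(),
                          upper_km = numeric(), predicted = character()))
  }
  dist_at <- function(v) {
    max_detection_distance(v, reaches$discharge_q, reaches$wetted_width_w,
                           source_concentration = source_concentration,
                           sample_volume = sample_volume,
                           detection_threshold = detection_threshold)
  }
  reaches |>
    dplyr::mutate(
      sp_m = transport_length(vdep$median, .data$discharge_q,
                              .data$wetted_width_w),
      predicted_km = dist_at(vdep$median),
      lower_km = dist_at(vdep$q3),
      upper_km = dist_at(vdep$q1),
      predicted = format_distance(.data$predicted_km))
}

format_distance <- function(km) {
  ifelse(km < 1, paste0(round(km * 1000), " m"),
         paste0(round(km, 1), " km"))
}

#' Fit a distance-decay detection curve
#'
#' Binomial-logit GLM of per-site PCR detection rate on downstream
#' distance from an eDNA source (e.g. a lake outlet releasing DNA of a
#' lake-dwelling species): logit(p) = a + b * distance, response k
#' positives in R replicates.
#'
#' @param detections Tibble with columns `distance_km`, `pcr_positive`,
#'   `pcr_total`.
#' @return A `distance_decay` object wrapping the GLM; supports
#'   [tidy()], [glance()], [distance_at_rate()] and [autoplot()].
#' @export
fit_distance_decay <- function(detections) {
  stopifnot(all(c("distance_km", "pcr_positive", "pcr_total") %in%
                  names(detections)))
  if (length(unique(detections$distance_km)) < 3) {
    abort("need at least 3 distinct distances")
  }
  fit <- glm(cbind(pcr_positive, pcr_total - pcr_positive) ~ distance_km,
             family = binomial(), data = detections,
             control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  structure(list(fit = fit, detections = tibble::as_tibble(detections),
                 intercept = coef(fit)[[1]],
                 slope = coef(fit)[["distance_km"]]),
            class = "distance_decay")
}

#' @export
print.distance_decay <- function(x, ...) {
  cat(sprintf("Distance-decay detection model: logit(p) = %.3f %+.4f * km\n",
              x$intercept, x$slope))
  invisible(x)
}

#' Distance at which the detection rate crosses a threshold
#'
#' Inverts the mean fitted curve of a [fit_distance_decay()] model at
#' `logit(target_rate)`, and brackets it by inverting the mean +/- 1
#' standard-error prediction curves (the near bound comes from the upper
#' curve, the far bound from the lower one).
#'
#' @param fit A `distance_decay` object with negative slope.
#' @param target_rate Detection rate to invert at (default 0.04, i.e.
#'   less than 1 positive out of 24 replicates).
#' @return One-row tibble: `target_rate`, `distance_km`, `lower_km`,
#'   `upper_km`.
#' @export
distance_at_rate <- function(fit, target_rate = 0.04) {
  stopifnot(inherits(fit, "distance_decay"))
  if (fit$slope >= 0) abort("non-negative slope: detection does not decay with distance")
  if (target_rate <= 0 || target_rate >= 1) {
    abort("target_rate must lie strictly between 0 and 1")
  }
  target <- logit(target_rate)
  central <- (target - fit$intercept) / fit$slope
  band <- function(sign) {
    f <- function(x) {
      pr <- predict(fit$fit, newdata = data.frame(distance_km = x),
                    se.fit = TRUE)
      pr$fit + sign * pr$se.fit - target
    }
    upper_x <- max(central * 10, max(fit$detections$distance_km) * 10, 1)
    tryCatch(uniroot(f, lower = 0, upper = upper_x)$root,
             error = function(e) NA_real_)
  }
  tibble::tibble(target_rate = target_rate, distance_km = central,
                 lower_km = band(-1), upper_km = band(1))
}
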