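#' @export
tidy.detection_glm <- function(x, ...) {
  if (x$model_form == "per_motu") {
    return(purrr::imap_dfr(x$fit, function(f, nm) {
      sm <- summary(f)$coefficients
      tibble::tibble(motu = nm, term = rownames(sm),
                     estimate = sm[, "Estimate"],
                     std_error = sm[, "Std. Error"],
                     p_value = sm[, "Pr(>|z|)"])
    }))
  }
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                 std_error = sm[, "Std. Error"],
                 p_value = sm[, "Pr(>|z|)"])
}

#' @export
glance.detection_glm <- function(x, ...) {
  tibble::tibble(model_form = x$model_form,
                 n_records = nrow(x$records),
                 n_parameters = x$n_parameters,
                 null_deviance = x$null_deviance,
                 residual_deviance = x$residual_deviance,
                 explained_deviance = x$explained_deviance)
}

#' @export
tidy.pca_result <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  m <- x[[matrix]]
  id <- if (matrix == "scores") "site" else "species"
  out <- tibble::as_tibble(m, rownames = id)
  tidyr::pivot_longer(out, cols = -1, names_to = "axis", values_to = "value")
}

#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(n_axes = x$n_axes,
                 total_inertia = sum(x$eigenvalues),
                 inertia_retained = sum(x$inertia_fraction[seq_len(x$n_axes)]))
}

#' @export
tidy.coinertia_result <- function(x, ...) {
  tibble::tibble(site = rownames(x$scores_x),
                 axis1_x = x$scores_x[, 1], axis2_x = x$scores_x[, 2],
                 axis1_y = x$scores_y[, 1], axis2_y = x$scores_y[, 2])
}

#' @export
glance.coinertia_result <- function(x, ...) {
  tibble::tibble(rv = x$rv, permutation_p = x$permutation_p,
                 inertia_axis1 = x$inertia_fraction[1],
                 inertia_axis2 = if (length(x$inertia_fraction) > 1) {
                   x$inertia_fraction[2]
                 } else NA_real_)
}

#' @export
tidy.correlogram_result <- function(x, ...) x$classes

#' @export
glance.correlogram_result <- function(x, ...) {
  tibble::tibble(extent_km = x$extent_km, n_classes = nrow(x$classes),
                 class_width_km = x$class_width_km, n_perm = x$n_perm,
                 alpha = x$alpha)
}

#' @export
tidy.distance_decay <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                 std_error = sm[, "Std. Error"],
                 p_value = sm[, "Pr(>|z|)"])
}

#' @export
glance.distance_decay <- function(x, ...) {
  tibble::tibble(n_sites = nrow(x$detections),
                 null_deviance = x$fit$null.deviance,
                 residual_deviance = x$fit$deviance,
                 explained_deviance = 1 - x$fit$deviance / x$fit$null.deviance)
}

#' @export
tidy.richness_comparison <- function(x, ...) x$per_location

#' @export
glance.richness_comparison <- function(x, ...) x$cross_location
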