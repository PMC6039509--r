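#' Select MOTUs suitable for detection-rate modelling
#'
#' A MOTU enters the detection model only if it is observed widely enough
#' to anchor a logistic curve: present (reads > 0) in more than
#' `min_sites` sites and with positive-PCR counts covering at least the
#' range `[k_min, k_max]` across its sites, so the steep part of the
#' curve is represented.
#'
#' @param tbl A long MOTU table with PCR columns.
#' @param min_sites A MOTU must be present in strictly more than this
#'   many sites (default 10).
#' @param k_min,k_max The observed positive-PCR counts of a MOTU must
#'   extend down to `k_min` and up to `k_max` (defaults 3 and 23, i.e.
#'   most of the 0--24 detection range).
#' @return Character vector of qualifying MOTU identifiers.
#' @export
select_modelable_motus <- function(tbl, min_sites = 10L, k_min = 3L, k_max = 23L) {
  if (nrow(tbl) == 0) return(character())
  validate_motu_table(tbl)
  if (!"pcr_positive" %in% names(tbl)) abort("table lacks pcr_positive")
  tbl |>
    dplyr::filter(.data$reads > 0) |>
    dplyr::group_by(.data$motu) |>
    dplyr::summarise(n_sites = dplyr::n(),
                     kmin = min(.data$pcr_positive),
                     kmax = max(.data$pcr_positive), .groups = "drop") |>
    dplyr::filter(.data$n_sites > min_sites,
                  .data$kmin <= k_min, .data$kmax >= k_max) |>
    dplyr::pull("motu")
}

#' Assemble detection records for GLM fitting
#'
#' One record per (site, MOTU) cell with positive standardized reads:
#' the natural log of the read count as covariate, and the positive-PCR
#' count out of the total replicates as a grouped binomial response.
#' Cells with zero reads carry no log-read covariate and are excluded;
#' any excluded cell that nonetheless had positive PCRs is reported via
#' a message so the exclusion is auditable.
#'
#' @param tbl A long MOTU table with PCR columns (typically rarefied).
#' @param motus Optional character vector restricting the records to
#'   these MOTUs (e.g. from [select_modelable_motus()]).
#' @return Tibble with columns `motu`, `site`, `log_reads`, `k`, `R`.
#' @export
detection_records <- function(tbl, motus = NULL) {
  validate_motu_table(tbl)
  if (!all(c("pcr_positive", "pcr_total") %in% names(tbl))) {
    abort("table lacks PCR columns (pcr_positive, pcr_total)")
  }
  if (!is.null(motus)) tbl <- dplyr::filter(tbl, .data$motu %in% motus)
  dropped <- sum(tbl$reads == 0 & tbl$pcr_positive > 0)
  if (dropped > 0) {
    inform(paste0(dropped, " record(s) with positive PCR but zero reads excluded from fitting"))
  }
  tbl |>
    dplyr::filter(.data$reads > 0) |>
    dplyr::transmute(motu = .data$motu, site = .data$site,
                     log_reads = log(.data$reads),
                     k = .data$pcr_positive, R = .data$pcr_total)
}

#' Fit a binomial-logit detection model
#'
#' Models the probability that one PCR replicate amplifies a MOTU as a
#' logistic function of the log standardized read count:
#' `logit(p) = a + b * log(reads)`. The response is the grouped binomial
#' count of `k` positives in `R` replicates. Four forms are supported:
#'
#' * `"pooled"` — one shared curve for all MOTUs;
#' * `"identity"` — shared slope, per-MOTU intercepts;
#' * `"identity_interaction"` — per-MOTU intercepts and slopes in one
#'   model (`log_reads * motu`);
#' * `"per_motu"` — fully separate fits, one per MOTU.
#'
#' @param records Tibble from [detection_records()].
#' @param model_form One of the forms above.
#' @return A `detection_glm` object with the fit(s), deviances and the
#'   fraction of null deviance explained. Supports [tidy()], [glance()],
#'   [predict_detection()], [invert_abundance_at_rate()] and
#'   [autoplot()].
#' @export
fit_detection_glm <- function(records,
                              model_form = c("pooled", "identity",
                                             "identity_interaction", "per_motu")) {
  model_form <- match.arg(model_form)
  if (length(unique(records$log_reads)) < 2) {
    abort("need at least 2 distinct log_reads values")
  }
  if (model_form %in% c("identity", "identity_interaction", "per_motu") &&
      length(unique(records$motu)) < 2 && model_form != "per_motu") {
    abort("per-MOTU terms need at least 2 MOTUs")
  }
  records$motu <- factor(records$motu)
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  fit_one <- function(df, formula) {
    withCallingHandlers(
      glm(formula, family = binomial(), data = df, control = ctrl),
      warning = function(w) {
        # perfect separation / fitted 0-1 probabilities: keep coefficients
        inform(paste0("detection GLM: ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  if (model_form == "per_motu") {
    fits <- records |>
      dplyr::group_by(.data$motu) |>
      dplyr::group_split() |>
      purrr::map(~ fit_one(.x, cbind(k, R - k) ~ log_reads))
    names(fits) <- purrr::map_chr(
      dplyr::group_split(dplyr::group_by(records, .data$motu)),
      ~ as.character(.x$motu[1]))
    null_dev <- sum(purrr::map_dbl(fits, ~ .x$null.deviance))
    resid_dev <- sum(purrr::map_dbl(fits, ~ .x$deviance))
    fit <- fits
  } else {
    formula <- switch(model_form,
                      pooled = cbind(k, R - k) ~ log_reads,
                      identity = cbind(k, R - k) ~ log_reads + motu,
                      identity_interaction = cbind(k, R - k) ~ log_reads * motu)
    fit <- fit_one(records, formula)
    null_dev <- fit$null.deviance
    resid_dev <- fit$deviance
  }
  structure(list(model_form = model_form,
                 fit = fit,
                 records = tibble::as_tibble(records),
                 null_deviance = null_dev,
                 residual_deviance = resid_dev,
                 explained_deviance = 1 - resid_dev / null_dev,
                 n_parameters = if (model_form == "per_motu") {
                   2L * length(fit)
                 } else {
                   length(coef(fit))
                 }),
            class = "detection_glm")
}

#' @export
print.detection_glm <- function(x, ...) {
  cat("Binomial-logit detection model (", x$model_form, ")\n", sep = "")
  cat(sprintf("  records: %d   MOTUs: %d\n", nrow(x$records),
              length(unique(x$records$motu))))
  cat(sprintf("  null deviance: %.2f   residual: %.2f   explained: %.1f%%\n",
              x$null_deviance, x$residual_deviance,
              100 * x$explained_deviance))
  invisible(x)
}

#' Per-MOTU intercept and slope of a detection model
#'
#' Resolves factor contrasts (or the per-MOTU fits) to one absolute
#' `(intercept, slope)` pair per MOTU; the pooled form returns a single
#' row labelled `.pooled`.
#'
#' @param fit A `detection_glm`.
#' @return Tibble with columns `motu`, `intercept`, `slope`.
#' @export
detection_coefficients <- function(fit) {
  stopifnot(inherits(fit, "detection_glm"))
  if (fit$model_form == "pooled") {
    cf <- coef(fit$fit)
    return(tibble::tibble(motu = ".pooled", intercept = cf[[1]],
                          slope = cf[["log_reads"]]))
  }
  if (fit$model_form == "per_motu") {
    return(purrr::imap_dfr(fit$fit, function(f, nm) {
      cf <- coef(f)
      tibble::tibble(motu = nm, intercept = cf[[1]], slope = cf[["log_reads"]])
    }))
  }
  motus <- levels(factor(fit$records$motu))
  cf <- coef(fit$fit)
  purrr::map_dfr(motus, function(m) {
    a <- cf[["(Intercept)"]] +
      (cf[paste0("motu", m)] %|na|% 0)
    b <- cf[["log_reads"]] +
      if (fit$model_form == "identity_interaction") {
        cf[paste0("log_reads:motu", m)] %|na|% 0
      } else 0
    tibble::tibble(motu = m, intercept = unname(a), slope = unname(b))
  })
}

`%|na|%` <- function(x, y) {
  if (length(x) == 0 || is.na(x)) y else x
}

#' Predicted detection rate at given log read counts
#'
#' @param fit A `detection_glm`.
#' @param log_reads Numeric vector of natural-log standardized read counts.
#' @param motu MOTU identifier for per-MOTU forms; ignored for the pooled
#'   form.
#' @return Numeric vector of detection probabilities.
#' @export
predict_detection <- function(fit, log_reads, motu = NULL) {
  cf <- detection_coefficients(fit)
  if (fit$model_form == "pooled") {
    row <- cf
  } else {
    if (is.null(motu)) abort("motu required for per-MOTU model forms")
    row <- cf[cf$motu == motu, ]
    if (nrow(row) == 0) abort(paste0("unknown MOTU: ", motu))
  }
  inv_logit(row$intercept + row$slope * log_reads)
}

#' Partition explained deviance over nested detection models
#'
#' Given the pooled model, the model with MOTU-identity intercepts added,
#' and the model with the identity-by-log-reads interaction added, report
#' the extra fraction of the total (null) deviance explained by each term
#' together with a likelihood-ratio chi-square test of the deviance drop.
#'
#' @param base,with_identity,with_interaction Nested `detection_glm` fits
#'   on identical records.
#' @return Tibble with one row per added term: `term`,
#'   `added_explained` (fraction of total deviance), `deviance_drop`,
#'   `df`, `p_value`.
#' @export
deviance_partition <- function(base, with_identity, with_interaction) {
  fits <- list(base, with_identity, with_interaction)
  n <- purrr::map_int(fits, ~ nrow(.x$records))
  if (length(unique(n)) != 1) abort("models are not fitted on identical records")
  nd <- purrr::map_dbl(fits, "null_deviance")
  if (max(nd) - min(nd) > 1e-6 * max(nd)) {
    abort("models do not share a null deviance; not nested on the same data")
  }
  purrr::map2_dfr(fits[-3], fits[-1], function(smaller, larger) {
    drop <- smaller$residual_deviance - larger$residual_deviance
    df <- larger$n_parameters - smaller$n_parameters
    tibble::tibble(
      term = paste0("+ ", larger$model_form),
      added_explained = drop / larger$null_deviance,
      deviance_drop = drop,
      df = df,
      p_value = if (df > 0) pchisq(pmax(drop, 0), df, lower.tail = FALSE) else 1)
  })
}

#' Invert a detection curve to relative abundance at a target rate
#'
#' Solves `logit(rate) = a + b * log(reads)` for the standardized read
#' count at which the fitted detection rate equals `target_rate`, and
#' scales by the rarefaction depth to express it as relative abundance.
#'
#' @param fit A `detection_glm` with positive slope(s).
#' @param target_rate Detection rate(s) in (0, 1) to invert at.
#' @param depth Standardized reads per site used when fitting.
#' @return Tibble with columns `motu`, `target_rate`, `reads`
#'   (standardized read count at the rate) and `rel_abundance`
#'   (`reads / depth`).
#' @export
invert_abundance_at_rate <- function(fit, target_rate, depth) {
  stopifnot(inherits(fit, "detection_glm"))
  if (any(target_rate <= 0 | target_rate >= 1)) {
    abort("target_rate must lie strictly between 0 and 1")
  }
  cf <- detection_coefficients(fit)
  if (any(cf$slope <= 0)) {
    abort("non-positive slope: detection curve cannot be inverted to an abundance")
  }
  tidyr::crossing(cf, target_rate = target_rate) |>
    dplyr::mutate(reads = exp((logit(.data$target_rate) - .data$intercept) /
                                .data$slope),
                  rel_abundance = .data$reads / depth) |>
    dplyr::select("motu", "target_rate", "reads", "rel_abundance")
}
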