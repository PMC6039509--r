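#' Run the full survey-analysis pipeline
#'
#' Orchestrates the stages — synthetic survey generation (or table
#' ingestion), rarefaction, detection-GLM fitting and inversion,
#' eDNA/capture comparison, co-inertia coupling, Mantel correlogram, and
#' transport predictions — writing per-stage delimited outputs plus one
#' machine-readable JSON summary. Stage selection is declarative:
#' disabling a stage never alters another stage's numbers, and a rerun
#' with the same configuration yields a byte-identical summary.
#'
#' @param config A named list or the path to a YAML file. Recognized
#'   keys: `seed` (master seed, default 1), `stages` (character subset of
#'   `c("rarefy", "detect", "compare", "coinertia", "correlogram",
#'   "transport")`; default all), `scenario` (argument list for
#'   [synthetic_scenario()]), `reads_path`/`pcr_path`/`pcr_replicates`
#'   (ingest real tables instead of simulating), `depth` (rarefaction
#'   depth; default minimum site total), `min_reads` and `exclude_taxa`
#'   (filter policy), `target_rates` (inversion rates, default 0.05, 0.5,
#'   0.95), `n_perm` (permutations, default 999), `class_width_km` and
#'   `n_classes` (correlogram grid), `transport` (list with `reaches`
#'   data frame, `v_dep_mm_s` values, and release scenario fields).
#' @param output_dir Directory for stage outputs; created if missing.
#'   `NULL` (default) computes the summary without writing files.
#' @return The summary list, invisibly when files are written.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  seed <- cfg$seed %||% 1L
  stages <- cfg$stages %||% c("rarefy", "detect", "compare", "coinertia",
                              "correlogram", "transport")
  outputs <- list()
  summary <- list(seed = seed, stages = stages)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  needs_data <- any(c("rarefy", "detect", "compare", "coinertia",
                      "correlogram") %in% stages)
  scenario <- NULL
  tbl <- NULL
  if (needs_data) {
    if (!is.null(cfg$reads_path)) {
      tbl <- run_stage("ingest", read_motu_table(
        cfg$reads_path, cfg$pcr_path, cfg$pcr_replicates %||% 24L))
    } else {
      scenario <- run_stage("simulate", do.call(
        synthetic_scenario, c(cfg$scenario %||% list(),
                              if (is.null(cfg$scenario$seed)) list(seed = seed))))
      tbl <- run_stage("simulate", simulate_survey(scenario))
      summary$simulate <- list(n_sites = scenario$n_sites,
                               n_species = scenario$n_species,
                               transport_sp_km = scenario$transport_sp_km)
    }
    tbl <- run_stage("filter", filter_taxa(
      tbl, exclude = cfg$exclude_taxa %||% character(),
      min_reads = cfg$min_reads %||% 10L))
  }

  if ("rarefy" %in% stages) {
    tbl <- run_stage("rarefy", rarefy_reads(tbl, depth = cfg$depth,
                                            seed = seed + 10L))
    depth <- sum(tbl$reads[tbl$site == tbl$site[1]])
    summary$rarefy <- list(depth = depth,
                           n_sites = length(unique(tbl$site)),
                           n_motus = length(unique(tbl$motu)))
    outputs$rarefied_reads <- tbl
  } else if (needs_data) {
    depth <- min(tapply(tbl$reads, tbl$site, sum))
  }

  if ("detect" %in% stages) {
    summary$detect <- run_stage("detect", {
      motus <- select_modelable_motus(tbl, cfg$min_sites %||% 10L,
                                      cfg$k_min %||% 3L, cfg$k_max %||% 23L)
      records <- detection_records(tbl, motus)
      pooled <- fit_detection_glm(records, "pooled")
      ident <- fit_detection_glm(records, "identity")
      inter <- fit_detection_glm(records, "identity_interaction")
      part <- deviance_partition(pooled, ident, inter)
      inv <- invert_abundance_at_rate(pooled, cfg$target_rates %||%
                                        c(0.05, 0.5, 0.95), depth)
      outputs$detection_terms <- tidy(pooled)
      outputs$detection_inversion <- inv
      list(n_motus_modeled = length(motus), n_records = nrow(records),
           explained_deviance = pooled$explained_deviance,
           added_identity = part$added_explained[1],
           added_interaction = part$added_explained[2],
           inversion = setNames(as.list(inv$rel_abundance),
                                paste0("rate_", inv$target_rate)))
    })
  }

  catches <- NULL
  if (any(c("compare", "coinertia") %in% stages)) {
    if (is.null(scenario)) {
      abort("compare/coinertia stages need simulated catches (no catch ingestion configured)")
    }
    catches <- run_stage("catches",
                         simulate_catches(true_assemblage(scenario), scenario))
  }

  if ("compare" %in% stages) {
    summary$compare <- run_stage("compare", {
      props <- relative_abundance(tbl)
      edna_div <- diversity_indices(motu_matrix(props, "prop"))
      cpue <- catches |>
        dplyr::group_by(.data$site, .data$species) |>
        dplyr::summarise(cpue = mean(.data$count / .data$effort),
                         .groups = "drop")
      rho <- props |>
        dplyr::select(location = "site", species = "motu", edna = "prop") |>
        dplyr::inner_join(dplyr::rename(cpue, location = "site",
                                        catch = "cpue"),
                          by = c("location", "species")) |>
        dplyr::group_by(.data$location) |>
        dplyr::group_modify(~ spearman_site_correlation(.x)) |>
        dplyr::ungroup()
      outputs$site_diversity <- edna_div
      outputs$site_correlations <- rho
      list(mean_edna_richness = mean(edna_div$richness),
           mean_edna_shannon = mean(edna_div$shannon),
           n_sites_significant_rho = sum(rho$p_value < 0.05, na.rm = TRUE),
           n_sites_tested = nrow(rho),
           median_rho = stats::median(rho$rho, na.rm = TRUE))
    })
  }

  if ("coinertia" %in% stages) {
    summary$coinertia <- run_stage("coinertia", {
      edna_mat <- log1p_abundance(motu_matrix(tbl, "reads"))
      catch_mat <- catches |>
        dplyr::group_by(.data$site, .data$km, .data$species) |>
        dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
        tidyr::pivot_wider(names_from = "species", values_from = "count",
                           values_fill = 0) |>
        dplyr::arrange(.data$km)
      catch_mat <- log1p_abundance(catch_mat)
      pca_e <- centered_pca(edna_mat, 2)
      pca_t <- centered_pca(catch_mat, 2)
      coi <- coinertia(pca_e, pca_t, n_perm = cfg$n_perm %||% 999L,
                       seed = seed + 20L)
      reg1 <- identity_regression(scale(coi$scores_x[, 1])[, 1],
                                  scale(coi$scores_y[, 1])[, 1])
      outputs$coinertia_scores <- tibble::tibble(
        site = rownames(coi$scores_x),
        edna_axis1 = coi$scores_x[, 1], edna_axis2 = coi$scores_x[, 2],
        catch_axis1 = coi$scores_y[, 1], catch_axis2 = coi$scores_y[, 2])
      list(rv = coi$rv, permutation_p = coi$permutation_p,
           pca_edna_inertia_2axes = sum(pca_e$inertia_fraction[1:2]),
           pca_catch_inertia_2axes = sum(pca_t$inertia_fraction[1:2]),
           axis1_r_squared = reg1$r_squared)
    })
  }

  if ("correlogram" %in% stages) {
    summary$correlogram <- run_stage("correlogram", {
      props <- motu_matrix(relative_abundance(tbl), "prop")
      d <- bray_curtis(props)
      km <- attr(props, "km")
      mt <- mantel_test(d, abs(outer(km, km, "-")),
                        n_perm = cfg$n_perm %||% 999L, seed = seed + 30L)
      cg <- mantel_correlogram(d, km,
                               class_width_km = cfg$class_width_km %||% 10,
                               n_classes = cfg$n_classes,
                               n_perm = cfg$n_perm %||% 999L,
                               seed = seed + 31L)
      outputs$correlogram <- cg$classes
      list(mantel_r = mt$r, mantel_p = mt$p_value,
           extent_km = cg$extent_km)
    })
  }

  if ("transport" %in% stages) {
    summary$transport <- run_stage("transport", {
      tr <- cfg$transport %||% list()
      vdep <- vdep_summary(tr$v_dep_mm_s %||% 0.180)
      reaches <- if (!is.null(tr$reaches)) tibble::as_tibble(tr$reaches) else
        tibble::tibble(label = "example reach", discharge_q = 436,
                       wetted_width_w = 132)
      tab <- predict_detection_table(
        reaches, vdep,
        source_concentration = tr$source_concentration %||% 2000,
        sample_volume = tr$sample_volume %||% 2.5,
        detection_threshold = tr$detection_threshold %||% 1)
      outputs$transport_predictions <- tab
      list(v_dep_median = vdep$median,
           predicted_km = setNames(as.list(tab$predicted_km), tab$label))
    })
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(outputs)) {
      readr::write_tsv(outputs[[nm]], file.path(output_dir, paste0(nm, ".tsv")))
    }
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(summary))
  }
  summary
}
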