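#' Define a synthetic river-survey scenario
#'
#' Bundles every parameter of the seeded generators: a longitudinal
#' species-turnover gradient (Gaussian niche responses along the river),
#' multinomial read sampling at site-specific depths, PCR-replicate
#' detections following a logit-linear model in log read count,
#' negative-binomial capture counts with per-species catchability bias,
#' and optional downstream advection of eDNA with first-order loss.
#' Defaults emulate a 500-km river surveyed at 40 sites with 40 MOTUs,
#' 24 PCR replicates, and the sequencing depths and detection-curve
#' steepness typical of a river-scale fish metabarcoding campaign.
#'
#' @param n_sites Number of sites, evenly spaced along the river.
#' @param river_length_km River length in km.
#' @param n_species Number of species / MOTUs.
#' @param niche_breadth Gaussian niche breadth(s) in km (recycled).
#' @param max_abundance Per-species peak response; default log-normal
#'   draws (seeded) so assemblages are uneven.
#' @param read_depth_range Min and max total reads per site; the study
#'   regime has a minimum of 163,121 reads.
#' @param glm_intercept,glm_slope Detection model logit(p) =
#'   a + b * ln(reads).
#' @param pcr_replicates PCR replicates per site (default 24).
#' @param transport_sp_km e-folding mixing length for downstream eDNA
#'   advection; 0 disables transport.
#' @param catchability_bias Per-species multiplier on capture rates
#'   (recycled); 1 = unbiased.
#' @param overdispersion Negative-binomial size for capture counts.
#' @param n_years Annual capture surveys per site.
#' @param effort Capture effort per site-year (expected catch scale).
#' @param seed Scenario seed; all generators derive their randomness from
#'   it, so a scenario is a complete, reproducible study specification.
#' @return A list of class `edna_scenario`.
#' @export
synthetic_scenario <- function(n_sites = 40L, river_length_km = 500,
                               n_species = 40L, niche_breadth = 80,
                               max_abundance = NULL,
                               read_depth_range = c(163121L, 500000L),
                               glm_intercept = -6.0, glm_slope = 1.2,
                               pcr_replicates = 24L, transport_sp_km = 0,
                               catchability_bias = 1,
                               overdispersion = 5, n_years = 10L,
                               effort = 400, seed = 1L) {
  stopifnot(n_sites >= 2, river_length_km > 0, n_species >= 1,
            all(niche_breadth > 0), pcr_replicates >= 1,
            transport_sp_km >= 0, overdispersion > 0, n_years >= 1)
  sc <- withr::with_seed(seed, {
    list(n_sites = as.integer(n_sites),
         river_length_km = river_length_km,
         n_species = as.integer(n_species),
         km = seq(0, river_length_km, length.out = n_sites),
         species = sprintf("sp%02d", seq_len(n_species)),
         niche_optima = sort(runif(n_species, 0, river_length_km)),
         niche_breadth = rep_len(niche_breadth, n_species),
         max_abundance = max_abundance %||% exp(stats::rnorm(n_species, 0, 1)),
         read_depth_range = as.integer(read_depth_range),
         glm_intercept = glm_intercept, glm_slope = glm_slope,
         pcr_replicates = as.integer(pcr_replicates),
         transport_sp_km = transport_sp_km,
         catchability_bias = rep_len(catchability_bias, n_species),
         overdispersion = overdispersion,
         n_years = as.integer(n_years), effort = effort,
         seed = as.integer(seed))
  })
  structure(sc, class = "edna_scenario")
}

#' @export
print.edna_scenario <- function(x, ...) {
  cat(sprintf("Synthetic river survey: %d sites over %g km, %d species, seed %d\n",
              x$n_sites, x$river_length_km, x$n_species, x$seed))
  cat(sprintf("  detection logit(p) = %g + %g ln(reads), R = %d; transport Sp = %g km\n",
              x$glm_intercept, x$glm_slope, x$pcr_replicates, x$transport_sp_km))
  invisible(x)
}

#' True relative-abundance assemblage along the river
#'
#' Gaussian species-response curves: the unnormalized response of species
#' i at kilometre point s is `max_abundance_i *
#' exp(-(s - optimum_i)^2 / (2 * breadth_i^2))`; rows are normalized to
#' sum to 1. Deterministic given the scenario (whose seed fixed the
#' optima and peak abundances).
#'
#' @param scenario An `edna_scenario`.
#' @return Wide tibble: `site`, `km`, then one relative-abundance column
#'   per species.
#' @export
true_assemblage <- function(scenario) {
  stopifnot(inherits(scenario, "edna_scenario"))
  resp <- outer(scenario$km, seq_len(scenario$n_species), function(s, i) {
    scenario$max_abundance[i] *
      exp(-(s - scenario$niche_optima[i])^2 / (2 * scenario$niche_breadth[i]^2))
  })
  resp <- resp / rowSums(resp)
  colnames(resp) <- scenario$species
  dplyr::bind_cols(
    tibble::tibble(site = sprintf("S%02d", seq_len(scenario$n_sites)),
                   km = scenario$km),
    tibble::as_tibble(resp))
}

#' Mix an assemblage downstream with first-order eDNA transport
#'
#' Each downstream site's signal gains the upstream sites' local signals
#' attenuated by first-order loss over the separation distance:
#' `signal(s) = local(s) + sum_u local(u) * exp(-(km_s - km_u) / sp_km)`
#' over upstream sites u, rows renormalized. `sp_km = 0` returns the
#' input unchanged. Emulates eDNA advection lengthening the apparent
#' spatial autocorrelation of assemblages.
#'
#' @param assemblage Wide tibble from [true_assemblage()] (columns `site`,
#'   `km`, species...). Sites must be ordered downstream.
#' @param sp_km e-folding mixing length in km.
#' @return Wide tibble of the same shape.
#' @export
apply_transport <- function(assemblage, sp_km) {
  if (sp_km < 0) abort("sp_km must be non-negative")
  if (sp_km == 0) return(assemblage)
  km <- assemblage$km
  if (is.unsorted(km)) abort("sites must be ordered downstream (increasing km)")
  m <- as_abundance_matrix(assemblage)
  n <- nrow(m)
  w <- exp(-outer(km, km, "-") / sp_km)  # w[s, u] for u upstream of s
  w[upper.tri(w)] <- 0                   # no upstream flow of signal
  diag(w) <- 1
  mixed <- w %*% m
  mixed <- mixed / rowSums(mixed)
  out <- assemblage
  out[, colnames(m)] <- tibble::as_tibble(mixed)
  out
}

#' Simulate sequencing reads from an assemblage
#'
#' Per site, a total read depth is drawn uniformly from the scenario's
#' depth range, and reads are allocated to species by a multinomial draw
#' on the (possibly transport-mixed) relative abundances.
#'
#' @param assemblage Wide tibble (`site`, `km`, species columns) with rows
#'   summing to 1.
#' @param scenario An `edna_scenario`.
#' @param seed Seed; defaults to `scenario$seed + 1` so the pipeline run
#'   is reproducible from the scenario alone.
#' @return Long MOTU table: `site`, `km`, `motu`, `reads`.
#' @export
simulate_reads <- function(assemblage, scenario, seed = scenario$seed + 1L) {
  m <- as_abundance_matrix(assemblage)
  stopifnot(max(abs(rowSums(m) - 1)) < 1e-8)
  rng <- scenario$read_depth_range
  withr::with_seed(seed, {
    depths <- if (rng[1] == rng[2]) rep(rng[1], nrow(m)) else
      sample(rng[1]:rng[2], nrow(m), replace = TRUE)
    counts <- t(vapply(seq_len(nrow(m)),
                       function(i) rmultinom(1, depths[i], m[i, ])[, 1],
                       integer(ncol(m))))
  })
  dimnames(counts) <- dimnames(m)
  tibble::tibble(site = rep(assemblage$site, each = ncol(m)),
                 km = rep(assemblage$km, each = ncol(m)),
                 motu = rep(colnames(m), nrow(m)),
                 reads = as.integer(t(counts)))
}

#' Simulate PCR-replicate detections from read counts
#'
#' Per (site, MOTU) cell with positive reads, the positive-PCR count is
#' `k ~ Binomial(R, logistic(a + b * ln(reads)))` — the detection model
#' conditions on realized reads, matching the covariate the detection
#' GLM is fitted against. Cells with zero reads get k = 0.
#'
#' @param read_table Long MOTU table (`site`, `km`, `motu`, `reads`).
#' @param scenario An `edna_scenario` (supplies a, b and R).
#' @param seed Seed; defaults to `scenario$seed + 2`.
#' @return The table with `pcr_positive` and `pcr_total` columns added.
#' @export
simulate_pcr <- function(read_table, scenario, seed = scenario$seed + 2L) {
  p <- ifelse(read_table$reads > 0,
              inv_logit(scenario$glm_intercept +
                          scenario$glm_slope * log(pmax(read_table$reads, 1))),
              0)
  k <- withr::with_seed(seed, rbinom(length(p), scenario$pcr_replicates, p))
  dplyr::mutate(read_table, pcr_positive = as.integer(k),
                pcr_total = scenario$pcr_replicates)
}

#' Simulate annual capture surveys from the true assemblage
#'
#' Per site, year and species, the catch is negative-binomial with mean
#' `effort * abundance * catchability_bias_i` and size
#' `overdispersion` — electrofishing counts are overdispersed, and bank
#' sampling over- or under-represents species according to their position
#' in the water column (the bias multiplier).
#'
#' @param assemblage Wide tibble from [true_assemblage()]; catches sample
#'   the true local assemblage, not the transport-mixed eDNA signal.
#' @param scenario An `edna_scenario`.
#' @param seed Seed; defaults to `scenario$seed + 3`.
#' @return Long tibble: `site`, `km`, `year`, `species`, `count`,
#'   `effort`.
#' @export
simulate_catches <- function(assemblage, scenario, seed = scenario$seed + 3L) {
  m <- as_abundance_matrix(assemblage)
  mu <- scenario$effort * sweep(m, 2, scenario$catchability_bias, "*")
  out <- tidyr::crossing(
    tibble::tibble(site = assemblage$site, km = assemblage$km),
    year = seq_len(scenario$n_years),
    species = colnames(m)) |>
    dplyr::arrange(.data$site, .data$year, .data$species)
  mu_vec <- mu[cbind(match(out$site, assemblage$site),
                     match(out$species, colnames(m)))]
  counts <- withr::with_seed(seed, {
    ifelse(mu_vec == 0, 0L,
           rnbinom(length(mu_vec), mu = mu_vec, size = scenario$overdispersion))
  })
  dplyr::mutate(out, count = as.integer(counts), effort = scenario$effort)
}

#' Simulate a full eDNA metabarcoding survey
#'
#' Convenience chain: [true_assemblage()] -> [apply_transport()] ->
#' [simulate_reads()] -> [simulate_pcr()].
#'
#' @param scenario An `edna_scenario`.
#' @return Long MOTU table with PCR columns.
#' @export
simulate_survey <- function(scenario) {
  assem <- true_assemblage(scenario)
  mixed <- apply_transport(assem, scenario$transport_sp_km)
  simulate_pcr(simulate_reads(mixed, scenario), scenario)
}
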