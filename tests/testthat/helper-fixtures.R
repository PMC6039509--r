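# Small in-code fixtures shared across test files.

# long MOTU table built from a wide count matrix (sites x motus)
toy_motu_table <- function(counts, km = NULL, pcr_positive = NULL,
                           pcr_total = 24L) {
  sites <- rownames(counts) %||% paste0("S", seq_len(nrow(counts)))
  motus <- colnames(counts) %||% paste0("m", seq_len(ncol(counts)))
  km <- km %||% seq(0, by = 10, length.out = nrow(counts))
  tbl <- tibble::tibble(
    site = rep(sites, each = ncol(counts)),
    km = rep(km, each = ncol(counts)),
    motu = rep(motus, nrow(counts)),
    reads = as.integer(t(counts)))
  if (!is.null(pcr_positive)) {
    tbl$pcr_positive <- as.integer(t(pcr_positive))
    tbl$pcr_total <- as.integer(pcr_total)
  }
  tbl
}

`%||%` <- rlang::`%||%`

# detection records simulated straight from the logit-linear model
gen_detection_records <- function(n, a, b, R = 24L, seed = 1,
                                  log_range = c(1, 9)) {
  withr::with_seed(seed, {
    log_reads <- runif(n, log_range[1], log_range[2])
    p <- plogis(a + b * log_reads)
    tibble::tibble(motu = "m1", site = paste0("S", seq_len(n)),
                   log_reads = log_reads,
                   k = rbinom(n, R, p), R = R)
  })
}

# a small survey scenario kept cheap for unit tests
small_scenario <- function(...) {
  args <- list(...)
  defaults <- list(n_sites = 20L, n_species = 15L, niche_breadth = 100,
                   read_depth_range = c(8000L, 12000L), seed = 42L)
  do.call(synthetic_scenario, utils::modifyList(defaults, args))
}
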