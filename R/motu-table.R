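#' Read a site-by-MOTU read-count table
#'
#' Ingests a delimited wide table (first column site identifier, second
#' column kilometre point, remaining columns MOTU read counts) and returns
#' it in long form. A companion file of identical shape can supply the
#' number of positive PCR amplifications per (site, MOTU) cell.
#'
#' @param path Path to the read-count table (TSV or CSV, sniffed from the
#'   extension).
#' @param pcr_path Optional path to a table of identical shape holding the
#'   count of positive PCR replicates per cell.
#' @param pcr_replicates Total number of PCR replicates run per site
#'   (default 24).
#' @return A long tibble with columns `site`, `km`, `motu`, `reads`, and —
#'   when PCR information is available — `pcr_positive` and `pcr_total`.
#' @export
read_motu_table <- function(path, pcr_path = NULL, pcr_replicates = 24L) {
  reads <- read_wide_counts(path)
  tbl <- tidyr::pivot_longer(reads, cols = -c(1, 2),
                             names_to = "motu", values_to = "reads")
  names(tbl)[1:2] <- c("site", "km")
  tbl$site <- as.character(tbl$site)
  tbl$reads <- as.integer(tbl$reads)
  if (!is.null(pcr_path)) {
    pcr <- read_wide_counts(pcr_path)
    ptbl <- tidyr::pivot_longer(pcr, cols = -c(1, 2),
                                names_to = "motu", values_to = "pcr_positive")
    names(ptbl)[1:2] <- c("site", "km")
    ptbl$site <- as.character(ptbl$site)
    tbl <- dplyr::left_join(tbl, ptbl[, c("site", "motu", "pcr_positive")],
                            by = c("site", "motu"))
    tbl$pcr_positive <- as.integer(tbl$pcr_positive)
    tbl$pcr_total <- as.integer(pcr_replicates)
  }
  validate_motu_table(tbl)
  tbl
}

read_wide_counts <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

validate_motu_table <- function(tbl) {
  need <- c("site", "km", "motu", "reads")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("MOTU table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(tbl$reads < 0) || any(tbl$reads != floor(tbl$reads))) {
    abort("read counts must be non-negative integers")
  }
  if (any(tbl$km < 0, na.rm = TRUE)) abort("kilometre points must be non-negative")
  if (anyDuplicated(unique(tbl[, c("site", "km")])$site) > 0) {
    abort("site identifiers must be unique")
  }
  if ("pcr_positive" %in% names(tbl)) {
    bad <- tbl$pcr_positive < 0 | tbl$pcr_positive > tbl$pcr_total
    if (any(bad, na.rm = TRUE)) {
      abort("pcr_positive must lie in [0, pcr_total] for every cell")
    }
  }
  invisible(tbl)
}

#' Drop implausible taxa and rare MOTUs from a read table
#'
#' Removes MOTUs named in an exclusion list (detections judged implausible
#' for the river, e.g. marine or farmed taxa whose DNA enters with
#' effluents) and MOTUs whose maximum read count over all sites falls
#' below a copy-number threshold. The site set is never altered.
#'
#' @param tbl A long MOTU table as returned by [read_motu_table()] or
#'   [simulate_reads()].
#' @param exclude Character vector of MOTU identifiers to drop. Names not
#'   present in the table raise a warning, not an error.
#' @param min_reads Minimum copy count: a MOTU is kept only if its read
#'   count reaches this value at one site at least. Default 10.
#' @return The filtered long tibble.
#' @export
filter_taxa <- function(tbl, exclude = character(), min_reads = 10L) {
  validate_motu_table(tbl)
  if (min_reads < 0) abort("min_reads must be >= 0")
  unknown <- setdiff(exclude, unique(tbl$motu))
  if (length(unknown) > 0) {
    warn(paste0("exclusion list names unknown MOTU(s): ",
                paste(unknown, collapse = ", ")))
  }
  keep <- tbl |>
    dplyr::group_by(.data$motu) |>
    dplyr::summarise(max_reads = max(.data$reads), .groups = "drop") |>
    dplyr::filter(.data$max_reads >= min_reads) |>
    dplyr::pull("motu")
  keep <- setdiff(keep, exclude)
  dplyr::filter(tbl, .data$motu %in% keep)
}

#' Rarefy read counts to a common depth per site
#'
#' Standardizes sequencing effort by subsampling each site's reads without
#' replacement down to a common depth, so that read counts are comparable
#' between sites as relative abundances. The subsample is an exact
#' multivariate hypergeometric draw (sequential conditional hypergeometric
#' sampling), i.e. uniform sampling of individual reads without
#' replacement.
#'
#' @param tbl A long MOTU table.
#' @param depth Target reads per site. Defaults to the smallest site
#'   total, the deepest depth every site can support.
#' @param seed Integer seed; required, so that any rarefied table is
#'   reproducible.
#' @return The table with `reads` replaced by the rarefied counts; every
#'   site total equals `depth` exactly.
#' @export
rarefy_reads <- function(tbl, depth = NULL, seed) {
  validate_motu_table(tbl)
  if (missing(seed)) abort("rarefy_reads() requires an explicit seed")
  totals <- tbl |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(total = sum(.data$reads), .groups = "drop")
  if (is.null(depth)) depth <- min(totals$total)
  depth <- as.integer(depth)
  short <- totals$site[totals$total < depth]
  if (length(short) > 0) {
    abort(paste0("rarefaction depth ", depth, " exceeds the total reads at site(s): ",
                 paste(short, collapse = ", ")))
  }
  withr::with_seed(seed, {
    tbl |>
      dplyr::group_by(.data$site) |>
      dplyr::mutate(reads = rmvhyper_counts(.data$reads, depth)) |>
      dplyr::ungroup()
  })
}

# Exact multivariate hypergeometric draw: category i receives a
# Hypergeometric(count_i, remaining, still_needed) count conditional on
# the categories already drawn.
rmvhyper_counts <- function(counts, depth) {
  out <- integer(length(counts))
  remaining <- sum(counts)
  need <- depth
  for (i in seq_along(counts)) {
    if (need == 0L) break
    remaining <- remaining - counts[i]
    x <- stats::rhyper(1L, counts[i], remaining, need)
    out[i] <- x
    need <- need - x
  }
  out
}

#' Per-site relative read abundance
#'
#' @param tbl A long MOTU table; every site total must be positive.
#' @return The tibble with an added `prop` column, `reads / site total`;
#'   proportions sum to 1 within each site.
#' @export
relative_abundance <- function(tbl) {
  validate_motu_table(tbl)
  out <- tbl |>
    dplyr::group_by(.data$site) |>
    dplyr::mutate(prop = .data$reads / sum(.data$reads)) |>
    dplyr::ungroup()
  if (anyNA(out$prop) || any(!is.finite(out$prop))) {
    zero <- unique(out$site[!is.finite(out$prop)])
    abort(paste0("site(s) with zero total reads: ", paste(zero, collapse = ", ")))
  }
  out
}

#' Per-cell PCR detection rate
#'
#' The detection rate of a MOTU at a site is the proportion of positive
#' PCR amplifications among the replicates run on that site's sample.
#'
#' @param tbl A long MOTU table carrying `pcr_positive` and `pcr_total`
#'   columns.
#' @return The tibble with an added `detection_rate` column in \[0, 1\].
#' @export
detection_rate <- function(tbl) {
  validate_motu_table(tbl)
  if (!all(c("pcr_positive", "pcr_total") %in% names(tbl))) {
    abort("table lacks PCR columns (pcr_positive, pcr_total)")
  }
  if (any(tbl$pcr_total <= 0)) abort("pcr_total must be positive")
  dplyr::mutate(tbl, detection_rate = .data$pcr_positive / .data$pcr_total)
}

#' Pivot a long MOTU table to a site-by-MOTU matrix
#'
#' @param tbl A long MOTU table.
#' @param value Column to spread: `"reads"` (default), `"prop"` or any
#'   other numeric column present.
#' @return A numeric matrix, sites in rows (ordered by kilometre point),
#'   MOTUs in columns; the kilometre points are kept in the `"km"`
#'   attribute.
#' @export
motu_matrix <- function(tbl, value = "reads") {
  if (!value %in% names(tbl)) abort(paste0("no column '", value, "' in table"))
  wide <- tbl |>
    dplyr::select("site", "km", "motu", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "motu", values_from = dplyr::all_of(value),
                       values_fill = 0) |>
    dplyr::arrange(.data$km)
  m <- as.matrix(wide[, -(1:2)])
  rownames(m) <- wide$site
  attr(m, "km") <- setNames(wide$km, wide$site)
  m
}
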