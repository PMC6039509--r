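#' Diversity indices per assemblage
#'
#' Species richness S, Shannon index H (natural log) and Pielou evenness
#' J = H / ln(S), computed per row of a site-by-species abundance matrix
#' (counts or proportions — H is scale-invariant within a row).
#' Zero-abundance entries are ignored; J is undefined (returned `NA`) for
#' single-species assemblages.
#'
#' @param x Numeric vector (one assemblage), site-by-species matrix, or a
#'   wide data frame whose first column is a site identifier.
#' @return Tibble with columns `site`, `richness`, `shannon`, `evenness`.
#' @export
diversity_indices <- function(x) {
  m <- as_abundance_matrix(x)
  if (any(rowSums(m) == 0)) {
    abort(paste0("all-zero abundance row(s): ",
                 paste(rownames(m)[rowSums(m) == 0], collapse = ", ")))
  }
  s <- unname(vegan::specnumber(m))
  h <- unname(vegan::diversity(m, index = "shannon"))
  tibble::tibble(site = rownames(m), richness = as.integer(s),
                 shannon = h,
                 evenness = ifelse(s > 1, h / log(s), NA_real_))
}

as_abundance_matrix <- function(x) {
  if (is.numeric(x) && is.null(dim(x))) {
    m <- matrix(x, nrow = 1, dimnames = list("1", names(x) %||% seq_along(x)))
  } else if (is.matrix(x)) {
    m <- x
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  } else if (is.data.frame(x)) {
    id_cols <- which(!purrr::map_lgl(x, is.numeric))
    km_col <- which(names(x) == "km")
    drop <- union(id_cols, km_col)
    m <- as.matrix(x[, setdiff(seq_along(x), drop), drop = FALSE])
    rownames(m) <- if (length(id_cols) > 0) as.character(x[[id_cols[1]]]) else
      as.character(seq_len(nrow(x)))
  } else {
    abort("cannot interpret input as an abundance matrix")
  }
  if (any(m < 0)) abort("abundances must be non-negative")
  m
}

#' Pair eDNA and capture-survey sites within river sections
#'
#' Within each river section, selects at most one (eDNA site, capture
#' site) pair sharing the same reach type (main channel, bypass, deltaic
#' arm), keeping the least distant pair along the river axis. Ties are
#' broken by site identifier. Sections with no same-type candidate are
#' skipped with a message.
#'
#' @param edna_sites,tef_sites Tibbles with columns `site`, `km`,
#'   `section`, `reach_type`.
#' @return Tibble with columns `section`, `reach_type`, `edna_site`,
#'   `tef_site`, `distance_km`.
#' @export
pair_sites <- function(edna_sites, tef_sites) {
  need <- c("site", "km", "section", "reach_type")
  stopifnot(all(need %in% names(edna_sites)), all(need %in% names(tef_sites)))
  sections <- sort(unique(edna_sites$section))
  purrr::map_dfr(sections, function(sec) {
    e <- dplyr::filter(edna_sites, .data$section == sec)
    t <- dplyr::filter(tef_sites, .data$section == sec)
    cand <- tidyr::crossing(
      dplyr::rename(e, edna_site = "site", edna_km = "km"),
      dplyr::rename(t[, need], tef_site = "site", tef_km = "km",
                    tef_section = "section", tef_reach = "reach_type")) |>
      dplyr::filter(.data$reach_type == .data$tef_reach)
    if (nrow(cand) == 0) {
      inform(paste0("section ", sec, ": no same-reach-type pair; skipped"))
      return(NULL)
    }
    cand |>
      dplyr::mutate(distance_km = abs(.data$edna_km - .data$tef_km)) |>
      dplyr::arrange(.data$distance_km, .data$edna_site, .data$tef_site) |>
      dplyr::slice(1) |>
      dplyr::transmute(section = sec, reach_type = .data$reach_type,
                       edna_site = .data$edna_site, tef_site = .data$tef_site,
                       distance_km = .data$distance_km)
  })
}

#' Compare eDNA richness with annual and cumulative capture richness
#'
#' Two comparisons, mirroring how a single eDNA sample relates to repeated
#' capture surveys: (i) per location, a one-sample Wilcoxon signed-rank
#' test of the annual capture richness values against the paired eDNA
#' richness (default alternative: annual captures find fewer species);
#' (ii) across locations, a paired Wilcoxon signed-rank test of the
#' cumulative (all-years) capture richness against the eDNA richness.
#'
#' @param annual Tibble with columns `location`, `year`, `richness`
#'   (capture survey richness per year).
#' @param edna Tibble with columns `location`, `richness` (one eDNA value
#'   per location).
#' @param cumulative Optional tibble `location`, `richness` of
#'   capture richness accumulated over all years; computed from `annual`
#'   only if a `cumulative` column is absent — pass it explicitly when
#'   the species lists are available, since max annual richness
#'   underestimates the cumulative list.
#' @param alternative Alternative for the per-location test (default
#'   `"less"`: annual capture richness below the eDNA value).
#' @return List of class `richness_comparison`: `$per_location` tibble
#'   (`location`, `n_years`, `mean_annual`, `edna_richness`, `statistic`,
#'   `p_value`) and `$cross_location` one-row tibble for the cumulative
#'   test.
#' @export
richness_comparison <- function(annual, edna, cumulative = NULL,
                                alternative = "less") {
  counts <- annual |>
    dplyr::group_by(.data$location) |>
    dplyr::summarise(n_years = dplyr::n(), .groups = "drop")
  few <- counts$location[counts$n_years < 2]
  if (length(few) > 0) {
    inform(paste0("location(s) with < 2 annual samples excluded: ",
                  paste(few, collapse = ", ")))
    annual <- dplyr::filter(annual, !.data$location %in% few)
  }
  per_loc <- annual |>
    dplyr::inner_join(dplyr::rename(edna, edna_richness = "richness"),
                      by = "location") |>
    dplyr::group_by(.data$location) |>
    dplyr::summarise(
      n_years = dplyr::n(),
      mean_annual = mean(.data$richness),
      edna_richness = .data$edna_richness[1],
      test = list(one_sample_wilcox(.data$richness, .data$edna_richness[1],
                                    alternative)),
      .groups = "drop") |>
    dplyr::mutate(statistic = purrr::map_dbl(.data$test, "statistic"),
                  p_value = purrr::map_dbl(.data$test, "p_value")) |>
    dplyr::select(-"test")
  if (is.null(cumulative)) {
    cumulative <- annual |>
      dplyr::group_by(.data$location) |>
      dplyr::summarise(richness = max(.data$richness), .groups = "drop")
  }
  paired <- dplyr::inner_join(dplyr::rename(cumulative, cum_richness = "richness"),
                              dplyr::rename(edna, edna_richness = "richness"),
                              by = "location")
  if (nrow(paired) < 6) {
    warn("fewer than 6 paired locations for the cross-location test")
  }
  diffs <- paired$cum_richness - paired$edna_richness
  cross <- if (all(diffs == 0)) {
    tibble::tibble(n = nrow(paired), statistic = NA_real_, p_value = 1)
  } else {
    wt <- suppressWarnings(wilcox.test(paired$cum_richness,
                                       paired$edna_richness, paired = TRUE))
    tibble::tibble(n = nrow(paired), statistic = unname(wt$statistic),
                   p_value = wt$p.value)
  }
  structure(list(per_location = per_loc, cross_location = cross),
            class = "richness_comparison")
}

one_sample_wilcox <- function(x, mu, alternative) {
  if (all(x == mu)) {
    # no signed differences: no evidence against mu
    return(list(statistic = NA_real_, p_value = 1))
  }
  wt <- suppressWarnings(wilcox.test(x, mu = mu, alternative = alternative))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' @export
print.richness_comparison <- function(x, ...) {
  cat("Per-location richness tests (annual capture vs eDNA):\n")
  print(x$per_location, ...)
  cat("\nCross-location cumulative test:\n")
  print(x$cross_location, ...)
  invisible(x)
}

#' Sign test for systematic abundance bias between methods
#'
#' For each species observed in enough paired locations, an exact
#' binomial sign test on the per-location sign of
#' (eDNA proportion - capture proportion), with Bonferroni correction
#' over the species entering the test. A significant positive direction
#' means the species is systematically enriched in the eDNA description.
#'
#' @param paired Tibble with columns `location`, `species`, `edna_prop`,
#'   `catch_prop`.
#' @param alpha Family-wise significance level (default 0.05).
#' @param min_locations Minimum paired locations where the species is
#'   present (in either method) to enter testing (default 6).
#' @return Tibble with columns `species`, `n`, `n_positive`, `direction`,
#'   `p_value`, `p_bonferroni`, `significant`.
#' @export
abundance_bias_test <- function(paired, alpha = 0.05, min_locations = 6L) {
  tested <- paired |>
    dplyr::filter(.data$edna_prop > 0 | .data$catch_prop > 0) |>
    dplyr::group_by(.data$species) |>
    dplyr::filter(dplyr::n() >= min_locations) |>
    dplyr::summarise(
      n = sum(.data$edna_prop != .data$catch_prop),
      n_positive = sum(.data$edna_prop > .data$catch_prop),
      .groups = "drop")
  m <- nrow(tested)
  tested |>
    dplyr::mutate(
      direction = dplyr::case_when(
        .data$n == 0 ~ "none",
        .data$n_positive * 2 > .data$n ~ "edna_enriched",
        .data$n_positive * 2 < .data$n ~ "catch_enriched",
        TRUE ~ "none"),
      p_value = purrr::map2_dbl(.data$n_positive, .data$n, function(k, n) {
        if (n == 0) return(1)
        binom.test(k, n, p = 0.5)$p.value
      }),
      p_bonferroni = pmin(1, .data$p_value * m),
      significant = .data$p_bonferroni < alpha)
}

#' Spearman correlation of eDNA reads and capture counts at one location
#'
#' Rank correlation (mid-ranks for ties) between the per-species read
#' counts and effort-normalized capture counts at a paired location.
#' Species absent from both methods are excluded.
#'
#' @param x Tibble with columns `species`, `edna`, `catch` (non-negative
#'   abundances in each method).
#' @param min_species Minimum species with a value in either method
#'   (default 5).
#' @return One-row tibble: `n_species`, `rho`, `p_value`. `rho` is `NA`
#'   when either vector is constant.
#' @export
spearman_site_correlation <- function(x, min_species = 5L) {
  stopifnot(all(c("species", "edna", "catch") %in% names(x)))
  x <- dplyr::filter(x, .data$edna > 0 | .data$catch > 0)
  if (nrow(x) < min_species) {
    abort(paste0("fewer than ", min_species, " species present in either method"))
  }
  if (sd(x$edna) == 0 || sd(x$catch) == 0) {
    return(tibble::tibble(n_species = nrow(x), rho = NA_real_,
                          p_value = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x$edna, x$catch, method = "spearman",
                                  exact = FALSE))
  tibble::tibble(n_species = nrow(x), rho = unname(ct$estimate),
                 p_value = ct$p.value)
}

#' Screen capture sites for temporal richness trends
#'
#' Pooling annual capture surveys into one cumulative assemblage assumes
#' the local richness is stationary over the survey decade. This fits a
#' Poisson GLM of annual richness on year per site and reports the trend
#' slope and its significance; sites with `p_value > alpha` are flagged
#' trend-free and safe to pool.
#'
#' @param annual Tibble with columns `site`, `year`, `richness`.
#' @param alpha Trend significance threshold (default 0.05).
#' @param min_years Minimum annual values per site (default 5); sites with
#'   fewer are excluded with a message.
#' @return Tibble with columns `site`, `n_years`, `slope`, `p_value`,
#'   `trend_free`.
#' @export
richness_trend_glm <- function(annual, alpha = 0.05, min_years = 5L) {
  stopifnot(all(c("site", "year", "richness") %in% names(annual)))
  counts <- dplyr::count(annual, .data$site)
  few <- counts$site[counts$n < min_years]
  if (length(few) > 0) {
    inform(paste0("site(s) with < ", min_years, " annual values excluded: ",
                  paste(few, collapse = ", ")))
    annual <- dplyr::filter(annual, !.data$site %in% few)
  }
  annual |>
    dplyr::group_by(.data$site) |>
    dplyr::group_modify(function(df, key) {
      fit <- glm(richness ~ year, family = poisson(), data = df)
      sm <- summary(fit)$coefficients
      tibble::tibble(n_years = nrow(df),
                     slope = sm["year", "Estimate"],
                     p_value = sm["year", "Pr(>|z|)"])
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(trend_free = .data$p_value > alpha)
}
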