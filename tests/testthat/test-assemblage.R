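test_that("diversity indices match their defining formulas", {
  # uniform assemblage: maximum entropy, evenness 1
  u <- diversity_indices(rep(0.25, 4))
  expect_equal(u$richness, 4L)
  expect_equal(u$shannon, log(4))
  expect_equal(u$evenness, 1)

  # single species: zero entropy, undefined evenness
  s <- diversity_indices(c(1, 0, 0))
  expect_equal(s$richness, 1L)
  expect_equal(s$shannon, 0)
  expect_true(is.na(s$evenness))

  # direct-summation oracle
  p <- c(0.5, 0.3, 0.2)
  expect_equal(diversity_indices(p)$shannon, -sum(p * log(p)))
  expect_equal(diversity_indices(p)$shannon, 1.0297, tolerance = 1e-4)

  # permutation invariance in species order
  withr::with_seed(3, {
    for (i in 1:5) {
      v <- runif(8)
      expect_equal(diversity_indices(v)$shannon,
                   diversity_indices(sample(v))$shannon)
    }
  })

  expect_error(diversity_indices(c(0, 0, 0)), "all-zero")
})

test_that("site pairing selects the least distant same-reach pair per section", {
  edna <- tibble::tibble(site = c("E1", "E2", "E3"),
                         km = c(10, 50, 90),
                         section = c("A", "A", "B"),
                         reach_type = c("MC", "MC", "BPS"))
  tef <- tibble::tibble(site = c("T1", "T2", "T3"),
                        km = c(15, 52, 200),
                        section = c("A", "A", "B"),
                        reach_type = c("MC", "MC", "MC"))
  expect_message(pairs <- pair_sites(edna, tef), "section B")
  expect_equal(nrow(pairs), 1)
  # candidates at |10-15|=5, |10-52|=42, |50-15|=35, |50-52|=2 -> the 2-km pair
  expect_equal(pairs$edna_site, "E2")
  expect_equal(pairs$tef_site, "T2")
  expect_equal(pairs$distance_km, 2)

  # single candidate is returned unchanged
  single <- pair_sites(edna[3, ], tibble::tibble(site = "T9", km = 91,
                                                 section = "B",
                                                 reach_type = "BPS"))
  expect_equal(single$tef_site, "T9")
})

test_that("pairing distance is minimal against exhaustive search", {
  withr::with_seed(14, {
    e <- tibble::tibble(site = paste0("E", 1:6), km = runif(6, 0, 100),
                        section = "A", reach_type = "MC")
    t <- tibble::tibble(site = paste0("T", 1:6), km = runif(6, 0, 100),
                        section = "A", reach_type = "MC")
  })
  best <- min(abs(outer(e$km, t$km, "-")))
  expect_equal(pair_sites(e, t)$distance_km, best)
})

test_that("richness comparisons behave at the null and under strict separation", {
  # annual richness strictly below the eDNA value everywhere (distinct
  # values, so the signed-rank null is exact): with 10 annual values the
  # one-sided signed-rank p is 1/2^10 < 0.001
  annual <- tidyr::crossing(location = c("L1", "L2"), year = 1:10) |>
    dplyr::mutate(richness = 10L + .data$year)
  edna <- tibble::tibble(location = c("L1", "L2"), richness = c(30L, 28L))
  cum <- tibble::tibble(location = c("L1", "L2"), richness = c(30L, 28L))
  # two paired locations only: the small-sample warning is expected
  expect_warning(rc <- richness_comparison(annual, edna, cumulative = cum),
                 "fewer than 6")
  expect_true(all(rc$per_location$p_value < 0.001))
  expect_equal(rc$per_location$p_value, rep(1 / 1024, 2), tolerance = 1e-10)
  # cumulative richness equal to eDNA richness: no cross-location signal
  expect_equal(rc$cross_location$p_value, 1)

  # identical annual values equal to the eDNA value: p = 1
  flat <- tidyr::crossing(location = "L1", year = 1:10) |>
    dplyr::mutate(richness = 20L)
  rc2 <- suppressWarnings(
    richness_comparison(flat, tibble::tibble(location = "L1", richness = 20L),
                        cumulative = tibble::tibble(location = "L1",
                                                    richness = 20L)))
  expect_equal(rc2$per_location$p_value, 1)

  # a single-year location is excluded with a message
  one <- dplyr::bind_rows(annual,
                          tibble::tibble(location = "L3", year = 1,
                                         richness = 5L))
  expect_message(
    rc3 <- suppressWarnings(richness_comparison(one, dplyr::bind_rows(
      edna, tibble::tibble(location = "L3", richness = 9L)),
      cumulative = cum)),
    "L3")
  expect_false("L3" %in% rc3$per_location$location)
})

test_that("sign test flags planted enrichment with exact binomial p-values", {
  # equal proportions everywhere: nothing flagged
  eq <- tidyr::crossing(location = paste0("L", 1:8),
                        species = c("a", "b")) |>
    dplyr::mutate(edna_prop = 0.5, catch_prop = 0.5)
  expect_true(all(!abundance_bias_test(eq)$significant))

  # one species eDNA-enriched at 16/16 locations: p = 2 * 0.5^16
  paired <- dplyr::bind_rows(
    tibble::tibble(location = paste0("L", 1:16), species = "biased",
                   edna_prop = 0.6, catch_prop = 0.3),
    tibble::tibble(location = paste0("L", 1:16), species = "fair",
                   edna_prop = 0.5, catch_prop = rep(c(0.4, 0.6), 8)))
  out <- abundance_bias_test(paired)
  b <- out[out$species == "biased", ]
  expect_equal(b$p_value, 2 * 0.5^16, tolerance = 1e-12)
  expect_equal(b$direction, "edna_enriched")
  expect_true(b$significant)
  expect_false(out$significant[out$species == "fair"])
})

test_that("sign-test p-values match the exact binomial tail for all n <= 20", {
  for (n in c(5, 10, 16, 20)) {
    for (k in 0:n) {
      paired <- tibble::tibble(
        location = paste0("L", seq_len(n)), species = "x",
        edna_prop = c(rep(0.6, k), rep(0.2, n - k)),
        catch_prop = 0.4)
      p <- abundance_bias_test(paired, min_locations = n)$p_value
      lo <- min(k, n - k); hi <- max(k, n - k)
      oracle <- min(1, pbinom(lo, n, 0.5) + pbinom(hi - 1, n, 0.5,
                                                   lower.tail = FALSE))
      expect_equal(p, oracle, tolerance = 1e-12)
    }
  }
})

test_that("Spearman site correlation matches a rank-then-Pearson oracle", {
  x <- tibble::tibble(species = letters[1:6],
                      edna = c(10, 50, 3, 80, 22, 7),
                      catch = c(4, 30, 1, 55, 20, 2))
  out <- spearman_site_correlation(x)
  expect_equal(out$rho, cor(rank(x$edna), rank(x$catch)))
  expect_equal(out$rho, 1)  # fully concordant ranks

  rev <- dplyr::mutate(x, catch = -catch + 100)
  expect_equal(spearman_site_correlation(rev)$rho,
               cor(rank(rev$edna), rank(rev$catch)))
  expect_equal(spearman_site_correlation(rev)$rho, -1)

  ties <- dplyr::mutate(x, edna = c(10, 10, 3, 80, 22, 22))
  expect_equal(spearman_site_correlation(ties)$rho,
               cor(rank(ties$edna), rank(ties$catch)))

  const <- dplyr::mutate(x, catch = 5)
  expect_true(is.na(spearman_site_correlation(const)$rho))
  expect_error(spearman_site_correlation(x[1:3, ]), "fewer than")
})

test_that("richness trend screening keeps only trend-free sites", {
  trendless <- tibble::tibble(site = "flat", year = 2006:2015, richness = 18L)
  rising <- tibble::tibble(site = "rising", year = 2006:2015,
                           richness = seq(10L, 28L, by = 2L))
  out <- richness_trend_glm(dplyr::bind_rows(trendless, rising))
  expect_equal(out$slope[out$site == "flat"], 0, tolerance = 1e-8)
  expect_equal(out$p_value[out$site == "flat"], 1, tolerance = 1e-6)
  expect_gt(out$slope[out$site == "rising"], 0)
  expect_lt(out$p_value[out$site == "rising"], 0.01)
  expect_identical(out$site[out$trend_free], "flat")

  short <- tibble::tibble(site = "short", year = 1:3, richness = 5L)
  expect_message(richness_trend_glm(dplyr::bind_rows(trendless, short)),
                 "short")
})
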