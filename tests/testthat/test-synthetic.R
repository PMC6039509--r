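test_that("the true assemblage is a Gaussian-response gradient", {
  sc <- small_scenario(n_species = 1)
  a <- true_assemblage(sc)
  expect_true(all(a$sp01 == 1))  # single species: trivially all mass

  sc2 <- small_scenario()
  a2 <- true_assemblage(sc2)
  m <- as.matrix(a2[, -(1:2)])
  expect_equal(unname(rowSums(m)), rep(1, sc2$n_sites), tolerance = 1e-12)
  expect_true(all(m >= 0))

  # at a species' optimum its unnormalized response equals its peak
  resp <- function(s, i) sc2$max_abundance[i] *
    exp(-(s - sc2$niche_optima[i])^2 / (2 * sc2$niche_breadth[i]^2))
  expect_equal(resp(sc2$niche_optima[3], 3), sc2$max_abundance[3])

  # deterministic: same scenario, same assemblage
  expect_identical(a2, true_assemblage(sc2))
})

test_that("downstream transport mixes upstream signal by first-order decay", {
  sc <- small_scenario()
  a <- true_assemblage(sc)
  expect_identical(apply_transport(a, 0), a)

  # two-site closed form
  two <- tibble::tibble(site = c("up", "down"), km = c(0, 30),
                        spA = c(1, 0.2), spB = c(0, 0.8))
  mixed <- apply_transport(two, sp_km = 20)
  w <- exp(-30 / 20)
  expected_A <- (0.2 + w * 1) / (1 + w * 1)  # row total: 1 + w*(1+0)
  expect_equal(mixed$spA[2], expected_A, tolerance = 1e-12)
  expect_equal(mixed$spA[1], 1)  # most upstream site unchanged

  unsorted <- two[2:1, ]
  expect_error(apply_transport(unsorted, 20), "ordered downstream")
})

test_that("read simulation follows the multinomial at the drawn depths", {
  sc <- small_scenario(read_depth_range = c(5000L, 5000L))
  a <- true_assemblage(sc)
  tbl <- simulate_reads(a, sc)
  totals <- tapply(tbl$reads, tbl$site, sum)
  expect_true(all(totals == 5000))  # fixed-depth regime

  # degenerate proportions put every read on the single species
  one <- tibble::tibble(site = "s", km = 0, only = 1)
  expect_equal(simulate_reads(one, sc, seed = 3)$reads, 5000L)

  # per-cell Monte-Carlo mean matches depth * proportion
  p_target <- a[[3]][1]  # first site, first species
  means <- withr::with_seed(55, {
    vapply(seq_len(400), function(i) {
      simulate_reads(a[1, ], sc, seed = sample.int(1e6, 1))$reads[1]
    }, integer(1))
  })
  se <- sqrt(5000 * p_target * (1 - p_target) / 400)
  expect_lt(abs(mean(means) - 5000 * p_target), 4 * se)

  # determinism
  expect_identical(simulate_reads(a, sc, seed = 9),
                   simulate_reads(a, sc, seed = 9))
})

test_that("PCR simulation follows the logit-linear detection model", {
  sc <- small_scenario(glm_intercept = -6, glm_slope = 1.2)
  tbl <- toy_motu_table(matrix(c(0L, 100L, 500L), nrow = 1))
  out <- simulate_pcr(tbl, sc, seed = 1)
  expect_equal(out$pcr_positive[out$reads == 0], 0L)
  expect_true(all(out$pcr_total == 24L))

  # reads at the 50% point: mean k concentrates at R/2
  r50 <- as.integer(round(exp(6 / 1.2)))
  many <- toy_motu_table(matrix(rep(r50, 500L), nrow = 1))
  k <- simulate_pcr(many, sc, seed = 2)$pcr_positive
  p50 <- plogis(-6 + 1.2 * log(r50))
  expect_lt(abs(mean(k) - 24 * p50), 4 * sqrt(24 * p50 * (1 - p50) / 500))

  # zero slope: detection concentrates at logistic(a)
  sc0 <- small_scenario(glm_intercept = 0, glm_slope = 0)
  k0 <- simulate_pcr(many, sc0, seed = 3)$pcr_positive
  expect_lt(abs(mean(k0) / 24 - 0.5), 0.03)

  # fitting the simulated survey recovers the generating coefficients
  sc_fit <- small_scenario(n_sites = 30, seed = 77)
  recs <- detection_records(rarefy_reads(simulate_survey(sc_fit), seed = 5))
  est <- tidy(fit_detection_glm(recs, "pooled"))
  expect_lt(abs(est$estimate[1] - (-6)) / est$std_error[1], 3)
  expect_lt(abs(est$estimate[2] - 1.2) / est$std_error[2], 3)
})

test_that("catch simulation reflects effort, bias and the true assemblage", {
  sc <- small_scenario(n_sites = 16, n_species = 10, effort = 0)
  a <- true_assemblage(sc)
  expect_true(all(simulate_catches(a, sc)$count == 0))

  # unbiased, nearly Poisson-at-large-mean: proportions track abundances
  sc2 <- small_scenario(n_sites = 16, n_species = 10, effort = 5000,
                        overdispersion = 1e6)
  catches <- simulate_catches(a, sc2, seed = 4)
  pooled <- catches |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  true_pooled <- colSums(as.matrix(a[, -(1:2)]))
  expect_gt(cor(pooled$count, true_pooled), 0.99)

  # a planted catchability bias is recovered by the sign test
  bias <- rep(1, 10); bias[4] <- 3
  sc3 <- small_scenario(n_sites = 16, n_species = 10, effort = 2000,
                        catchability_bias = bias)
  catches3 <- simulate_catches(a, sc3, seed = 6)
  catch_prop <- catches3 |>
    dplyr::group_by(.data$site, .data$species) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::group_by(.data$site) |>
    dplyr::mutate(catch_prop = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  paired <- catch_prop |>
    dplyr::transmute(location = .data$site, species = .data$species,
                     catch_prop = .data$catch_prop) |>
    dplyr::left_join(
      tidyr::pivot_longer(a, cols = -(1:2), names_to = "species",
                          values_to = "edna_prop") |>
        dplyr::rename(location = "site") |> dplyr::select(-"km"),
      by = c("location", "species"))
  flagged <- abundance_bias_test(paired)
  sp4 <- flagged[flagged$species == "sp04", ]
  expect_equal(sp4$direction, "catch_enriched")
  expect_true(sp4$significant)
})

test_that("read proportions correlate with CPUE across seeded replicate surveys", {
  n_ok <- 0L
  for (s in 1:10) {
    sc <- synthetic_scenario(n_sites = 15, n_species = 25,
                             read_depth_range = c(20000L, 30000L),
                             niche_breadth = 100, effort = 400, seed = 300 + s)
    tbl <- relative_abundance(simulate_reads(true_assemblage(sc), sc))
    cpue <- simulate_catches(true_assemblage(sc), sc) |>
      dplyr::group_by(.data$site, .data$species) |>
      dplyr::summarise(cpue = mean(.data$count / .data$effort),
                       .groups = "drop")
    per_site <- tbl |>
      dplyr::select(location = "site", species = "motu", edna = "prop") |>
      dplyr::inner_join(dplyr::rename(cpue, location = "site", catch = "cpue"),
                        by = c("location", "species")) |>
      dplyr::group_by(.data$location) |>
      dplyr::group_modify(~ spearman_site_correlation(.x)) |>
      dplyr::ungroup()
    ok <- median(per_site$rho, na.rm = TRUE) > 0 &&
      mean(per_site$p_value < 0.05, na.rm = TRUE) > 0.5
    n_ok <- n_ok + ok
  }
  expect_gte(n_ok, 9)
})
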