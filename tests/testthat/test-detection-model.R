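test_that("MOTU selection applies the site-count and k-range rules", {
  expect_identical(select_modelable_motus(tibble::tibble()), character())

  # 12 sites; m1 spans k 2..24 and is present everywhere: qualifies.
  # m2 present at 3 sites only; m3 present everywhere but k stuck at 10..12.
  n <- 12
  counts <- cbind(m1 = rep(100L, n),
                  m2 = c(5L, 5L, 5L, rep(0L, n - 3)),
                  m3 = rep(100L, n))
  k <- cbind(m1 = as.integer(round(seq(2, 24, length.out = n))),
             m2 = rep(3L, n),
             m3 = rep(11L, n))
  tbl <- toy_motu_table(counts, pcr_positive = k)
  expect_identical(select_modelable_motus(tbl, min_sites = 10,
                                          k_min = 3, k_max = 23), "m1")
})

test_that("detection records exclude zero-read cells and log the exclusions", {
  counts <- rbind(c(100L, 0L), c(50L, 10L))
  k <- rbind(c(12L, 4L), c(8L, 2L))
  tbl <- toy_motu_table(counts, pcr_positive = k)
  expect_message(recs <- detection_records(tbl), "zero reads")
  expect_equal(nrow(recs), 3)
  expect_equal(recs$log_reads, log(c(100, 50, 10)))
})

test_that("pooled GLM recovers the generating coefficients", {
  recs <- gen_detection_records(200, a = -6, b = 1.2, seed = 31)
  fit <- fit_detection_glm(recs, "pooled")
  est <- tidy(fit)
  a_hat <- est$estimate[est$term == "(Intercept)"]
  b_hat <- est$estimate[est$term == "log_reads"]
  expect_lt(abs(a_hat - (-6)) / est$std_error[1], 3)
  expect_lt(abs(b_hat - 1.2) / est$std_error[2], 3)
  expect_gt(fit$explained_deviance, 0)
  expect_lt(fit$explained_deviance, 1)

  # MLE beats the generating parameters on the same data
  dev_at <- function(a, b) {
    p <- plogis(a + b * recs$log_reads)
    -2 * sum(dbinom(recs$k, recs$R, p, log = TRUE))
  }
  expect_lte(dev_at(a_hat, b_hat), dev_at(-6, 1.2) + 1e-8)
})

test_that("a flat half-detection dataset gives a null curve", {
  recs <- tibble::tibble(motu = "m1", site = paste0("S", 1:20),
                         log_reads = seq(1, 8, length.out = 20),
                         k = 12L, R = 24L)
  fit <- fit_detection_glm(recs, "pooled")
  cf <- detection_coefficients(fit)
  expect_equal(cf$slope, 0, tolerance = 1e-6)
  expect_equal(cf$intercept, 0, tolerance = 1e-6)
})

test_that("explained deviance grows with added per-MOTU terms", {
  sc <- small_scenario()
  recs <- detection_records(rarefy_reads(simulate_survey(sc), seed = 2))
  pooled <- fit_detection_glm(recs, "pooled")
  ident <- fit_detection_glm(recs, "identity")
  inter <- fit_detection_glm(recs, "identity_interaction")
  expect_lte(pooled$explained_deviance, ident$explained_deviance + 1e-10)
  expect_lte(ident$explained_deviance, inter$explained_deviance + 1e-10)
  expect_lte(inter$residual_deviance, inter$null_deviance + 1e-8)
})

test_that("deviance partition detects planted MOTU effects and not absent ones", {
  # distinct per-MOTU intercepts: identity term must be highly significant
  withr::with_seed(8, {
    motus <- rep(sprintf("m%d", 1:5), each = 100)
    a_i <- rep(c(-8, -7, -6, -5, -4), each = 100)
    log_reads <- runif(500, 1, 9)
    k <- rbinom(500, 24, plogis(a_i + 1.2 * log_reads))
  })
  recs <- tibble::tibble(motu = motus, site = as.character(seq_len(500)),
                         log_reads = log_reads, k = k, R = 24L)
  fits <- purrr::map(c("pooled", "identity", "identity_interaction"),
                     ~ fit_detection_glm(recs, .x))
  part <- deviance_partition(fits[[1]], fits[[2]], fits[[3]])
  expect_lt(part$p_value[1], 0.01)
  expect_gt(part$added_explained[1], 0)

  # one shared curve: added fractions stay near zero
  recs0 <- dplyr::mutate(gen_detection_records(400, -6, 1.2, seed = 12),
                         motu = rep(sprintf("m%d", 1:4), each = 100))
  fits0 <- purrr::map(c("pooled", "identity", "identity_interaction"),
                      ~ fit_detection_glm(recs0, .x))
  part0 <- deviance_partition(fits0[[1]], fits0[[2]], fits0[[3]])
  expect_lt(sum(part0$added_explained), 0.05)

  # degenerate partition: same model three times
  same <- deviance_partition(fits[[3]], fits[[3]], fits[[3]])
  expect_equal(same$added_explained, c(0, 0))
  expect_equal(same$p_value, c(1, 1))

  # non-nested inputs are refused
  expect_error(deviance_partition(fits[[1]], fits0[[2]], fits0[[3]]),
               "identical records")
})

test_that("abundance inversion is the exact algebraic inverse of the fit", {
  recs <- gen_detection_records(200, a = -6, b = 1.2, seed = 5)
  fit <- fit_detection_glm(recs, "pooled")
  cf <- detection_coefficients(fit)
  depth <- 163121

  inv50 <- invert_abundance_at_rate(fit, 0.5, depth)
  expect_equal(inv50$reads, exp(-cf$intercept / cf$slope), tolerance = 1e-12)

  # round trip at 5%, 50%, 95% to 10 significant digits
  for (r in c(0.05, 0.5, 0.95)) {
    inv <- invert_abundance_at_rate(fit, r, depth)
    expect_equal(predict_detection(fit, log(inv$reads)), r,
                 tolerance = 1e-10)
  }

  # fitted curve is monotone increasing when the slope is positive
  grid <- seq(0, 12, by = 0.5)
  expect_true(all(diff(predict_detection(fit, grid)) > 0))
})

test_that("inversion refuses a non-positive slope", {
  recs <- gen_detection_records(100, a = 3, b = -0.8, seed = 9)
  fit <- fit_detection_glm(recs, "pooled")
  expect_error(invert_abundance_at_rate(fit, 0.5, 1000), "slope")
})

test_that("per-MOTU forms expose one curve per MOTU", {
  withr::with_seed(21, {
    motus <- rep(c("mA", "mB"), each = 80)
    a_i <- rep(c(-7, -5), each = 80)
    b_i <- rep(c(1.0, 1.5), each = 80)
    log_reads <- runif(160, 1, 9)
    k <- rbinom(160, 24, plogis(a_i + b_i * log_reads))
  })
  recs <- tibble::tibble(motu = motus, site = as.character(1:160),
                         log_reads = log_reads, k = k, R = 24L)
  sep <- fit_detection_glm(recs, "per_motu")
  full <- fit_detection_glm(recs, "identity_interaction")
  cf_sep <- detection_coefficients(sep)
  cf_full <- detection_coefficients(full)
  # a saturated interaction model reproduces the separate fits
  expect_equal(dplyr::arrange(cf_sep, motu), dplyr::arrange(cf_full, motu),
               tolerance = 1e-6)
  inv <- invert_abundance_at_rate(sep, 0.5, 10000)
  expect_equal(nrow(inv), 2)
})
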