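#' Centered principal component analysis
#'
#' PCA of a section-by-species abundance table with uniform row weights
#' 1/n: columns are centered (not scaled), axes come from the singular
#' value decomposition of the centered matrix, and the eigenvalue of axis
#' k is (singular value k)^2 / n, so the eigenvalues sum to the total
#' inertia (mean squared deviation from the column means).
#'
#' @param x Section-by-species matrix, or wide data frame whose first
#'   (non-numeric) column holds section identifiers. Log-transform count
#'   tables upstream (see [log1p_abundance()]).
#' @param n_axes Number of axes to retain in the scores/loadings
#'   (default 2).
#' @return A `pca_result`: `scores` (n x n_axes), `loadings`
#'   (species x n_axes), `eigenvalues` and `inertia_fraction` over all
#'   axes, plus the centered matrix for downstream co-inertia.
#' @export
centered_pca <- function(x, n_axes = 2L) {
  m <- as_abundance_matrix_signed(x)
  if (nrow(m) < 2 || ncol(m) < 2) abort("need at least 2 sections and 2 species")
  centered <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(centered)
  n <- nrow(m)
  eig <- sv$d^2 / n
  rank <- sum(sv$d > max(sv$d, 1) * 1e-12)
  n_axes <- min(n_axes, max(rank, 1L))
  scores <- sv$u[, seq_len(n_axes), drop = FALSE] %*%
    diag(sv$d[seq_len(n_axes)], n_axes)
  loadings <- sv$v[, seq_len(n_axes), drop = FALSE]
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(n_axes)))
  dimnames(loadings) <- list(colnames(m), paste0("PC", seq_len(n_axes)))
  structure(list(scores = scores, loadings = loadings,
                 eigenvalues = eig,
                 inertia_fraction = if (sum(eig) > 0) eig / sum(eig) else eig,
                 n_axes = n_axes, centered = centered),
            class = "pca_result")
}

# like as_abundance_matrix but admits negative entries (centered/log data)
as_abundance_matrix_signed <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
    return(x)
  }
  if (is.data.frame(x)) {
    id_cols <- which(!purrr::map_lgl(x, is.numeric))
    km_col <- which(names(x) == "km")
    drop <- union(id_cols, km_col)
    m <- as.matrix(x[, setdiff(seq_along(x), drop), drop = FALSE])
    rownames(m) <- if (length(id_cols) > 0) as.character(x[[id_cols[1]]]) else
      as.character(seq_len(nrow(x)))
    return(m)
  }
  abort("cannot interpret input as a numeric matrix")
}

#' log(x + 1) transform of an abundance table
#'
#' Standard variance-stabilizing transform for count tables ahead of
#' centered PCA; the +1 offset admits zero counts.
#'
#' @param x Matrix or wide data frame of non-negative abundances.
#' @return Matrix of the same shape.
#' @export
log1p_abundance <- function(x) {
  m <- as_abundance_matrix(x)
  log1p(m)
}

#' @export
print.pca_result <- function(x, ...) {
  cat("Centered PCA:", nrow(x$scores), "sections,", nrow(x$loadings),
      "species,", x$n_axes, "retained axes\n")
  frac <- x$inertia_fraction[seq_len(x$n_axes)]
  cat("  inertia:", paste0(sprintf("%.1f%%", 100 * frac), collapse = " + "),
      sprintf("= %.1f%%\n", 100 * sum(frac)))
  invisible(x)
}

# uniform-weight cross-covariance of two centered score matrices
cross_cov <- function(x, y) crossprod(x, y) / nrow(x)

# RV coefficient between two (centered) score matrices
rv_statistic <- function(x, y) {
  cxy <- cross_cov(x, y)
  cxx <- cross_cov(x, x)
  cyy <- cross_cov(y, y)
  sum(cxy^2) / sqrt(sum(cxx^2) * sum(cyy^2))
}

coerce_scores <- function(x) {
  if (inherits(x, "pca_result")) return(x$scores)
  if (is.matrix(x)) return(scale(x, center = TRUE, scale = FALSE))
  abort("expected a pca_result or a numeric score matrix")
}

#' Co-inertia analysis of two ordinations
#'
#' Couples two PCA score matrices over the same sections: the co-inertia
#' axes are the singular vectors of the uniform-weight cross-covariance
#' of the two score matrices, maximizing the covariance between the
#' projected section coordinates. The RV coefficient (0--1) summarizes
#' the global coupling; its significance can be assessed by
#' [rv_permutation_test()].
#'
#' @param pca_x,pca_y `pca_result` objects (or centered score matrices)
#'   over the same sections in the same order.
#' @param n_perm If non-`NULL`, run the RV permutation test with this many
#'   permutations.
#' @param seed Seed for the permutation test (required with `n_perm`).
#' @return A `coinertia_result`: `rv`, `axes_x`/`axes_y` (unit vectors in
#'   each score space), `scores_x`/`scores_y` (section coordinates on the
#'   co-inertia axes), `axis_correlations` (of co-inertia scores with each
#'   table's own PCs), `inertia_fraction` (per co-inertia axis, from the
#'   squared singular values), and `permutation_p` when requested.
#' @export
coinertia <- function(pca_x, pca_y, n_perm = NULL, seed = NULL) {
  x <- coerce_scores(pca_x)
  y <- coerce_scores(pca_y)
  if (nrow(x) != nrow(y) ||
      !identical(rownames(x), rownames(y))) {
    abort("the two ordinations must share the same sections in the same order")
  }
  cxy <- cross_cov(x, y)
  sv <- svd(cxy)
  k <- length(sv$d)
  scores_x <- x %*% sv$u
  scores_y <- y %*% sv$v
  colnames(scores_x) <- colnames(scores_y) <- paste0("CoPC", seq_len(k))
  ax_cor <- function(ci_scores, pc_scores) {
    out <- suppressWarnings(cor(ci_scores, pc_scores))
    out[!is.finite(out)] <- NA_real_
    out
  }
  structure(list(
    rv = rv_statistic(x, y),
    axes_x = sv$u, axes_y = sv$v,
    singular_values = sv$d,
    inertia_fraction = if (sum(sv$d^2) > 0) sv$d^2 / sum(sv$d^2) else sv$d,
    scores_x = scores_x, scores_y = scores_y,
    axis_correlations = list(x = ax_cor(scores_x, x), y = ax_cor(scores_y, y)),
    permutation_p = if (!is.null(n_perm)) {
      rv_permutation_test(x, y, n_perm = n_perm, seed = seed)$p_value
    } else NA_real_),
    class = "coinertia_result")
}

#' @export
print.coinertia_result <- function(x, ...) {
  cat(sprintf("Co-inertia analysis: RV = %.3f", x$rv))
  if (!is.na(x$permutation_p)) cat(sprintf(" (permutation p = %.4g)", x$permutation_p))
  cat("\n  co-inertia axis inertia:",
      paste0(sprintf("%.1f%%", 100 * x$inertia_fraction), collapse = ", "), "\n")
  invisible(x)
}

#' Permutation test of the RV coefficient
#'
#' Permutes the section rows of one score matrix and recomputes RV. With
#' random sampling the p-value is `(1 + exceedances) / (1 + n_perm)`;
#' with `method = "exhaustive"` every row order is enumerated and the
#' p-value is the exact fraction of orders (including the identity) whose
#' RV reaches the observed one.
#'
#' @param pca_x,pca_y `pca_result` objects or centered score matrices.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Seed (required for the sampled test).
#' @param method `"sample"` (default) or `"exhaustive"` (feasible for
#'   small section counts only).
#' @return One-row tibble: `rv`, `p_value`, `n_perm`, `method`.
#' @export
rv_permutation_test <- function(pca_x, pca_y, n_perm = 999L, seed = NULL,
                                method = c("sample", "exhaustive")) {
  method <- match.arg(method)
  x <- coerce_scores(pca_x)
  y <- coerce_scores(pca_y)
  n <- nrow(x)
  obs <- rv_statistic(x, y)
  if (method == "exhaustive") {
    perms <- all_permutations(n)
    rvs <- apply(perms, 1, function(p) rv_statistic(x[p, , drop = FALSE], y))
    p <- mean(rvs >= obs - 1e-12)
    return(tibble::tibble(rv = obs, p_value = p, n_perm = nrow(perms),
                          method = method))
  }
  if (n_perm < 99) abort("n_perm must be at least 99")
  if (is.null(seed)) abort("seed is required for the sampled permutation test")
  exceed <- withr::with_seed(seed, {
    sum(purrr::map_lgl(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      rv_statistic(x[p, , drop = FALSE], y) >= obs - 1e-12
    }))
  })
  tibble::tibble(rv = obs, p_value = (1 + exceed) / (1 + n_perm),
                 n_perm = n_perm, method = method)
}

all_permutations <- function(n) {
  n <- as.integer(n)
  if (n > 8) abort("exhaustive enumeration is limited to n <= 8 sections")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    cbind(sub[, seq_len(pos - 1L), drop = FALSE],
          n,
          if (pos <= n - 1L) sub[, pos:(n - 1L), drop = FALSE])
  }))
}

#' Identity-line regression diagnostics
#'
#' Ordinary least squares of one set of section coordinates on another,
#' with Student t-tests of the slope against 1 and the intercept against
#' 0 — the two coordinates describe the same sections, so agreement means
#' the regression line is indistinguishable from the identity line.
#'
#' @param scores_a,scores_b Numeric vectors of per-section coordinates
#'   (`scores_b` is regressed on `scores_a`).
#' @return One-row tibble: `slope`, `intercept`, `r_squared`,
#'   `t_slope_vs_1`, `p_slope_vs_1`, `t_intercept_vs_0`,
#'   `p_intercept_vs_0`, `n`.
#' @export
identity_regression <- function(scores_a, scores_b) {
  n <- length(scores_a)
  if (n < 3) abort("need at least 3 sections")
  if (length(scores_b) != n) abort("coordinate vectors differ in length")
  if (sd(scores_a) == 0) abort("zero variance in the predictor coordinates")
  fit <- stats::lm(scores_b ~ scores_a)
  # degenerate exact fits are handled explicitly below
  sfit <- suppressWarnings(summary(fit))
  cf <- sfit$coefficients
  slope <- cf["scores_a", "Estimate"]
  intercept <- cf["(Intercept)", "Estimate"]
  r2 <- sfit$r.squared
  if (sfit$sigma < 1e-12) {
    # exact linear relation: residual SE is 0 and the t statistics are
    # degenerate; report exact identity as p = 1, any other line as p = 0
    exact_identity <- abs(slope - 1) < 1e-10 && abs(intercept) < 1e-10
    return(tibble::tibble(
      slope = slope, intercept = intercept, r_squared = r2,
      t_slope_vs_1 = NA_real_,
      p_slope_vs_1 = if (abs(slope - 1) < 1e-10) 1 else 0,
      t_intercept_vs_0 = NA_real_,
      p_intercept_vs_0 = if (abs(intercept) < 1e-10) 1 else 0,
      n = n, exact_identity = exact_identity))
  }
  t_slope <- (slope - 1) / cf["scores_a", "Std. Error"]
  t_int <- intercept / cf["(Intercept)", "Std. Error"]
  df <- fit$df.residual
  tibble::tibble(
    slope = slope, intercept = intercept, r_squared = r2,
    t_slope_vs_1 = t_slope,
    p_slope_vs_1 = 2 * pt(abs(t_slope), df, lower.tail = FALSE),
    t_intercept_vs_0 = t_int,
    p_intercept_vs_0 = 2 * pt(abs(t_int), df, lower.tail = FALSE),
    n = n, exact_identity = FALSE)
}
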