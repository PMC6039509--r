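#' Bray-Curtis dissimilarity between sites
#'
#' Compositional dissimilarity d(i, j) = sum|x_i - x_j| / sum(x_i + x_j),
#' bounded in \[0, 1\]: 0 for identical rows, 1 for disjoint supports.
#'
#' @param x Site-by-species abundance matrix (or wide data frame, first
#'   non-numeric column = site id). Rows must be non-negative with a
#'   positive total.
#' @return Symmetric site-by-site dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(x) {
  m <- as_abundance_matrix(x)
  zero <- rownames(m)[rowSums(m) == 0]
  if (length(zero) > 0) {
    abort(paste0("all-zero abundance row(s): ", paste(zero, collapse = ", ")))
  }
  as.matrix(vegan::vegdist(m, method = "bray"))
}

upper_tri <- function(m) m[upper.tri(m)]

#' Mantel test between two distance matrices
#'
#' The Mantel statistic r is the Pearson correlation of the upper
#' triangles. Significance comes from simultaneous row/column
#' permutations of the second matrix, one-tailed for r at least as large
#' as observed, with p = (1 + exceedances) / (1 + n_perm). With
#' `method = "exhaustive"` all n! site orders are enumerated and the
#' p-value is the exact fraction of orders reaching the observed r.
#'
#' @param d1,d2 Symmetric matrices over the same sites.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Seed (required for the sampled test).
#' @param method `"sample"` or `"exhaustive"` (small n only).
#' @return One-row tibble: `r`, `p_value`, `n_perm`, `method`. `r` is
#'   `NA` when either upper triangle is constant.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = NULL,
                        method = c("sample", "exhaustive")) {
  method <- match.arg(method)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) abort("distance matrices differ in size")
  v1 <- upper_tri(d1)
  if (sd(v1) == 0 || sd(upper_tri(d2)) == 0) {
    return(tibble::tibble(r = NA_real_, p_value = NA_real_,
                          n_perm = 0L, method = method))
  }
  obs <- cor(v1, upper_tri(d2))
  n <- nrow(d1)
  perm_r <- function(p) cor(v1, upper_tri(d2[p, p, drop = FALSE]))
  if (method == "exhaustive") {
    perms <- all_permutations(n)
    rs <- apply(perms, 1, perm_r)
    return(tibble::tibble(r = obs, p_value = mean(rs >= obs - 1e-12),
                          n_perm = nrow(perms), method = method))
  }
  if (is.null(seed)) abort("seed is required for the sampled permutation test")
  exceed <- withr::with_seed(seed, {
    sum(purrr::map_lgl(seq_len(n_perm),
                       function(i) perm_r(sample.int(n)) >= obs - 1e-12))
  })
  tibble::tibble(r = obs, p_value = (1 + exceed) / (1 + n_perm),
                 n_perm = n_perm, method = method)
}

#' Mantel correlogram along the river axis
#'
#' Splits site pairs into contiguous distance classes of fixed width and
#' computes, per class, the Mantel correlation between the community
#' dissimilarity matrix and the class-membership indicator matrix. The
#' statistic is sign-flipped so that a positive value means sites of that
#' class are more similar than average (positive spatial
#' autocorrelation). Per-class permutation p-values are corrected
#' progressively (Holm over the classes tested so far). The
#' autocorrelation extent is the upper edge of the last class in the
#' initial run of significant positive classes.
#'
#' @param d_comm Community dissimilarity matrix (e.g. [bray_curtis()]).
#' @param positions Kilometre points of the sites, in matrix row order;
#'   separation is measured along the river axis.
#' @param class_width_km Width of each distance class (default 10).
#' @param n_classes Number of classes; default covers the largest
#'   observed separation.
#' @param n_perm Permutations per class (default 999).
#' @param seed Seed for the class permutations.
#' @param alpha Significance level on the corrected p-values (default
#'   0.05).
#' @return A `correlogram_result`: `$classes` tibble (`class_index`,
#'   `lower_km`, `upper_km`, `midpoint_km`, `n_pairs`, `r`, `p_value`,
#'   `p_corrected`, `significant`) and `$extent_km`.
#' @export
mantel_correlogram <- function(d_comm, positions, class_width_km = 10,
                               n_classes = NULL, n_perm = 999L, seed = NULL,
                               alpha = 0.05) {
  d_comm <- as.matrix(d_comm)
  n <- nrow(d_comm)
  if (length(positions) != n) abort("positions must match the matrix rows")
  if (class_width_km <= 0) abort("class_width_km must be positive")
  d_geo <- abs(outer(positions, positions, "-"))
  if (is.null(n_classes)) n_classes <- ceiling(max(upper_tri(d_geo)) / class_width_km)
  if (n_classes < 2) abort("need at least 2 distance classes")
  if (is.null(seed)) abort("seed is required for the permutation tests")
  edges <- class_width_km * (0:n_classes)
  classes <- purrr::map_dfr(seq_len(n_classes), function(ci) {
    inside <- d_geo >= edges[ci] & d_geo < edges[ci + 1]
    diag(inside) <- FALSE
    n_pairs <- sum(upper_tri(inside))
    if (n_pairs == 0 || n_pairs == choose(n, 2)) {
      return(tibble::tibble(class_index = ci, lower_km = edges[ci],
                            upper_km = edges[ci + 1],
                            midpoint_km = (edges[ci] + edges[ci + 1]) / 2,
                            n_pairs = n_pairs, r = NA_real_,
                            p_value = NA_real_))
    }
    ind <- matrix(as.numeric(inside), n, n)
    # positive r = within-class pairs less dissimilar than average
    v_ind <- upper_tri(ind)
    v_comm <- upper_tri(d_comm)
    obs <- -cor(v_comm, v_ind)
    exceed_hi <- 0L; exceed_lo <- 0L
    withr::with_seed(seed + ci, {
      for (i in seq_len(n_perm)) {
        p <- sample.int(n)
        r_p <- -cor(upper_tri(d_comm[p, p]), v_ind)
        if (r_p >= obs - 1e-12) exceed_hi <- exceed_hi + 1L
        if (r_p <= obs + 1e-12) exceed_lo <- exceed_lo + 1L
      }
    })
    # one-tailed in the direction of the observed statistic
    exceed <- if (obs >= 0) exceed_hi else exceed_lo
    tibble::tibble(class_index = ci, lower_km = edges[ci],
                   upper_km = edges[ci + 1],
                   midpoint_km = (edges[ci] + edges[ci + 1]) / 2,
                   n_pairs = n_pairs, r = obs,
                   p_value = (1 + exceed) / (1 + n_perm))
  })
  # progressive Holm correction: class i is corrected within classes 1..i
  tested <- which(!is.na(classes$p_value))
  p_corr <- rep(NA_real_, nrow(classes))
  for (j in seq_along(tested)) {
    i <- tested[j]
    p_corr[i] <- stats::p.adjust(classes$p_value[tested[seq_len(j)]],
                                 method = "holm")[j]
  }
  classes$p_corrected <- p_corr
  classes$significant <- !is.na(p_corr) & p_corr < alpha
  run <- classes$significant & !is.na(classes$r) & classes$r > 0
  extent <- 0
  for (i in seq_len(nrow(classes))) {
    if (isTRUE(run[i])) extent <- classes$upper_km[i] else break
  }
  structure(list(classes = classes, extent_km = extent, alpha = alpha,
                 n_perm = n_perm, class_width_km = class_width_km),
            class = "correlogram_result")
}

#' @export
print.correlogram_result <- function(x, ...) {
  cat(sprintf("Mantel correlogram: %d classes of %g km, extent %g km\n",
              nrow(x$classes), x$class_width_km, x$extent_km))
  print(x$classes, ...)
  invisible(x)
}
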