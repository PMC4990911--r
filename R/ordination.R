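# Sample ordination (classical MDS) and a distance-based permutation
# multivariate ANOVA (PERMANOVA-style pseudo-F) for group separation.

#' Pairwise sample distance matrix
#'
#' Euclidean distance on per-feature standardized values (features with
#' zero variance are dropped), or 1 - Pearson correlation between sample
#' profiles.
#'
#' @param values Numeric matrix, features (sites/genes) x samples, no
#'   missing values.
#' @param metric "euclidean" or "one_minus_pearson".
#' @param standardize Standardize features before Euclidean distance
#'   (default `TRUE`).
#' @return A symmetric `dist`-convertible matrix with zero diagonal;
#'   attribute `"metric"` records the choice.
#' @export
distance_matrix <- function(values,
                            metric = c("euclidean", "one_minus_pearson"),
                            standardize = TRUE) {
  metric <- match.arg(metric)
  if (any(is.na(values))) stop("distance_matrix: missing values")
  if (metric == "euclidean") {
    v <- values
    if (standardize) {
      sds <- apply(v, 1, stats::sd)
      v <- v[sds > 0, , drop = FALSE]
      v <- (v - rowMeans(v)) / apply(v, 1, stats::sd)
    }
    d <- as.matrix(stats::dist(t(v)))
  } else {
    sds <- apply(values, 2, stats::sd)
    if (any(sds == 0))
      stop("distance_matrix: constant sample vector(s): ",
           paste(colnames(values)[sds == 0], collapse = ", "))
    d <- 1 - stats::cor(values)
    diag(d) <- 0
  }
  attr(d, "metric") <- metric
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix and takes the top-`k`
#' positive-eigenvalue axes. If fewer than `k` positive eigenvalues
#' exist, the dimensionality is reduced with a warning. Coordinates are
#' centered at the origin.
#'
#' @param d Distance matrix (symmetric matrix or `dist`).
#' @param k Number of dimensions (default 2).
#' @return Matrix of sample coordinates (samples x <= k), with eigenvalues
#'   as attribute `"eig"`.
#' @export
classical_mds <- function(d, k = 2) {
  dm <- as.matrix(d)
  if (all(dm == 0)) {
    coords <- matrix(0, nrow(dm), k,
                     dimnames = list(rownames(dm), NULL))
    attr(coords, "eig") <- rep(0, nrow(dm))
    return(coords)
  }
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = k,
                                          eig = TRUE))
  n_pos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  if (n_pos < k) {
    warning(sprintf("classical_mds: only %d positive eigenvalue axes; k reduced",
                    n_pos))
    k <- n_pos
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  coords <- sweep(coords, 2, colMeans(coords))
  attr(coords, "eig") <- fit$eig
  coords
}

# Pseudo-F for a given label assignment from a squared-distance matrix.
permanova_stat <- function(d2, labels) {
  n <- nrow(d2)
  groups <- unique(labels)
  a <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in groups) {
    idx <- which(labels == g)
    ss_within <- ss_within +
      sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

#' Distance-based permutation multivariate ANOVA
#'
#' PERMANOVA-style pseudo-F contrasting between-group and within-group
#' sums of squared distances, with an empirical p-value from random label
#' permutations: `p = (#(F* >= F) + 1) / (n_perm + 1)`.
#'
#' @param d Distance matrix (symmetric matrix or `dist`).
#' @param labels Group labels, one per sample; >= 2 groups with >= 2
#'   samples each.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed; reproducible.
#' @return List with `pseudo_f`, `p`, `n_perm`.
#' @export
permutation_manova <- function(d, labels, n_perm = 999L, seed = 1L) {
  dm <- as.matrix(d)
  labels <- as.character(labels)
  stopifnot(nrow(dm) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2L) stop("permutation_manova: need >= 2 groups")
  if (any(tab < 2L)) stop("permutation_manova: every group needs >= 2 samples")
  d2 <- dm^2
  f_obs <- permanova_stat(d2, labels)
  f_perm <- with_rng_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      permanova_stat(d2, sample(labels)), numeric(1))
  })
  p <- (sum(f_perm >= f_obs) + 1) / (n_perm + 1)
  list(pseudo_f = f_obs, p = p, n_perm = n_perm)
}
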