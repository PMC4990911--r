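# Two-group differential expression on gene-level counts: median-of-ratios
# normalization, a transparent NB-Wald test with trend-shrunk moment
# dispersion, and hypergeometric over-representation analysis.

#' Construct a gene-level expression count matrix
#'
#' @param counts Non-negative integer matrix, genes x samples, with unique
#'   gene rownames.
#' @param samples Sample sheet data frame (`sample_id`, `generation`,
#'   `tissue`, `group`), one row per column.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == nrow(samples))
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("expr_matrix: counts need unique gene-id rownames")
  if (any(is.na(counts)) || any(counts < 0))
    stop("expr_matrix: counts must be non-negative with no missing entries")
  colnames(counts) <- samples$sample_id
  obj <- list(counts = counts, samples = samples)
  class(obj) <- "expr_matrix"
  obj
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' Median-of-ratios size factors
#'
#' Per-sample factor = median over genes of the ratio of the sample's
#' count to the gene-wise geometric mean, computed over genes expressed in
#' all samples; factors are rescaled to geometric mean 1.
#'
#' @param x An [expr_matrix()] or a counts matrix.
#' @return Named positive numeric vector of size factors.
#' @export
normalize_size_factors <- function(x) {
  counts <- if (inherits(x, "expr_matrix")) x$counts else as.matrix(x)
  if (ncol(counts) < 2L) stop("normalize_size_factors: need >= 2 samples")
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  usable <- is.finite(loggeo)
  if (!any(usable))
    stop("normalize_size_factors: no gene expressed in all samples")
  sf <- apply(logc[usable, , drop = FALSE], 2, function(lc)
    exp(stats::median(lc - loggeo[usable])))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Mean normalized coverage over tested genes
#'
#' @param x An [expr_matrix()].
#' @param genes Gene ids defining the tested subset (default: all).
#' @param size_factors Optional precomputed size factors.
#' @return Mean of normalized counts over the tested genes and samples.
#' @export
mean_coverage <- function(x, genes = rownames(x$counts),
                          size_factors = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (length(genes) == 0L) stop("mean_coverage: empty tested gene set")
  if (is.null(size_factors)) size_factors <- normalize_size_factors(x)
  norm <- sweep(x$counts[genes, , drop = FALSE], 2, size_factors, "/")
  mean(norm)
}

# Moment dispersion per gene, shrunk toward a 1/mean trend on the log
# scale (prior weight 2). Returns the per-gene dispersions used by the
# Wald test.
estimate_dispersions <- function(norm, group, floor = 1e-8,
                                 prior_weight = 2) {
  groups <- unique(group)
  n1 <- sum(group == groups[1]); n2 <- sum(group == groups[2])
  m1 <- rowMeans(norm[, group == groups[1], drop = FALSE])
  m2 <- rowMeans(norm[, group == groups[2], drop = FALSE])
  v1 <- apply(norm[, group == groups[1], drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, group == groups[2], drop = FALSE], 1, stats::var)
  v <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mu <- (n1 * m1 + n2 * m2) / (n1 + n2)
  disp_raw <- (v - mu) / mu^2
  disp <- pmax(disp_raw, floor)
  pos <- disp_raw > 0 & mu > 0
  if (sum(pos) >= 10) {
    fit <- stats::lm(disp_raw[pos] ~ I(1 / mu[pos]))
    co <- stats::coef(fit)
    trend <- pmax(co[1] + co[2] / mu, floor)
  } else {
    trend <- rep(pmax(mean(disp), floor), length(disp))
  }
  exp((log(disp) + prior_weight * log(trend)) / (1 + prior_weight))
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' Normalizes by median-of-ratios size factors, removes genes below an
#' independent low-count filter (mean normalized count < `min_mean`) from
#' testing and from the BH denominator, estimates per-gene NB dispersion
#' by the method of moments shrunk toward a mean-dispersion trend, fits a
#' per-gene NB log-linear model of counts on group (size factors as
#' offsets) at the shrunk dispersion, and reports a Wald p-value on the
#' group log2 fold change, BH-adjusted across tested genes. Because the
#' dispersion is estimated from the same few replicates, the Wald
#' statistic is referred to a moderated t distribution instead of a
#' normal: the residual degrees of freedom `n1 + n2 - 2` are scaled by
#' `1 + prior_weight` to credit the information borrowed from the
#' mean-dispersion trend during shrinkage. Direction is
#' "up" for significant positive log2FC (exposed over control), "down"
#' symmetric, else "ns".
#'
#' @param x An [expr_matrix()].
#' @param contrast List with optional `tissue`, `generation`, and `groups`
#'   (control first; default `c("Ctrl", "DSS")`).
#' @param q_threshold BH significance threshold (default 0.05).
#' @param min_mean Independent-filter floor on mean normalized counts
#'   (default 1).
#' @param dispersion_floor Lower bound on dispersions (default 1e-8).
#' @param prior_weight Weight of the mean-dispersion trend in the
#'   shrinkage (default 2); also sets the moderated degrees of freedom.
#' @return Data frame (class `de_result`): gene, log2fc, p, q, direction,
#'   flag; attribute `"summary"` with n_tested, n_up, n_down and the mean
#'   coverage of tested genes.
#' @export
de_test <- function(x, contrast = NULL, q_threshold = 0.05, min_mean = 1,
                    dispersion_floor = 1e-8, prior_weight = 2) {
  stopifnot(inherits(x, "expr_matrix"))
  s <- x$samples
  sel <- rep(TRUE, nrow(s))
  groups <- c("Ctrl", "DSS")
  if (!is.null(contrast)) {
    if (!is.null(contrast$tissue)) sel <- sel & s$tissue == contrast$tissue
    if (!is.null(contrast$generation))
      sel <- sel & s$generation == contrast$generation
    if (!is.null(contrast$groups)) groups <- contrast$groups
  }
  j1 <- which(sel & s$group == groups[1])
  j2 <- which(sel & s$group == groups[2])
  if (length(j1) < 2L || length(j2) < 2L)
    stop("de_test: need >= 2 samples per group")
  jj <- c(j1, j2)
  counts <- x$counts[, jj, drop = FALSE]
  group <- factor(rep(c("ctrl", "exp"), c(length(j1), length(j2))),
                  levels = c("ctrl", "exp"))
  sf <- normalize_size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  tested <- rowMeans(norm) >= min_mean
  if (!any(tested)) stop("de_test: no gene passes the low-count filter")

  nt <- norm[tested, , drop = FALSE]
  ct <- counts[tested, , drop = FALSE]
  disp <- estimate_dispersions(nt, group, floor = dispersion_floor,
                               prior_weight = prior_weight)

  off <- log(sf)
  df_mod <- (length(jj) - 2L) * (1 + prior_weight)
  n_genes <- nrow(ct)
  log2fc <- numeric(n_genes); p <- rep(NA_real_, n_genes)
  flag <- character(n_genes)
  for (i in seq_len(n_genes)) {
    y <- ct[i, ]
    if (all(y == 0)) { log2fc[i] <- 0; p[i] <- 1; flag[i] <- "all_zero"; next }
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ group + offset(off),
                                  family = MASS::negative.binomial(
                                    theta = 1 / disp[i]))),
      error = function(e) NULL)
    if (is.null(fit)) {
      # fall back to the delta-method Wald on group means
      mu1 <- mean(nt[i, group == "ctrl"]); mu2 <- mean(nt[i, group == "exp"])
      eps <- 0.5
      log2fc[i] <- log2((mu2 + eps) / (mu1 + eps))
      v1 <- (1 / length(j1)) * (1 / max(mu1, eps) + disp[i])
      v2 <- (1 / length(j2)) * (1 / max(mu2, eps) + disp[i])
      z <- log((mu2 + eps) / (mu1 + eps)) / sqrt(v1 + v2)
      p[i] <- 2 * stats::pt(-abs(z), df = df_mod)
      flag[i] <- "fallback"
      next
    }
    co <- summary(fit)$coefficients
    log2fc[i] <- co["groupexp", "Estimate"] / log(2)
    p[i] <- 2 * stats::pt(-abs(co["groupexp", "Estimate"] /
                                 co["groupexp", "Std. Error"]),
                          df = df_mod)
  }
  q <- bh_adjust(p)
  direction <- rep("ns", n_genes)
  direction[q < q_threshold & log2fc > 0] <- "up"
  direction[q < q_threshold & log2fc < 0] <- "down"
  res <- data.frame(gene = rownames(ct), log2fc = log2fc, p = p, q = q,
                    direction = direction, flag = flag,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "summary") <- data.frame(
    n_tested = n_genes,
    n_up = sum(direction == "up"),
    n_down = sum(direction == "down"),
    mean_coverage = mean(nt))
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(paste0("de_result: %d genes tested (mean coverage %.2fx), ",
                     "%d up- and %d down-regulated\n"),
              s$n_tested, s$mean_coverage, s$n_up, s$n_down))
  NextMethod()
}

#' Read a GMT gene-set collection
#' @param path GMT file path.
#' @return Named list of gene-id character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the query genes within
#' the universe (upper-tail hypergeometric), BH-adjusted across sets.
#' Sets are intersected with the universe before testing.
#'
#' @param de_genes Character vector of query genes (must lie in
#'   `universe`).
#' @param universe Character vector, the tested-gene universe.
#' @param gene_sets Named list of gene-id vectors (e.g. [read_gmt()]).
#' @return Data frame: set, set_size, overlap, fold, p, q.
#' @export
ora_enrichment <- function(de_genes, universe, gene_sets) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("ora_enrichment: empty universe")
  if (!all(de_genes %in% universe))
    stop("ora_enrichment: de_genes must be a subset of the universe")
  de_genes <- unique(de_genes)
  N <- length(universe); nde <- length(de_genes)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(set, de_genes))
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, length(set), N - length(set), nde,
                    lower.tail = FALSE)
    fold <- if (nde == 0 || length(set) == 0) NA_real_ else
      (k / nde) / (length(set) / N)
    data.frame(set = nm, set_size = length(set), overlap = k,
               fold = fold, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}
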