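# Analysis-ready per-CpG methylation matrix with sample metadata.

#' Construct a per-CpG methylation count matrix
#'
#' @param meth,unmeth Integer matrices (sites x samples) of methylated and
#'   unmethylated read counts; `NA` marks a site not covered in a sample.
#' @param sites Data frame with `chrom` and 1-based `pos`; must be unique.
#' @param samples Data frame with `sample_id`, `generation` (F0/F1),
#'   `tissue` (sperm/IEC) and `group` (Ctrl/DSS).
#' @return A `meth_matrix` object. Sites are stored strictly sorted by
#'   (chrom, pos).
#' @export
meth_matrix <- function(meth, unmeth, sites, samples) {
  meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
  storage.mode(meth) <- "integer"
  storage.mode(unmeth) <- "integer"
  stopifnot(nrow(meth) == nrow(sites), ncol(meth) == nrow(samples),
            all(dim(meth) == dim(unmeth)))
  if (anyDuplicated(sites[c("chrom", "pos")]))
    stop("meth_matrix: duplicated (chrom, pos) site keys")
  req <- c("sample_id", "generation", "tissue", "group")
  if (!all(req %in% names(samples)))
    stop("meth_matrix: samples must have columns ",
         paste(req, collapse = ", "))
  ord <- order(sites$chrom, sites$pos)
  obj <- list(meth = meth[ord, , drop = FALSE],
              unmeth = unmeth[ord, , drop = FALSE],
              sites = sites[ord, c("chrom", "pos"), drop = FALSE],
              samples = samples)
  rownames(obj$sites) <- NULL
  colnames(obj$meth) <- colnames(obj$unmeth) <- samples$sample_id
  class(obj) <- "meth_matrix"
  obj
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d CpG sites x %d samples\n",
              nrow(x$sites), nrow(x$samples)))
  tab <- table(x$samples$tissue, x$samples$generation, x$samples$group)
  print(tab)
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Coverage matrix (methylated + unmethylated reads)
#' @param m A [meth_matrix()].
#' @return Numeric matrix of per-site, per-sample coverage (`NA` where the
#'   site is not observed).
#' @export
coverage_matrix <- function(m) m$meth + m$unmeth

#' Per-site methylation fractions
#'
#' Methylation value = methylated / (methylated + unmethylated), in
#' `[0, 1]`. On a filtered matrix every entry is defined.
#'
#' @param m A [meth_matrix()].
#' @return Numeric matrix of methylation fractions.
#' @export
methylation_values <- function(m) {
  cov <- coverage_matrix(m)
  m$meth / cov
}

#' Quality-filter CpG sites by coverage
#'
#' Retains sites covered with at least `min_coverage` reads in every
#' sample (complete cases) and removes high-coverage outliers: sites above
#' a sample's `max_coverage_quantile` coverage quantile (guarding against
#' PCR duplicates) are dropped, and this trim is iterated to its fixed
#' point so that filtering is idempotent — applying the filter to an
#' already-filtered matrix changes nothing.
#'
#' @param m A [meth_matrix()].
#' @param min_coverage Minimum reads per site per sample (default 10).
#' @param max_coverage_quantile Upper coverage quantile per sample
#'   (default 0.999); sites above it in any sample are removed.
#' @return Filtered `meth_matrix`; attribute `"audit"` holds counts of
#'   input sites, complete cases, and sites removed by each predicate.
#' @export
filter_sites <- function(m, min_coverage = 10, max_coverage_quantile = 0.999) {
  stopifnot(inherits(m, "meth_matrix"))
  if (nrow(m$sites) == 0L) stop("filter_sites: empty matrix")
  cov <- coverage_matrix(m)
  complete <- rowSums(is.na(cov)) == 0L
  ok_min <- complete & rowSums(cov < min_coverage, na.rm = TRUE) == 0L
  keep <- complete & ok_min
  n_fail_max <- 0L
  if (max_coverage_quantile < 1) {
    repeat {
      if (!any(keep)) break
      hi <- apply(cov[keep, , drop = FALSE], 2, function(x)
        stats::quantile(x, max_coverage_quantile, names = FALSE))
      over <- keep & rowSums(sweep(cov, 2, hi, ">"), na.rm = TRUE) > 0L
      if (!any(over)) break
      n_fail_max <- n_fail_max + sum(over)
      keep <- keep & !over
    }
  }
  if (!any(keep))
    stop("filter_sites: all sites removed by the coverage filters")
  out <- meth_matrix(m$meth[keep, , drop = FALSE],
                     m$unmeth[keep, , drop = FALSE],
                     m$sites[keep, , drop = FALSE], m$samples)
  attr(out, "audit") <- data.frame(
    n_input = nrow(m$sites),
    n_complete = sum(complete),
    n_fail_min = sum(complete & !ok_min),
    n_fail_max = n_fail_max,
    n_retained = sum(keep))
  out
}

#' Classify imprinting-control loci
#'
#' Bisulfite-conversion sanity check: imprinted control loci are expected
#' to show no (< 0.10), partial, or complete (> 0.90) methylation. The
#' class is taken from the mean methylation across all retained CpGs of
#' the locus and all samples; loci with no retained CpG are reported as
#' "uncovered".
#'
#' @param m A filtered [meth_matrix()].
#' @param control_loci Data frame with `gene_id` (or `name`), `chrom`, and
#'   0-based half-open `start`, `end`.
#' @return Data frame with locus name, number of CpGs, mean methylation
#'   and class in `{none, partial, complete, uncovered}`.
#' @export
imprinting_control_report <- function(m, control_loci) {
  stopifnot(inherits(m, "meth_matrix"))
  vals <- methylation_values(m)
  nm <- if ("gene_id" %in% names(control_loci)) control_loci$gene_id
        else control_loci$name
  res <- lapply(seq_len(nrow(control_loci)), function(i) {
    in_locus <- m$sites$chrom == control_loci$chrom[i] &
      (m$sites$pos - 1) >= control_loci$start[i] &
      (m$sites$pos - 1) < control_loci$end[i]
    if (!any(in_locus))
      return(data.frame(locus = nm[i], n_cpgs = 0L,
                        mean_methylation = NA_real_, class = "uncovered"))
    mu <- mean(vals[in_locus, , drop = FALSE], na.rm = TRUE)
    cls <- if (mu < 0.10) "none" else if (mu > 0.90) "complete" else "partial"
    data.frame(locus = nm[i], n_cpgs = sum(in_locus),
               mean_methylation = mu, class = cls)
  })
  do.call(rbind, res)
}
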