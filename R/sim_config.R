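#' Simulation configuration for a synthetic inheritance study
#'
#' Bundles every parameter of the synthetic-data generator: genome geometry,
#' RRBS coverage and overdispersion, expression model, and the planted
#' intergenerational signal. Defaults describe a desk-scale two-chromosome
#' study with four biological replicates per group, ~30x per-CpG coverage
#' and a planted methylation shift of 0.3 at clustered promoter CpGs of the
#' inherited genes.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param n_genes Total number of genes across the genome.
#' @param genome_length_per_chrom Chromosome length in bp.
#' @param n_cpg_sites Total number of CpG sites to place.
#' @param promoter_window Length-2 integer vector `(upstream, downstream)`
#'   of the TSS, in bp, defining promoters (strand-aware).
#' @param n_samples_per_group Biological replicates per
#'   (generation, tissue, group) cell.
#' @param mean_coverage Mean per-CpG read coverage.
#' @param bb_dispersion Beta-binomial intra-class correlation rho in (0,1);
#'   biological variability of methylation between replicates.
#' @param baseline_meth_profile Mixture weights for the low (~0.05),
#'   intermediate (~0.5) and high (~0.95) baseline methylation states.
#' @param n_planted_inherited Number of genes given a concordant methylation
#'   shift in F0 sperm, F1 sperm and F1 IECs.
#' @param planted_delta Methylation shift in (0,1] at planted CpGs
#'   (exposed minus control, magnitude).
#' @param sites_per_planted_gene Number of clustered promoter CpGs shifted
#'   per planted gene.
#' @param coupling_fraction Fraction of planted genes whose expression is
#'   shifted concordantly (hypo-methylated -> up-regulated).
#' @param planted_log2fc Expression effect size (log2 fold change) for
#'   coupled genes.
#' @param n_de_background Number of additional non-inherited genes with a
#'   planted expression change (either sign), emulating the direct
#'   transcriptome response.
#' @param nb_dispersion Negative-binomial dispersion (1/size) for counts;
#'   the default 0.02 reflects the low biological variability of inbred
#'   littermate replicates.
#' @param expression_mean Median of the log-normal distribution of baseline
#'   gene expression means.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chromosomes = 2L,
                       n_genes = 2000L,
                       genome_length_per_chrom = 2e7,
                       n_cpg_sites = 8000L,
                       promoter_window = c(2000L, 500L),
                       n_samples_per_group = 4L,
                       mean_coverage = 30,
                       bb_dispersion = 0.02,
                       baseline_meth_profile = c(low = 0.55, mid = 0.15, high = 0.30),
                       n_planted_inherited = 50L,
                       planted_delta = 0.3,
                       sites_per_planted_gene = 5L,
                       coupling_fraction = 0.5,
                       planted_log2fc = 1,
                       n_de_background = 100L,
                       nb_dispersion = 0.02,
                       expression_mean = 30,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    n_genes = as.integer(n_genes),
    genome_length_per_chrom = as.numeric(genome_length_per_chrom),
    n_cpg_sites = as.integer(n_cpg_sites),
    promoter_window = as.integer(promoter_window),
    n_samples_per_group = as.integer(n_samples_per_group),
    mean_coverage = as.numeric(mean_coverage),
    bb_dispersion = as.numeric(bb_dispersion),
    baseline_meth_profile = baseline_meth_profile / sum(baseline_meth_profile),
    n_planted_inherited = as.integer(n_planted_inherited),
    planted_delta = as.numeric(planted_delta),
    sites_per_planted_gene = as.integer(sites_per_planted_gene),
    coupling_fraction = as.numeric(coupling_fraction),
    planted_log2fc = as.numeric(planted_log2fc),
    n_de_background = as.integer(n_de_background),
    nb_dispersion = as.numeric(nb_dispersion),
    expression_mean = as.numeric(expression_mean),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c("n_chromosomes", "n_genes", "n_cpg_sites", "n_samples_per_group",
              "sites_per_planted_gene")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stop(sprintf("sim_config: '%s' must be a single positive count", f))
  }
  if (cfg$n_planted_inherited < 0L || cfg$n_planted_inherited > cfg$n_genes)
    stop("sim_config: n_planted_inherited must be in [0, n_genes]")
  if (cfg$n_de_background < 0L)
    stop("sim_config: n_de_background must be >= 0")
  if (!(cfg$planted_delta > 0 && cfg$planted_delta <= 1) &&
      cfg$n_planted_inherited > 0L)
    stop("sim_config: planted_delta must be in (0, 1]")
  if (!(cfg$bb_dispersion > 0 && cfg$bb_dispersion < 1))
    stop("sim_config: bb_dispersion must be in (0, 1)")
  if (cfg$mean_coverage <= 0) stop("sim_config: mean_coverage must be > 0")
  if (length(cfg$promoter_window) != 2L || any(cfg$promoter_window < 0L))
    stop("sim_config: promoter_window must be two non-negative integers")
  if (length(cfg$baseline_meth_profile) != 3L ||
      any(cfg$baseline_meth_profile < 0))
    stop("sim_config: baseline_meth_profile needs 3 non-negative weights")
  if (!(cfg$coupling_fraction >= 0 && cfg$coupling_fraction <= 1))
    stop("sim_config: coupling_fraction must be in [0, 1]")
  if (cfg$nb_dispersion <= 0) stop("sim_config: nb_dispersion must be > 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%d chrom x %.3g bp, %d genes, %d CpGs", x$n_chromosomes,
              x$genome_length_per_chrom, x$n_genes, x$n_cpg_sites), "\n")
  cat(sprintf("  n/group = %d, coverage = %.1fx, rho = %.3g\n",
              x$n_samples_per_group, x$mean_coverage, x$bb_dispersion))
  cat(sprintf("  planted: %d genes x %d CpGs, delta = %.2f, coupling = %.2f (log2FC %.2f)\n",
              x$n_planted_inherited, x$sites_per_planted_gene,
              x$planted_delta, x$coupling_fraction, x$planted_log2fc))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}
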