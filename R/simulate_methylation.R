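# Beta-binomial RRBS count simulation with planted intergenerational
# methylation shifts and imprinting-control loci.

INHERITED_LAYERS <- c("sperm_F0", "sperm_F1", "IEC_F1")

layer_meta <- function(layer) {
  parts <- strsplit(layer, "_", fixed = TRUE)[[1]]
  list(tissue = parts[1], generation = parts[2])
}

#' Simulate per-CpG methylation counts for all study layers
#'
#' For each tissue-by-generation layer, draws per-sample coverage
#' (negative binomial around `mean_coverage`) and methylated counts from a
#' beta-binomial with intra-class correlation `bb_dispersion`. A set of
#' `n_planted_inherited` genes receives a concordant methylation shift of
#' `planted_delta` at `sites_per_planted_gene` clustered promoter CpGs in
#' the exposed (DSS) group of the three inheritance layers (F0 sperm,
#' F1 sperm, F1 IECs); "hypo" means lower methylation in the exposed group.
#' Seven imprinting-control loci are emitted at fixed methylation levels
#' (~0, ~0.5, ~1) in every sample, mimicking bisulfite-conversion controls.
#'
#' @param cfg A [sim_config()].
#' @param ann Result of [simulate_annotation()].
#' @param layers Character vector of layers to generate
#'   (`tissue_generation`).
#' @return List with `layers` (named list of [meth_matrix()] objects) and
#'   `truth` (ground-truth list: `inherited_genes`, `dm_sites`,
#'   `imprint_controls`).
#' @export
simulate_methylation <- function(cfg, ann,
                                 layers = c("sperm_F0", "sperm_F1",
                                            "IEC_F1", "IEC_F0")) {
  validate_sim_config(cfg)
  with_rng_seed(cfg$seed + 1L, simulate_methylation_impl(cfg, ann, layers))
}

simulate_methylation_impl <- function(cfg, ann, layers) {
  cpg <- ann$cpg_sites
  n_sites <- nrow(cpg)
  prom_cpgs <- ann$promoter_cpgs

  # imprinting-control loci: genes with >= 2 promoter CpGs
  imprint_classes <- c("none", "none", "partial", "partial",
                       "complete", "complete", "complete")
  imprint_levels <- c(none = 0.03, partial = 0.5, complete = 0.97)
  eligible_imp <- names(prom_cpgs)[vapply(prom_cpgs, length, 1L) >= 2L]
  if (length(eligible_imp) < length(imprint_classes))
    stop("too few genes with promoter CpGs to place imprinting controls")
  imprint_genes <- sample(eligible_imp, length(imprint_classes))
  imprint_site_idx <- unlist(prom_cpgs[imprint_genes], use.names = FALSE)

  # planted inherited genes: enough promoter CpGs, not imprint controls
  eligible <- setdiff(
    names(prom_cpgs)[vapply(prom_cpgs, length, 1L) >=
                       cfg$sites_per_planted_gene],
    imprint_genes)
  if (length(eligible) < cfg$n_planted_inherited)
    stop(sprintf(paste0("only %d genes have >= %d promoter CpGs; cannot ",
                        "plant %d inherited genes"),
                 length(eligible), cfg$sites_per_planted_gene,
                 cfg$n_planted_inherited))
  planted_genes <- if (cfg$n_planted_inherited > 0L)
    sample(eligible, cfg$n_planted_inherited) else character(0)
  planted_dir <- if (length(planted_genes) > 0L)
    sample(rep_len(c("hypo", "hyper"), length(planted_genes))) else character(0)
  names(planted_dir) <- planted_genes

  planted_site_idx <- integer(0)
  planted_site_dir <- character(0)
  planted_site_gene <- character(0)
  for (g in planted_genes) {
    idx <- sample(prom_cpgs[[g]], cfg$sites_per_planted_gene)
    planted_site_idx <- c(planted_site_idx, idx)
    planted_site_dir <- c(planted_site_dir,
                          rep(planted_dir[[g]], length(idx)))
    planted_site_gene <- c(planted_site_gene, rep(g, length(idx)))
  }
  if (any(planted_site_idx %in% imprint_site_idx))
    stop("planted site collides with an imprinting-control locus")

  # baseline methylation: bimodal mixture typical of RRBS
  state <- sample(c("low", "mid", "high"), n_sites, replace = TRUE,
                  prob = cfg$baseline_meth_profile)
  level <- c(low = 0.05, mid = 0.5, high = 0.95)[state]
  conc <- 50
  mu0 <- stats::rbeta(n_sites, level * conc, (1 - level) * conc)
  mu0 <- pmin(pmax(mu0, 0.01), 0.99)
  # planted baselines leave headroom for the shift in either direction
  mu0[planted_site_idx] <- ifelse(planted_site_dir == "hypo",
                                  0.5 + cfg$planted_delta / 2,
                                  0.5 - cfg$planted_delta / 2)
  imprint_class_per_site <- rep(NA_character_, n_sites)
  for (k in seq_along(imprint_genes))
    imprint_class_per_site[prom_cpgs[[imprint_genes[k]]]] <-
      imprint_classes[k]
  is_imp <- !is.na(imprint_class_per_site)
  mu0[is_imp] <- imprint_levels[imprint_class_per_site[is_imp]]

  shift <- numeric(n_sites)
  shift[planted_site_idx] <- ifelse(planted_site_dir == "hypo",
                                    -cfg$planted_delta, cfg$planted_delta)

  n <- cfg$n_samples_per_group
  rho <- cfg$bb_dispersion
  rho_imp <- 0.005
  out <- list()
  for (layer in layers) {
    lm <- layer_meta(layer)
    group <- rep(c("Ctrl", "DSS"), each = n)
    sample_id <- sprintf("%s_%s_%s_%d", lm$tissue, lm$generation, group,
                         rep(seq_len(n), 2))
    meth <- matrix(0L, n_sites, 2 * n)
    unmeth <- matrix(0L, n_sites, 2 * n)
    inherit_here <- layer %in% INHERITED_LAYERS
    for (j in seq_len(2 * n)) {
      mu <- mu0
      if (group[j] == "DSS" && inherit_here) mu <- mu + shift
      mu <- pmin(pmax(mu, 0.005), 0.995)
      r <- ifelse(is_imp, rho_imp, rho)
      size_par <- (1 - r) / r
      p <- stats::rbeta(n_sites, mu * size_par, (1 - mu) * size_par)
      cov <- pmax(1L, stats::rnbinom(n_sites, mu = cfg$mean_coverage,
                                     size = 10))
      m <- stats::rbinom(n_sites, cov, p)
      meth[, j] <- m
      unmeth[, j] <- cov - m
    }
    samples <- data.frame(sample_id = sample_id,
                          generation = lm$generation, tissue = lm$tissue,
                          group = group, stringsAsFactors = FALSE)
    out[[layer]] <- meth_matrix(meth, unmeth,
                                sites = cpg[c("chrom", "pos")],
                                samples = samples)
  }

  dm_sites <- data.frame(
    chrom = cpg$chrom[planted_site_idx],
    pos = cpg$pos[planted_site_idx],
    gene_id = planted_site_gene,
    direction = planted_site_dir,
    delta = shift[planted_site_idx],
    layers = rep(paste(intersect(layers, INHERITED_LAYERS),
                       collapse = ";"), length(planted_site_idx)),
    stringsAsFactors = FALSE)

  imprint_controls <- do.call(rbind, lapply(seq_along(imprint_genes),
    function(k) {
      idx <- prom_cpgs[[imprint_genes[k]]]
      data.frame(gene_id = imprint_genes[k], class = imprint_classes[k],
                 chrom = cpg$chrom[idx[1]],
                 start = min(cpg$pos[idx]) - 1,   # 0-based half-open locus
                 end = max(cpg$pos[idx]),
                 stringsAsFactors = FALSE)
    }))

  truth <- list(
    inherited_genes = data.frame(gene_id = planted_genes,
                                 direction = unname(planted_dir),
                                 stringsAsFactors = FALSE),
    dm_sites = dm_sites,
    imprint_controls = imprint_controls,
    de_genes = data.frame(gene_id = character(0), sign = numeric(0),
                          layer = character(0), stringsAsFactors = FALSE))
  list(layers = out, truth = truth)
}
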