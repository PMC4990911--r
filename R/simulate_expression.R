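# Negative-binomial expression count simulation with planted
# methylation-coupled effects.

#' Simulate gene-level expression counts
#'
#' Draws negative-binomial counts for every annotated gene in each
#' requested expression layer. A `coupling_fraction` of the planted
#' inherited genes receives an expression shift of `planted_log2fc` in the
#' exposed group of F1 IECs, with sign coupled to the methylation
#' direction: hypo-methylated genes go up, hyper-methylated genes go down
#' (the dominant regulation quadrants). Each expression layer additionally
#' receives `n_de_background` unlinked differentially expressed genes with
#' random sign, emulating the direct transcriptome response. Library sizes
#' vary by +/-30% through true per-sample size factors.
#'
#' @param cfg A [sim_config()].
#' @param ann Result of [simulate_annotation()].
#' @param truth Ground-truth list from [simulate_methylation()]; its
#'   `de_genes` element is filled in.
#' @param layers Expression layers to generate (default F1 and F0 IECs).
#' @return List with `layers` (named list of [expr_matrix()] objects) and
#'   the updated `truth`.
#' @export
simulate_expression <- function(cfg, ann, truth,
                                layers = c("IEC_F1", "IEC_F0")) {
  validate_sim_config(cfg)
  with_rng_seed(cfg$seed + 2L,
                simulate_expression_impl(cfg, ann, truth, layers))
}

simulate_expression_impl <- function(cfg, ann, truth, layers) {
  genes <- ann$features[ann$features$kind == "gene", ]
  gene_ids <- genes$gene_id
  n_genes <- length(gene_ids)
  base_mu <- stats::rlnorm(n_genes, log(cfg$expression_mean), 1.2)
  names(base_mu) <- gene_ids

  inherited <- truth$inherited_genes
  n_coupled <- round(cfg$coupling_fraction * nrow(inherited))
  coupled <- if (n_coupled > 0L)
    inherited[sample(nrow(inherited), n_coupled), ] else inherited[0, ]
  coupled_sign <- ifelse(coupled$direction == "hypo", 1, -1)

  n <- cfg$n_samples_per_group
  size_nb <- 1 / cfg$nb_dispersion
  out <- list()
  de_records <- list()
  for (layer in layers) {
    lm <- layer_meta(layer)
    group <- rep(c("Ctrl", "DSS"), each = n)
    sample_id <- sprintf("%s_%s_%s_%d", lm$tissue, lm$generation, group,
                         rep(seq_len(n), 2))
    lfc <- numeric(n_genes)
    names(lfc) <- gene_ids
    if (layer == "IEC_F1" && nrow(coupled) > 0L)
      lfc[coupled$gene_id] <- coupled_sign * cfg$planted_log2fc
    bg_pool <- setdiff(gene_ids, c(truth$inherited_genes$gene_id))
    n_bg <- min(cfg$n_de_background, length(bg_pool))
    bg <- if (n_bg > 0L) sample(bg_pool, n_bg) else character(0)
    if (n_bg > 0L)
      lfc[bg] <- sample(c(-1, 1), n_bg, replace = TRUE) * cfg$planted_log2fc

    sf_true <- stats::runif(2 * n, 0.7, 1.3)
    counts <- matrix(0L, n_genes, 2 * n,
                     dimnames = list(gene_ids, sample_id))
    for (j in seq_len(2 * n)) {
      mu <- base_mu * sf_true[j]
      if (group[j] == "DSS") mu <- mu * 2^lfc
      counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = size_nb)
    }
    samples <- data.frame(sample_id = sample_id,
                          generation = lm$generation, tissue = lm$tissue,
                          group = group, stringsAsFactors = FALSE)
    out[[layer]] <- expr_matrix(counts, samples)
    de_idx <- which(lfc != 0)
    if (length(de_idx) > 0L)
      de_records[[layer]] <- data.frame(gene_id = gene_ids[de_idx],
                                        sign = sign(lfc[de_idx]),
                                        layer = layer,
                                        stringsAsFactors = FALSE)
  }
  truth$de_genes <- if (length(de_records) > 0L)
    do.call(rbind, c(de_records, list(make.row.names = FALSE)))
  else truth$de_genes
  list(layers = out, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_annotation()],
#' [simulate_methylation()] and [simulate_expression()] under one
#' configuration.
#'
#' @param cfg A [sim_config()].
#' @param meth_layers,expr_layers Layers passed through to the stage
#'   generators.
#' @return List with `annotation`, `methylation` (named list of
#'   [meth_matrix()]), `expression` (named list of [expr_matrix()]), and
#'   `truth`.
#' @export
simulate_study <- function(cfg,
                           meth_layers = c("sperm_F0", "sperm_F1",
                                           "IEC_F1", "IEC_F0"),
                           expr_layers = c("IEC_F1", "IEC_F0")) {
  ann <- simulate_annotation(cfg)
  meth <- simulate_methylation(cfg, ann, meth_layers)
  expr <- simulate_expression(cfg, ann, meth$truth, expr_layers)
  list(annotation = ann, methylation = meth$layers,
       expression = expr$layers, truth = expr$truth)
}
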