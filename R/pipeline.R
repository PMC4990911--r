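# Configuration-driven orchestration of the full analysis: QC ->
# differential methylation per contrast -> differential expression ->
# annotation -> cross-set overlaps with permutation nulls -> quadrant
# integration -> ordination -> report.

#' Pipeline configuration
#'
#' Houses the study constants: the 0.20 methylation-difference rule, the
#' adjusted-p 0.05 significance threshold and the 10,000-permutation null
#' are the defaults.
#'
#' @param sim A [sim_config()] for a synthetic run, or `NULL` to read a
#'   study from `input_dir`.
#' @param input_dir Directory in [write_simulation()] layout (used when
#'   `sim` is `NULL`).
#' @param out_dir Optional output directory; when set, stage tables and
#'   the report are written there.
#' @param min_coverage,max_coverage_quantile QC thresholds
#'   ([filter_sites()]).
#' @param dm_method Per-site DM test ([call_dm()]).
#' @param q_threshold Significance threshold for DM and DE (adjusted p).
#' @param delta_threshold Methylation-difference threshold.
#' @param p_mode "adjusted" or "raw" significance for DM sites.
#' @param n_perm Permutations for every overlap null and the MANOVA.
#' @param p_convention Empirical-p convention ([permutation_null()]).
#' @param seed Master seed; stage seeds are derived from it.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            out_dir = NULL,
                            min_coverage = 10,
                            max_coverage_quantile = 0.999,
                            dm_method = "fisher_pooled",
                            q_threshold = 0.05, delta_threshold = 0.20,
                            p_mode = "adjusted",
                            n_perm = 10000L, p_convention = "paper",
                            seed = 1L) {
  cfg <- list(sim = sim, input_dir = input_dir, out_dir = out_dir,
              min_coverage = min_coverage,
              max_coverage_quantile = max_coverage_quantile,
              dm_method = dm_method, q_threshold = q_threshold,
              delta_threshold = delta_threshold, p_mode = p_mode,
              n_perm = as.integer(n_perm), p_convention = p_convention,
              seed = as.integer(seed))
  if (is.null(sim) && is.null(input_dir))
    stop("pipeline_config: provide either a sim_config or an input_dir")
  if (!is.null(sim)) validate_sim_config(sim)
  if (!(cfg$q_threshold > 0 && cfg$q_threshold < 1))
    stop("pipeline_config: q_threshold must be in (0, 1)")
  if (!(cfg$delta_threshold >= 0 && cfg$delta_threshold <= 1))
    stop("pipeline_config: delta_threshold must be in [0, 1]")
  if (!(cfg$max_coverage_quantile > 0 && cfg$max_coverage_quantile <= 1))
    stop("pipeline_config: max_coverage_quantile must be in (0, 1]")
  if (cfg$min_coverage < 1) stop("pipeline_config: min_coverage must be >= 1")
  if (cfg$n_perm < 1) stop("pipeline_config: n_perm must be >= 1")
  if (!cfg$p_mode %in% c("adjusted", "raw"))
    stop("pipeline_config: p_mode must be 'adjusted' or 'raw'")
  if (!cfg$p_convention %in% c("paper", "plus_one"))
    stop("pipeline_config: unknown p_convention")
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, expr, log) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full inheritance-analysis pipeline
#'
#' Stages run in order: simulate/load, coverage QC, per-contrast DM,
#' per-layer DE, site annotation and gene collapse, cross-generation and
#' DM/DE overlaps with permutation nulls, three-way inheritance
#' candidates and quadrant integration, MDS ordination with permutation
#' MANOVA, and the report. Deterministic for a fixed configuration
#' (stochastic stages draw from seeds derived from `cfg$seed`).
#'
#' @param cfg A [pipeline_config()].
#' @return A result bundle (list) with all stage outputs, the config and
#'   the report lines.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$sim)) {
    sim <- run_stage("simulate", simulate_study(cfg$sim))
    features <- sim$annotation$features
    meth <- sim$methylation
    expr <- sim$expression
    truth <- sim$truth
  } else {
    sim <- run_stage("load", read_simulation(cfg$input_dir))
    features <- sim$features
    meth <- sim$methylation
    expr <- sim$expression
    truth <- sim$truth
  }

  filtered <- run_stage("qc", lapply(meth, filter_sites,
                                     min_coverage = cfg$min_coverage,
                                     max_coverage_quantile =
                                       cfg$max_coverage_quantile))
  qc_audit <- lapply(filtered, attr, "audit")

  dm <- run_stage("dm", lapply(filtered, call_dm,
                               method = cfg$dm_method,
                               q_threshold = cfg$q_threshold,
                               delta_threshold = cfg$delta_threshold,
                               p_mode = cfg$p_mode))

  de <- run_stage("de", lapply(expr, de_test,
                               q_threshold = cfg$q_threshold))

  index <- run_stage("annotate", build_feature_index(features))
  annotated <- lapply(filtered, function(m)
    annotate_sites(m$sites, index))
  dm_gene_sets <- Map(dm_genes, dm, annotated)

  # universes: genes with >= 1 retained CpG (DM) / tested genes (DE)
  dm_universe <- lapply(annotated, function(a)
    sort(unique(a$primary_gene[!is.na(a$primary_gene)])))
  de_universe <- lapply(de, function(d) sort(unique(d$gene)))

  overlaps <- list()
  candidates <- NULL
  positional <- NULL
  three_way <- NULL
  if (all(c("sperm_F0", "sperm_F1") %in% names(dm))) {
    uni <- intersect(dm_universe$sperm_F0, dm_universe$sperm_F1)
    keep <- function(s) s[s$gene_id %in% uni, , drop = FALSE]
    overlaps$sperm_F0_vs_F1 <- run_stage("overlap", permutation_null(
      gene_overlap(keep(dm_gene_sets$sperm_F0), keep(dm_gene_sets$sperm_F1),
                   uni, concordant_only = TRUE,
                   labels = c("F0_sperm_DM", "F1_sperm_DM")),
      n_perm = cfg$n_perm, seed = cfg$seed + 11L,
      p_convention = cfg$p_convention))
    positional <- positional_overlap(dm$sperm_F0, dm$sperm_F1)
  }
  if (all(c("IEC_F1") %in% names(dm)) && "IEC_F1" %in% names(de)) {
    de_sig <- de$IEC_F1[de$IEC_F1$direction != "ns", , drop = FALSE]
    uni <- intersect(dm_universe$IEC_F1, de_universe$IEC_F1)
    dm_set <- dm_gene_sets$IEC_F1
    overlaps$IEC_F1_dm_vs_de <- run_stage("overlap", dm_de_same_tissue_overlap(
      dm_set[dm_set$gene_id %in% uni, , drop = FALSE],
      de_sig[de_sig$gene %in% uni, , drop = FALSE], uni,
      n_perm = cfg$n_perm, seed = cfg$seed + 12L,
      p_convention = cfg$p_convention))
  }
  if (all(c("sperm_F0", "sperm_F1", "IEC_F1") %in% names(dm))) {
    uni <- Reduce(intersect, dm_universe[c("sperm_F0", "sperm_F1", "IEC_F1")])
    keep <- function(s) s[s$gene_id %in% uni, , drop = FALSE]
    three_way <- run_stage("inherit", three_way_candidates(
      keep(dm_gene_sets$sperm_F0), keep(dm_gene_sets$sperm_F1),
      keep(dm_gene_sets$IEC_F1), uni, n_perm = cfg$n_perm,
      seed = cfg$seed + 13L, p_convention = cfg$p_convention))
    overlaps$three_way <- three_way$overlap
  }
  if (all(c("sperm_F0", "sperm_F1") %in% names(dm)) &&
      "IEC_F1" %in% names(de)) {
    de_sig <- de$IEC_F1[de$IEC_F1$direction != "ns", , drop = FALSE]
    candidates <- run_stage("integrate", integrate_dm_de(
      dm_gene_sets$sperm_F0, dm_gene_sets$sperm_F1, de_sig))
  }

  imprint <- NULL
  if (!is.null(truth$imprint_controls) && "IEC_F1" %in% names(filtered))
    imprint <- imprinting_control_report(filtered$IEC_F1,
                                         truth$imprint_controls)

  ordination <- run_stage("ordinate", {
    res <- list()
    for (layer in names(filtered)) {
      vals <- methylation_values(filtered[[layer]])
      d <- distance_matrix(vals, metric = "euclidean")
      coords <- classical_mds(d, k = 2)
      mv <- permutation_manova(d, filtered[[layer]]$samples$group,
                               n_perm = min(cfg$n_perm, 999L),
                               seed = cfg$seed + 21L)
      res[[paste0("meth_", layer)]] <-
        list(coords = coords, manova = mv,
             samples = filtered[[layer]]$samples)
    }
    for (layer in names(expr)) {
      sf <- normalize_size_factors(expr[[layer]])
      lognorm <- log2(sweep(expr[[layer]]$counts, 2, sf, "/") + 1)
      d <- distance_matrix(lognorm, metric = "euclidean",
                           standardize = FALSE)
      coords <- classical_mds(d, k = 2)
      mv <- permutation_manova(d, expr[[layer]]$samples$group,
                               n_perm = min(cfg$n_perm, 999L),
                               seed = cfg$seed + 22L)
      res[[paste0("expr_", layer)]] <-
        list(coords = coords, manova = mv,
             samples = expr[[layer]]$samples)
    }
    res
  })

  bundle <- list(config = cfg, truth = truth, qc_audit = qc_audit,
                 filtered = filtered, dm = dm, de = de,
                 annotated = annotated, dm_gene_sets = dm_gene_sets,
                 dm_universe = dm_universe, de_universe = de_universe,
                 overlaps = overlaps, positional = positional,
                 three_way = three_way, candidates = candidates,
                 imprint = imprint, ordination = ordination)
  bundle$report <- pipeline_report(bundle)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(bundle, cfg$out_dir)
  bundle
}

#' Select the top-N most differential rows
#'
#' @param tab A [call_dm()] or [de_test()] result.
#' @param n Number of rows (default 50).
#' @return The `n` rows with largest |delta| (DM) or |log2fc| (DE).
#' @export
top_differential <- function(tab, n = 50) {
  score <- if ("delta" %in% names(tab)) abs(tab$delta) else abs(tab$log2fc)
  out <- tab[order(-score), , drop = FALSE]
  utils::head(out, n)
}

#' Render the pipeline report
#'
#' Per-contrast DM/DE counts by direction, annotation category
#' proportions, every overlap in "observed; mean [min, max]; p" form, the
#' candidate quadrant table and the imprinting-control classes.
#'
#' @param bundle A [run_pipeline()] result.
#' @return Character vector of report lines.
#' @export
pipeline_report <- function(bundle) {
  ln <- c("== Intergenerational methylation inheritance report ==", "")
  for (layer in names(bundle$dm)) {
    s <- attr(bundle$dm[[layer]], "summary")
    ln <- c(ln, sprintf(
      "DM %s: %d sites tested (%d hypo-methylated and %d hyper-methylated)",
      layer, s$n_tested, s$n_hypo, s$n_hyper))
  }
  for (layer in names(bundle$de)) {
    s <- attr(bundle$de[[layer]], "summary")
    ln <- c(ln, sprintf(
      "DE %s: %d genes tested, mean coverage %.2fx (%d up, %d down)",
      layer, s$n_tested, s$mean_coverage, s$n_up, s$n_down))
  }
  ln <- c(ln, "")
  for (layer in names(bundle$annotated)) {
    pr <- attr(bundle$annotated[[layer]], "proportions")
    ln <- c(ln, sprintf("Categories %s: %s", layer,
                        paste(sprintf("%s %.3f", names(pr), as.numeric(pr)),
                              collapse = ", ")))
  }
  ln <- c(ln, "")
  for (nm in names(bundle$overlaps))
    ln <- c(ln, format_overlap(bundle$overlaps[[nm]]))
  if (!is.null(bundle$positional))
    ln <- c(ln, sprintf("Positional overlap sperm F0/F1: %d shared sites (%d concordant)",
                        nrow(bundle$positional),
                        sum(bundle$positional$concordant)))
  if (!is.null(bundle$candidates)) {
    qc <- quadrant_counts(bundle$candidates)
    ln <- c(ln, "", sprintf(
      "DM/DE candidates: %d (%d hypo-up, %d hyper-down, %d hypo-down, %d hyper-up)",
      nrow(bundle$candidates), qc[["hypo-up"]], qc[["hyper-down"]],
      qc[["hypo-down"]], qc[["hyper-up"]]))
  }
  if (!is.null(bundle$imprint))
    ln <- c(ln, "", paste("Imprinting controls:",
                          paste(sprintf("%s=%s", bundle$imprint$locus,
                                        bundle$imprint$class),
                                collapse = ", ")))
  for (nm in names(bundle$ordination)) {
    mv <- bundle$ordination[[nm]]$manova
    ln <- c(ln, sprintf("MANOVA %s: pseudo-F = %.3f, P = %.4g", nm,
                        mv$pseudo_f, mv$p))
  }
  ln
}

write_pipeline_outputs <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (layer in names(bundle$dm))
    write_dm_result(bundle$dm[[layer]],
                    file.path(dir, paste0("dm_", layer, ".tsv")))
  for (layer in names(bundle$de))
    utils::write.table(as.data.frame(bundle$de[[layer]]),
                       file.path(dir, paste0("de_", layer, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$candidates))
    utils::write.table(as.data.frame(bundle$candidates),
                       file.path(dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  ovl <- lapply(bundle$overlaps, function(o)
    list(labels = o$labels, observed = o$observed, n_perm = o$n_perm,
         perm_mean = o$perm_mean, perm_min = o$perm_min,
         perm_max = o$perm_max, p = o$p, formatted = format_overlap(o)))
  jsonlite::write_json(ovl, file.path(dir, "overlaps.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(bundle$ordination)) {
    o <- bundle$ordination[[nm]]
    utils::write.table(
      data.frame(o$samples, dim1 = o$coords[, 1], dim2 = o$coords[, 2]),
      file.path(dir, paste0("mds_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (layer in names(bundle$dm))
    utils::write.table(
      top_differential(bundle$dm[[layer]]),
      file.path(dir, paste0("top50_dm_", layer, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(bundle$report, file.path(dir, "report.txt"))
  invisible(dir)
}
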