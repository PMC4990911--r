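# Synthetic-data generator: determinism, geometry, planted effects.

test_that("identical configuration gives byte-identical simulated files", {
  cfg <- small_cfg(seed = 11L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_study(cfg), d1)
  write_simulation(simulate_study(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  sums1 <- unname(tools::md5sum(file.path(d1, f1)))
  sums2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(sums1, sums2)
})

test_that("annotation geometry: genes non-overlapping, promoters strand-aware", {
  cfg <- small_cfg(seed = 3L)
  ann <- simulate_annotation(cfg)
  genes <- ann$features[ann$features$kind == "gene", ]
  expect_equal(nrow(genes), cfg$n_genes)
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
    expect_true(all(g$end <= ann$chrom_lengths[[ch]]))
  }
  # promoter arithmetic from the window definition
  pw <- promoter_interval(10000, "+", c(1000L, 500L))
  expect_equal(pw$start, 9000)
  expect_equal(pw$end, 10500)
  # CpGs within chromosome bounds, unique and sorted
  cpg <- ann$cpg_sites
  expect_true(all(cpg$pos >= 1 & cpg$pos <= cfg$genome_length_per_chrom))
  expect_false(anyDuplicated(cpg[c("chrom", "pos")]) > 0)
  expect_true(sum(ann$features$kind == "CGI") >= 1)
})

test_that("a genome too small for the requested genes raises a sizing error", {
  cfg <- small_cfg(n_genes = 300L, genome_length_per_chrom = 1e5)
  expect_error(simulate_annotation(cfg), "too small to place")
})

test_that("planted group difference matches planted_delta on average", {
  cfg <- small_cfg(seed = 5L, n_genes = 600L, n_cpg_sites = 4000L,
                   genome_length_per_chrom = 8e6,
                   n_planted_inherited = 50L, planted_delta = 0.3)
  ann <- simulate_annotation(cfg)
  sm <- simulate_methylation(cfg, ann, layers = "sperm_F0")
  m <- sm$layers$sperm_F0
  truth <- sm$truth$dm_sites
  expect_gte(nrow(truth), 200)  # >= 200 planted sites averaged
  vals <- methylation_values(m)
  idx <- match(paste(truth$chrom, truth$pos),
               paste(m$sites$chrom, m$sites$pos))
  ctrl <- rowMeans(vals[idx, m$samples$group == "Ctrl"], na.rm = TRUE)
  dss <- rowMeans(vals[idx, m$samples$group == "DSS"], na.rm = TRUE)
  obs <- dss - ctrl
  signed <- ifelse(truth$direction == "hypo", -obs, obs)
  expect_lt(abs(mean(signed) - cfg$planted_delta), 0.03)
  # directions concordant across layers by construction
  expect_true(all(table(truth$gene_id, truth$direction) %in%
                    c(0L, cfg$sites_per_planted_gene)))
})

test_that("null generator plants nothing and zero coupling decouples DE", {
  cfg <- small_cfg(seed = 9L, n_planted_inherited = 0L,
                   n_de_background = 0L)
  sim <- simulate_study(cfg)
  expect_equal(nrow(sim$truth$inherited_genes), 0)
  expect_equal(nrow(sim$truth$dm_sites), 0)
  expect_equal(nrow(sim$truth$de_genes), 0)

  cfg2 <- small_cfg(seed = 9L, coupling_fraction = 0,
                    n_de_background = 20L)
  sim2 <- simulate_study(cfg2)
  expect_length(intersect(sim2$truth$de_genes$gene_id,
                          sim2$truth$inherited_genes$gene_id), 0)
})

test_that("expression coupling doubles the mean and follows hypo->up", {
  cfg <- small_cfg(seed = 13L, coupling_fraction = 1, planted_log2fc = 1,
                   n_de_background = 0L, nb_dispersion = 0.05)
  sim <- simulate_study(cfg)
  de <- sim$truth$de_genes[sim$truth$de_genes$layer == "IEC_F1", ]
  inh <- sim$truth$inherited_genes
  expect_setequal(de$gene_id, inh$gene_id)
  # sign coupling: hypo-methylated -> up-regulated, hyper -> down
  merged <- merge(de, inh, by = "gene_id")
  expect_true(all(merged$sign[merged$direction == "hypo"] == 1))
  expect_true(all(merged$sign[merged$direction == "hyper"] == -1))
  # a log2fc of 1 doubles the expected normalized mean
  e <- sim$expression$IEC_F1
  sf <- normalize_size_factors(e)
  norm <- sweep(e$counts, 2, sf, "/")
  up <- merged$gene_id[merged$sign == 1]
  r <- rowMeans(norm[up, e$samples$group == "DSS", drop = FALSE]) /
    rowMeans(norm[up, e$samples$group == "Ctrl", drop = FALSE])
  expect_lt(abs(median(log2(r)) - 1), 0.4)
})

test_that("complete-methylation control loci read near 1 in every sample", {
  cfg <- small_cfg(seed = 21L)
  sim <- simulate_study(cfg)
  m <- sim$methylation$IEC_F1
  vals <- methylation_values(m)
  imp <- sim$truth$imprint_controls
  comp <- imp[imp$class == "complete", ]
  for (i in seq_len(nrow(comp))) {
    in_locus <- m$sites$chrom == comp$chrom[i] &
      (m$sites$pos - 1) >= comp$start[i] & (m$sites$pos - 1) < comp$end[i]
    expect_true(all(colMeans(vals[in_locus, , drop = FALSE],
                             na.rm = TRUE) > 0.9))
  }
})
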