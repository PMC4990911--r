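# Feature index queries, precedence-based site annotation, gene-level DM
# collapse, and GTF/BED round-trips.

toy_features <- function() {
  data.frame(
    chrom = "chr1",
    start = c(1000, 900, 1100, 1150, 5000),
    end = c(3000, 1200, 1300, 1250, 5200),
    kind = c("gene", "promoter", "CGI", "CTCF", "CTCF"),
    gene_id = c("gA", "gA", NA, NA, NA),
    strand = c("+", "+", "*", "*", "*"),
    tss = c(1001, 1001, NA, NA, NA),
    stringsAsFactors = FALSE)
}

test_that("point queries respect half-open boundaries", {
  idx <- build_feature_index(toy_features())
  # 0-based promoter [900, 1200): 1-based pos 901 included, 1201 excluded
  ann <- annotate_sites(data.frame(chrom = "chr1",
                                   pos = c(901L, 1200L, 1201L)), idx)
  expect_equal(ann$category, c("promoter", "promoter", "CGI"))
  expect_equal(ann$primary_gene, c("gA", "gA", "gA"))
})

test_that("empty index annotates everything intergenic", {
  idx <- build_feature_index(toy_features()[0, ])
  ann <- annotate_sites(data.frame(chrom = "chrX", pos = c(5L, 10L)), idx)
  expect_equal(ann$category, c("intergenic", "intergenic"))
  expect_true(all(is.na(ann$primary_gene)))
})

test_that("precedence: promoter beats CGI and CTCF; gene body is last", {
  idx <- build_feature_index(toy_features())
  ann <- annotate_sites(data.frame(chrom = "chr1",
                                   pos = c(1180L, 1270L, 2500L, 5100L,
                                           4000L)), idx)
  expect_equal(ann$category,
               c("promoter", "CGI", "gene_body", "CTCF", "intergenic"))
  expect_equal(ann$primary_gene, c("gA", "gA", "gA", NA, NA))
})

test_that("unknown chromosomes are flagged and excluded from proportions", {
  idx <- build_feature_index(toy_features())
  ann <- annotate_sites(data.frame(chrom = c("chr1", "chrZ"),
                                   pos = c(2500L, 100L)), idx)
  expect_equal(ann$unknown_chrom, c(FALSE, TRUE))
  pr <- attr(ann, "proportions")
  expect_equal(sum(pr), 1)
  expect_equal(unname(pr[["gene_body"]]), 1)
})

test_that("index queries match the brute-force interval scan", {
  cfg <- small_cfg(seed = 19L)
  ann <- simulate_annotation(cfg)
  idx <- build_feature_index(ann$features)
  set.seed(99)
  q <- data.frame(
    chrom = sample(names(ann$chrom_lengths), 1000, replace = TRUE),
    pos = sample.int(4e6, 1000))
  fast <- annotate_sites(q, idx)
  brute <- methinherit:::annotate_sites_brute(q, ann$features)
  expect_equal(fast$category, brute$category)
  expect_equal(fast$primary_gene, brute$gene_id)
})

test_that("simulated CpG categories equal generator truth exactly", {
  cfg <- small_cfg(seed = 25L)
  ann <- simulate_annotation(cfg)
  idx <- build_feature_index(ann$features)
  res <- annotate_sites(ann$cpg_sites[c("chrom", "pos")], idx)
  expect_equal(res$category, ann$cpg_sites$true_category)
  expect_equal(res$primary_gene, ann$cpg_sites$gene_id)
})

test_that("invalid intervals are rejected", {
  f <- toy_features(); f$end[1] <- f$start[1]
  expect_error(build_feature_index(f), "start < end")
  f2 <- toy_features(); f2$start[1] <- -5
  expect_error(build_feature_index(f2), "start < end|0 <=")
})

test_that("dm_genes collapses by the most significant site", {
  dm <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
                   delta = c(-0.5, -0.3, 0.4, 0.3),
                   p = c(1e-5, 1e-3, 1e-4, 0.5),
                   q = c(1e-4, 1e-2, 1e-3, 0.6),
                   direction = c("hypo", "hypo", "hyper", "ns"),
                   stringsAsFactors = FALSE)
  an <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
                   category = "promoter",
                   primary_gene = c("gA", "gA", "gA", "gB"),
                   stringsAsFactors = FALSE)
  g <- dm_genes(dm, an)
  expect_equal(nrow(g), 1L)         # gB's only site is ns
  expect_equal(g$direction, "hypo") # most significant site wins
  expect_true(g$mixed)              # conflicting directions flagged
  expect_equal(g$n_sites, 3L)
  # no significant sites -> empty set
  dm$direction <- "ns"
  expect_equal(nrow(dm_genes(dm, an)), 0L)
})

test_that("GTF/BED round-trip preserves coordinates through base conversion", {
  cfg <- small_cfg(seed = 27L, n_genes = 50L, n_cpg_sites = 300L,
                   genome_length_per_chrom = 1.5e6)
  ann <- simulate_annotation(cfg)
  d <- withr::local_tempdir()
  write_annotation_tracks(ann, d)
  back <- read_annotation_tracks(
    file.path(d, "genes.gtf"),
    bed_tracks = list(CGI = file.path(d, "cgi.bed"),
                      CTCF = file.path(d, "ctcf.bed")),
    promoter_window = cfg$promoter_window)
  for (kd in c("gene", "promoter", "CGI", "CTCF")) {
    a <- ann$features[ann$features$kind == kd,
                      c("chrom", "start", "end")]
    b <- back[back$kind == kd, c("chrom", "start", "end")]
    a <- a[order(a$chrom, a$start, a$end), ]
    b <- b[order(b$chrom, b$start, b$end), ]
    expect_equal(unname(as.matrix(a)), unname(as.matrix(b)),
                 label = kd)
  }
  genes_a <- ann$features[ann$features$kind == "gene", ]
  genes_b <- back[back$kind == "gene", ]
  expect_setequal(genes_a$gene_id, genes_b$gene_id)
})
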