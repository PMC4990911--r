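# Bismark coverage parsing, coverage filtering, methylation values,
# imprinting-control classification.

test_that("bismark coverage lines parse with counts authoritative", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr1\t100\t100\t75.0\t3\t1",
               "chr1\t200\t200\t0.0\t0\t20",
               "chr2\t50\t50\t100.0\t20\t0"), f)
  calls <- read_bismark_coverage(f)
  expect_equal(calls$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(calls$pos, c(100L, 200L, 50L))
  expect_equal(calls$n_meth, c(3L, 0L, 20L))
  expect_equal(calls$n_unmeth, c(1L, 20L, 0L))
})

test_that("zero-coverage records are dropped and % mismatches warned", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr1\t100\t100\t75.0\t3\t1",
               "chr1\t150\t150\t0.0\t0\t0"), f)
  expect_warning(calls <- read_bismark_coverage(f), "zero-coverage")
  expect_equal(nrow(calls), 1L)

  f2 <- withr::local_tempfile(fileext = ".cov")
  writeLines("chr1\t100\t100\t10.0\t3\t1", f2)  # counts say 75%
  expect_warning(read_bismark_coverage(f2), "disagrees")

  f3 <- withr::local_tempfile(fileext = ".cov")
  writeLines("chr1\tnot_a_number\t100\t75.0\t3\t1", f3)
  expect_error(read_bismark_coverage(f3), "parse error|malformed")
})

test_that("write -> read round-trip is count-exact", {
  cfg <- small_cfg(seed = 2L, n_genes = 100L, n_cpg_sites = 400L,
                   genome_length_per_chrom = 2e6)
  sim <- simulate_study(cfg)
  m <- sim$methylation$sperm_F0
  f <- withr::local_tempfile(fileext = ".cov")
  sid <- m$samples$sample_id[1]
  write_bismark_coverage(m, sid, f)
  back <- read_bismark_coverage(f)
  j <- match(sid, m$samples$sample_id)
  keep <- !is.na(m$meth[, j])
  expect_equal(back$chrom, m$sites$chrom[keep])
  expect_equal(back$pos, m$sites$pos[keep])
  expect_equal(back$n_meth, unname(m$meth[keep, j]))
  expect_equal(back$n_unmeth, unname(m$unmeth[keep, j]))
})

test_that("coverage filter matches a brute-force scan and is idempotent", {
  cfg <- small_cfg(seed = 4L, n_genes = 100L, n_cpg_sites = 600L,
                   genome_length_per_chrom = 2e6)
  m <- simulate_study(cfg)$methylation$IEC_F1
  filt <- filter_sites(m, min_coverage = 10, max_coverage_quantile = 0.999)
  # brute-force predicate scan (iterating the outlier trim as specified)
  cov <- coverage_matrix(m)
  keep <- vapply(seq_len(nrow(cov)), function(i) {
    x <- cov[i, ]
    !any(is.na(x)) && all(x >= 10)
  }, logical(1))
  repeat {
    hi <- apply(cov[keep, , drop = FALSE], 2, quantile, 0.999, names = FALSE)
    over <- keep & vapply(seq_len(nrow(cov)), function(i)
      any(cov[i, ] > hi, na.rm = TRUE), logical(1))
    if (!any(over)) break
    keep <- keep & !over
  }
  expect_equal(nrow(filt$sites), sum(keep))
  expect_equal(filt$sites, m$sites[keep, ], ignore_attr = TRUE)
  # idempotence
  filt2 <- filter_sites(filt, min_coverage = 10,
                        max_coverage_quantile = 0.999)
  expect_equal(filt2$sites, filt$sites)
  expect_equal(filt2$meth, filt$meth)
  # sorted unique site index after filtering
  expect_false(is.unsorted(order(filt$sites$chrom, filt$sites$pos)))
  expect_false(anyDuplicated(filt$sites) > 0)
})

test_that("threshold edges: 9x removed at min 10; identity filter keeps complete cases", {
  meth <- rbind(c(5L, 5L), c(9L, 20L))
  unmeth <- rbind(c(5L, 6L), c(0L, 5L))
  m <- toy_meth_matrix(meth, unmeth)
  filt <- filter_sites(m, min_coverage = 10, max_coverage_quantile = 1)
  expect_equal(nrow(filt$sites), 1L)  # site 2 has a 9x sample
  expect_equal(filt$sites$pos, 100L)
  ident <- filter_sites(m, min_coverage = 1, max_coverage_quantile = 1)
  expect_equal(nrow(ident$sites), 2L)
  expect_error(filter_sites(m, min_coverage = 100),
               "all sites removed")
})

test_that("methylation values are count fractions in [0, 1]", {
  m <- toy_meth_matrix(rbind(c(3L, 0L), c(20L, 10L)),
                       rbind(c(1L, 20L), c(0L, 10L)))
  v <- methylation_values(m)
  expect_equal(unname(v[1, ]), c(0.75, 0))
  expect_equal(unname(v[2, ]), c(1, 0.5))
})

test_that("imprinting-control loci classify by mean methylation", {
  # three loci at chr1: none-like, partial-like, complete-like
  meth <- rbind(c(0L, 1L), c(10L, 10L), c(19L, 20L))
  unmeth <- rbind(c(20L, 19L), c(10L, 10L), c(1L, 0L))
  m <- toy_meth_matrix(meth, unmeth, pos = c(100L, 200L, 300L))
  loci <- data.frame(gene_id = c("L1", "L2", "L3", "L4"),
                     chrom = "chr1",
                     start = c(90, 190, 290, 1000),
                     end = c(110, 210, 310, 1100))
  rep <- imprinting_control_report(m, loci)
  expect_equal(rep$class, c("none", "partial", "complete", "uncovered"))
  # generator-truth check: simulated controls classify correctly
  cfg <- small_cfg(seed = 6L)
  sim <- simulate_study(cfg)
  filt <- filter_sites(sim$methylation$sperm_F1, min_coverage = 5)
  rep2 <- imprinting_control_report(filt, sim$truth$imprint_controls)
  covered <- rep2$class != "uncovered"
  expect_equal(rep2$class[covered],
               sim$truth$imprint_controls$class[covered])
})
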