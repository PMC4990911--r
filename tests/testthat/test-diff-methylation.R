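# Pooled exact test against enumeration oracles, BH adjustment, and the
# |delta| > 0.20 direction rule.

test_that("pooled exact p matches the enumeration oracle on hand cases", {
  # ctrl (9 meth, 1 unmeth) vs exposed (1, 9): 202/184756
  r <- dm_test_site(9L, 1L, 1L, 9L)
  expect_equal(r$delta, -0.8)
  expect_equal(r$p, 202 / 184756, tolerance = 1e-12)
  # ctrl (5,5) vs exposed (8,2)
  r2 <- dm_test_site(5L, 5L, 8L, 2L)
  expect_equal(r2$p, enumerate_fisher_p(5, 5, 8, 2), tolerance = 1e-12)
  # identical pooled tables: null identity
  r3 <- dm_test_site(c(3L, 2L), c(2L, 3L), c(2L, 3L), c(3L, 2L))
  expect_equal(r3$delta, 0)
  expect_equal(r3$p, 1)
})

test_that("pooled exact p agrees with stats::fisher.test on random tables", {
  set.seed(42)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 15) + 1L, 2)
    p_ours <- fisher_pooled_p(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2])
    p_ref <- stats::fisher.test(tab)$p.value
    expect_equal(p_ours, p_ref, tolerance = 1e-9)
  }
})

test_that("delta is monotone in the exposed methylated count", {
  deltas <- vapply(0:20, function(cc)
    dm_test_site(10L, 10L, cc, 20L - cc)$delta, numeric(1))
  expect_true(all(diff(deltas) > 0))
})

test_that("zero coverage in a group skips the site with a reason", {
  r <- dm_test_site(0L, 0L, 5L, 5L)
  expect_null(r)
})

test_that("logistic mode returns a valid replicate-aware p", {
  r <- dm_test_site(c(8L, 9L, 7L), c(2L, 1L, 3L),
                    c(2L, 1L, 3L), c(8L, 9L, 7L), method = "logistic")
  expect_lt(r$p, 0.01)
  expect_equal(r$delta, -0.6, tolerance = 1e-9)
  r_null <- dm_test_site(c(5L, 5L), c(5L, 5L), c(5L, 5L), c(5L, 5L),
                         method = "logistic")
  expect_gt(r_null$p, 0.9)
})

test_that("bh_adjust reproduces the hand-computed step-up", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand-computed: sorted p * m / i, cumulative minimum from the top
  p <- c(0.005, 0.009, 0.05, 0.2, 0.9)
  expect_equal(bh_adjust(p), c(0.0225, 0.0225, 0.25 / 3, 0.25, 0.9))
  set.seed(1)
  p2 <- runif(50)
  expect_true(all(bh_adjust(p2) >= p2))
  expect_error(bh_adjust(c(0.5, 1.2)), "must be in")
})

test_that("direction calls follow significance and the 0.20 delta rule", {
  # construct pooled counts with known outcomes: coverage 200 per group
  mk <- function(p_ctrl, p_dss) {
    meth <- rbind(c(round(p_ctrl * 100), round(p_ctrl * 100),
                    round(p_dss * 100), round(p_dss * 100)))
    unmeth <- 100 - meth
    toy_meth_matrix(meth, unmeth)
  }
  strong_hyper <- call_dm(mk(0.30, 0.55), q_threshold = 0.05,
                          delta_threshold = 0.20)
  expect_equal(strong_hyper$direction, "hyper")
  below_delta <- call_dm(mk(0.30, 0.45), q_threshold = 0.05,
                         delta_threshold = 0.20)
  expect_lt(below_delta$q, 0.05)        # significant but small effect
  expect_equal(below_delta$direction, "ns")
  strong_hypo <- call_dm(mk(0.80, 0.30))
  expect_equal(strong_hypo$direction, "hypo")
})

test_that("call_dm summary counts and raw-p mode behave", {
  cfg <- small_cfg(seed = 15L)
  sim <- simulate_study(cfg)
  filt <- filter_sites(sim$methylation$sperm_F0, min_coverage = 10)
  dm <- call_dm(filt)
  s <- attr(dm, "summary")
  expect_equal(s$n_hypo, sum(dm$direction == "hypo"))
  expect_equal(s$n_hyper, sum(dm$direction == "hyper"))
  expect_true(all(dm$q >= dm$p))
  # raw-p mode can only add significant sites
  dm_raw <- call_dm(filt, p_mode = "raw")
  expect_gte(sum(dm_raw$direction != "ns"), sum(dm$direction != "ns"))
  # determinism
  dm2 <- call_dm(filt)
  expect_identical(dm, dm2)
})

test_that("planted DM sites are recovered with few false calls", {
  cfg <- small_cfg(seed = 17L, n_genes = 500L, n_cpg_sites = 2500L,
                   genome_length_per_chrom = 7e6,
                   n_planted_inherited = 20L)
  sim <- simulate_study(cfg)
  filt <- filter_sites(sim$methylation$sperm_F1, min_coverage = 10)
  dm <- call_dm(filt)
  truth_key <- paste(sim$truth$dm_sites$chrom, sim$truth$dm_sites$pos)
  called <- dm[dm$direction != "ns", ]
  called_key <- paste(called$chrom, called$pos)
  tested_truth <- intersect(truth_key, paste(dm$chrom, dm$pos))
  sens <- length(intersect(called_key, tested_truth)) / length(tested_truth)
  expect_gt(sens, 0.7)
  fdr <- 1 - length(intersect(called_key, truth_key)) /
    max(1, length(called_key))
  expect_lt(fdr, 0.2)
  # recovered planted sites carry the planted direction
  hit <- merge(called, sim$truth$dm_sites, by = c("chrom", "pos"))
  expect_true(all(hit$direction.x == hit$direction.y))
})
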