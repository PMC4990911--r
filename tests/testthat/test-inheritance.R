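# Gene-set overlaps, the permutation null, positional overlap, three-way
# candidates, and quadrant integration.

dirset <- function(...) {
  x <- c(...)
  data.frame(gene_id = names(x), direction = unname(x),
             stringsAsFactors = FALSE)
}

test_that("concordant overlap matches the hand-enumerated case", {
  A <- dirset(g1 = "hypo", g2 = "hypo", g3 = "hyper")
  B <- dirset(g2 = "hypo", g3 = "hyper", g4 = "hyper")
  uni <- paste0("g", 1:10)
  ov <- gene_overlap(A, B, uni, concordant_only = TRUE)
  expect_equal(ov$observed, 2L)
  expect_setequal(ov$members$gene_id, c("g2", "g3"))
  expect_equal(unname(ov$direction_counts[c("hypo", "hyper")]), c(1L, 1L))
  # identity and disjoint cases
  self <- gene_overlap(A, A, uni, concordant_only = TRUE)
  expect_equal(self$observed, 3L)
  disj <- gene_overlap(dirset(g1 = "hypo"), dirset(g9 = "hypo"), uni)
  expect_equal(disj$observed, 0L)
  # constrained overlap is a subset of unconstrained
  ov_u <- gene_overlap(A, B, uni, concordant_only = FALSE)
  expect_true(all(ov$members$gene_id %in% ov_u$members$gene_id))
  expect_error(gene_overlap(dirset(zz = "hypo"), B, uni),
               "outside the universe")
})

test_that("permutation mean matches the hypergeometric expectation", {
  obs <- gene_overlap(dirset(g1 = "hypo"), dirset(g1 = "hypo"),
                      paste0("g", 1:20))
  obs$set_sizes <- c(5L, 4L)
  res <- permutation_null(obs, universe_size = 20, set_sizes = c(5L, 4L),
                          n_perm = 10000L, seed = 42L)
  # E[overlap] = 5*4/20 = 1.0; allow 3 Monte-Carlo SE
  expect_lt(abs(res$perm_mean - 1.0), 3 * 0.9 / sqrt(10000))
  expect_true(res$perm_min <= res$perm_mean &&
                res$perm_mean <= res$perm_max)
})

test_that("p conventions: paper ratio can be 0, add-one never is", {
  uni <- paste0("g", 1:30)
  A <- dirset(structure(rep("hypo", 10), names = paste0("g", 1:10)))
  ov <- gene_overlap(A, A, uni)   # observed = 10, far above chance
  p0 <- permutation_null(ov, n_perm = 500L, seed = 1L,
                         p_convention = "paper")
  p1 <- permutation_null(ov, n_perm = 500L, seed = 1L,
                         p_convention = "plus_one")
  expect_equal(p0$p, 0)
  expect_equal(p1$p, 1 / 501)
  # degenerate: sets = universe -> every permuted overlap = |universe|
  full <- gene_overlap(dirset(structure(rep("hypo", 30), names = uni)),
                       dirset(structure(rep("hypo", 30), names = uni)), uni)
  pf <- permutation_null(full, n_perm = 100L, seed = 1L)
  expect_equal(pf$perm_mean, 30)
  expect_equal(pf$p, 1)
  expect_error(permutation_null(ov, universe_size = 5,
                                set_sizes = c(10L, 10L)),
               "exceeds universe")
})

test_that("permutation null is seed-reproducible bit-for-bit", {
  uni <- paste0("g", 1:100)
  A <- dirset(structure(rep("hypo", 20), names = paste0("g", 1:20)))
  B <- dirset(structure(rep("hypo", 30), names = paste0("g", 41:70)))
  ov <- gene_overlap(A, B, uni)
  r1 <- permutation_null(ov, n_perm = 2000L, seed = 7L)
  r2 <- permutation_null(ov, n_perm = 2000L, seed = 7L)
  expect_identical(r1, r2)
  expect_match(format_overlap(r1), "mean number after 2000 permutations")
  expect_equal(lengths(regmatches(format_overlap(r1),
                                  gregexpr("\\[", format_overlap(r1)))),
               1L)  # exactly one [min, max] bracket pair
})

test_that("positional overlap is exact-coordinate and matches brute force", {
  mkdm <- function(pos, dir) data.frame(chrom = "chr1", pos = pos,
                                        direction = dir,
                                        stringsAsFactors = FALSE)
  A <- mkdm(c(100L, 200L, 300L), c("hypo", "hyper", "hypo"))
  B <- mkdm(c(100L, 201L, 300L), c("hypo", "hyper", "hyper"))
  ov <- positional_overlap(A, B)
  expect_equal(ov$pos, c(100L, 300L))   # 201 is offset by 1 bp: no match
  expect_equal(ov$concordant, c(TRUE, FALSE))
  # identical lists share everything
  expect_equal(nrow(positional_overlap(A, A)), 3L)
  # brute-force double loop on random site lists
  set.seed(5)
  A2 <- mkdm(sample.int(2000, 800), sample(c("hypo", "hyper"), 800, TRUE))
  B2 <- mkdm(sample.int(2000, 800), sample(c("hypo", "hyper"), 800, TRUE))
  ov2 <- positional_overlap(A2, B2)
  brute <- 0L
  for (i in seq_len(nrow(A2)))
    brute <- brute + sum(B2$pos == A2$pos[i])
  expect_equal(nrow(ov2), brute)
})

test_that("three-way candidates need all layers and concordant direction", {
  uni <- paste0("g", 1:50)
  f0 <- dirset(g1 = "hypo", g2 = "hyper", g3 = "hypo", g4 = "hypo")
  f1 <- dirset(g1 = "hypo", g2 = "hyper", g3 = "hyper", g5 = "hypo")
  iec <- dirset(g1 = "hypo", g2 = "hypo", g3 = "hyper", g6 = "hypo")
  tw <- three_way_candidates(f0, f1, iec, uni, n_perm = 200L, seed = 3L)
  # g1 concordant everywhere; g2 flips in IEC; g3 flips in F1 sperm
  expect_equal(tw$candidates$gene_id, "g1")
  expect_equal(tw$candidates$direction, "hypo")
  # empty layer -> no candidates, p = 1
  empty <- data.frame(gene_id = character(0), direction = character(0))
  tw0 <- three_way_candidates(f0, f1, empty, uni,
                              n_perm = 100L, seed = 3L)
  expect_equal(nrow(tw0$candidates), 0L)
  expect_equal(tw0$overlap$p, 1)
})

test_that("quadrant integration reproduces the four-class structure", {
  # five hypo-up, four hyper-down, four hypo-down, one hyper-up
  genes <- paste0("g", 1:14)
  meth_dir <- c(rep("hypo", 5), rep("hyper", 4), rep("hypo", 4), "hyper")
  expr_dir <- c(rep("up", 5), rep("down", 4), rep("down", 4), "up")
  f0 <- data.frame(gene_id = genes, direction = meth_dir)
  f1 <- f0
  de <- data.frame(gene_id = genes, direction = expr_dir)
  cand <- integrate_dm_de(f0, f1, de)
  qc <- quadrant_counts(cand)
  expect_equal(unname(qc[c("hypo-up", "hyper-down", "hypo-down",
                           "hyper-up")]),
               c(5L, 4L, 4L, 1L))
  expect_equal(sort(unique(cand$regulation[cand$quadrant %in%
                                             c("hypo-up", "hyper-down")])),
               "negatively regulated")
  expect_equal(sort(unique(cand$regulation[cand$quadrant %in%
                                             c("hypo-down", "hyper-up")])),
               "positively regulated")
  # a gene DM in only one sperm layer is excluded
  f1b <- f1[-1, ]
  cand2 <- integrate_dm_de(f0, f1b, de)
  expect_false("g1" %in% cand2$gene_id)
  # discordant sperm directions are excluded
  f1c <- f1; f1c$direction[2] <- "hyper"
  cand3 <- integrate_dm_de(f0, f1c, de)
  expect_false("g2" %in% cand3$gene_id)
})

test_that("same-tissue DM/DE overlap completes with a null and handles empty DE", {
  uni <- paste0("g", 1:40)
  dm <- dirset(g1 = "hypo", g2 = "hyper", g3 = "hypo")
  de <- data.frame(gene_id = c("g2", "g10"), direction = c("down", "up"),
                   stringsAsFactors = FALSE)
  ov <- dm_de_same_tissue_overlap(dm, de, uni, n_perm = 500L, seed = 2L)
  expect_equal(ov$observed, 1L)
  expect_false(ov$direction_constrained)
  empty_de <- de[0, ]
  ov0 <- dm_de_same_tissue_overlap(dm, empty_de, uni, n_perm = 100L,
                                   seed = 2L)
  expect_equal(ov0$observed, 0L)
  expect_equal(ov0$p, 1)
})
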