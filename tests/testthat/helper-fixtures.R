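# Shared fixtures: small study configurations and hand-built matrices.

small_cfg <- function(seed = 7L, ...) {
  args <- list(n_genes = 300L, n_cpg_sites = 1500L,
               genome_length_per_chrom = 4e6, n_planted_inherited = 10L,
               n_de_background = 30L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# A tiny meth_matrix with explicit counts: `meth` and `unmeth` are
# site x sample matrices.
toy_meth_matrix <- function(meth, unmeth,
                            chrom = rep("chr1", nrow(meth)),
                            pos = seq_len(nrow(meth)) * 100L,
                            group = rep(c("Ctrl", "DSS"),
                                        each = ncol(meth) / 2)) {
  samples <- data.frame(
    sample_id = paste0("s", seq_len(ncol(meth))),
    generation = "F0", tissue = "sperm", group = group,
    stringsAsFactors = FALSE)
  meth_matrix(meth, unmeth, data.frame(chrom = chrom, pos = pos), samples)
}

# Enumeration oracle for the two-sided pooled exact test, written directly
# from binomial coefficients (independent of dhyper and fisher.test).
enumerate_fisher_p <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
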