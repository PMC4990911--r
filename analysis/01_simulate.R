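#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-generation study.
#
# Produces a full on-disk study under results/study/: Bismark coverage
# files for sperm (F0, F1) and IECs (F0, F1), gene-level count matrices
# for IEC expression, GTF/BED annotation tracks, a sample sheet and the
# ground truth (50 planted inherited genes, methylation shift 0.3 at 5
# promoter CpGs each, half of them coupled to expression).

library(methinherit)

cfg <- sim_config(seed = 1L)
print(cfg)

sim <- simulate_study(cfg)
dir <- "results/study"
write_simulation(sim, dir)

cat("\nWrote study to", dir, "\n")
cat("Layers:", paste(names(sim$methylation), collapse = ", "), "|",
    paste(names(sim$expression), collapse = ", "), "\n")
cat("Planted inherited genes:", nrow(sim$truth$inherited_genes),
    sprintf("(%d hypo, %d hyper)",
            sum(sim$truth$inherited_genes$direction == "hypo"),
            sum(sim$truth$inherited_genes$direction == "hyper")), "\n")
cat("Planted DM sites:", nrow(sim$truth$dm_sites), "\n")
cat("Coupled/background DE genes (IEC_F1):",
    sum(sim$truth$de_genes$layer == "IEC_F1"), "\n")
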