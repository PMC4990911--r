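#!/usr/bin/env Rscript
# Stage 6: the inheritance inference itself.
#
# Direction-concordant overlap of sperm DM genes across generations,
# same-tissue DM/DE overlap in F1 IECs, exact-position overlaps, the
# three-way intergenerational candidates (F0 sperm + F1 sperm + F1 IEC),
# each with a 10,000-permutation null, and the DM-DE quadrant
# integration. Ends by checking the candidates against the planted truth.

library(methinherit)

study <- read_simulation("results/study")
dir.create("results/inheritance", showWarnings = FALSE, recursive = TRUE)

read_genes <- function(layer)
  read.table(file.path("results/annotation", paste0(layer, "_dm_genes.tsv")),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
read_dm <- function(layer)
  read.table(file.path("results/dm", paste0(layer, ".tsv")),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
gene_universe <- function(layer) {
  a <- read.table(file.path("results/annotation",
                            paste0(layer, "_sites.tsv")),
                  header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  sort(unique(a$primary_gene[!is.na(a$primary_gene)]))
}

g_f0s <- read_genes("sperm_F0"); g_f1s <- read_genes("sperm_F1")
g_f1i <- read_genes("IEC_F1")
de1 <- read.table("results/de/IEC_F1.tsv", header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
de_sig <- de1[de1$direction != "ns", ]

overlaps <- list()

uni_sperm <- intersect(gene_universe("sperm_F0"), gene_universe("sperm_F1"))
keep <- function(s, u) s[s$gene_id %in% u, , drop = FALSE]
overlaps$sperm_F0_vs_F1 <- permutation_null(
  gene_overlap(keep(g_f0s, uni_sperm), keep(g_f1s, uni_sperm), uni_sperm,
               concordant_only = TRUE,
               labels = c("F0_sperm_DM", "F1_sperm_DM")),
  n_perm = 10000L, seed = 11L)

uni_iec <- intersect(gene_universe("IEC_F1"), sort(unique(de1$gene)))
overlaps$IEC_F1_dm_vs_de <- dm_de_same_tissue_overlap(
  keep(g_f1i, uni_iec), de_sig[de_sig$gene %in% uni_iec, ], uni_iec,
  n_perm = 10000L, seed = 12L)

uni3 <- Reduce(intersect, list(gene_universe("sperm_F0"),
                               gene_universe("sperm_F1"),
                               gene_universe("IEC_F1")))
tw <- three_way_candidates(keep(g_f0s, uni3), keep(g_f1s, uni3),
                           keep(g_f1i, uni3), uni3,
                           n_perm = 10000L, seed = 13L)
overlaps$three_way <- tw$overlap

for (nm in names(overlaps)) cat(format_overlap(overlaps[[nm]]), "\n")

pos <- positional_overlap(read_dm("sperm_F0"), read_dm("sperm_F1"))
cat(sprintf("Exact-position sperm F0/F1 overlap: %d sites (%d concordant)\n",
            nrow(pos), sum(pos$concordant)))

cand <- integrate_dm_de(g_f0s, g_f1s, de_sig)
qc <- quadrant_counts(cand)
cat(sprintf("DM-DE candidates: %d (%s)\n", nrow(cand),
            paste(sprintf("%d %s", qc, names(qc)), collapse = ", ")))

planted <- study$truth$inherited_genes$gene_id
cat(sprintf("Three-way recovery of planted genes: %d/%d\n",
            sum(planted %in% tw$candidates$gene_id), length(planted)))

write.table(cand, "results/inheritance/candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(pos, "results/inheritance/positional_overlap.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  lapply(overlaps, function(o)
    list(labels = o$labels, observed = o$observed, n_perm = o$n_perm,
         perm_mean = o$perm_mean, perm_min = o$perm_min,
         perm_max = o$perm_max, p = o$p, formatted = format_overlap(o))),
  "results/inheritance/overlaps.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/inheritance/\n")
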