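#!/usr/bin/env Rscript
# Stage 5: genomic annotation of retained CpG sites and gene-level DM sets.
#
# Builds the interval index from the GTF/BED tracks on disk, annotates
# every retained site with its category (promoter > CGI > CTCF >
# gene_body > intergenic) and primary gene, and collapses the significant
# DM sites of each layer to gene-level sets with per-gene direction.

library(methinherit)

study <- read_simulation("results/study")
idx <- build_feature_index(study$features)
dir.create("results/annotation", showWarnings = FALSE, recursive = TRUE)

for (layer in names(study$methylation)) {
  filt <- filter_sites(study$methylation[[layer]])
  ann <- annotate_sites(filt$sites, idx)
  pr <- attr(ann, "proportions")
  cat(sprintf("%s categories: %s\n", layer,
              paste(sprintf("%s %.3f", names(pr), as.numeric(pr)),
                    collapse = ", ")))
  write.table(as.data.frame(ann),
              file.path("results/annotation", paste0(layer, "_sites.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  dm <- read.table(file.path("results/dm", paste0(layer, ".tsv")),
                   header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  genes <- dm_genes(dm, ann)
  cat(sprintf("  %d DM genes (%d hypo, %d hyper, %d mixed)\n",
              nrow(genes), sum(genes$direction == "hypo"),
              sum(genes$direction == "hyper"), sum(genes$mixed)))
  write.table(genes,
              file.path("results/annotation", paste0(layer, "_dm_genes.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("Wrote annotated sites and DM gene sets to results/annotation/\n")
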