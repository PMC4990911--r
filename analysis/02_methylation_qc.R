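#!/usr/bin/env Rscript
# Stage 2: coverage QC of the methylation layers.
#
# Re-assembles each tissue-by-generation layer from its Bismark coverage
# files, applies the coverage filter (>= 10x in every sample, iterated
# 99.9th-percentile outlier trim, complete cases), writes the filter
# audit, and checks the imprinting-control loci (expected none / partial
# / complete methylation) as a bisulfite-conversion sanity check.

library(methinherit)

study <- read_simulation("results/study")
dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)

audits <- list()
for (layer in names(study$methylation)) {
  filt <- filter_sites(study$methylation[[layer]])
  audits[[layer]] <- cbind(layer = layer, attr(filt, "audit"))
  cat(sprintf("%s: %d of %d sites retained\n", layer,
              attr(filt, "audit")$n_retained,
              attr(filt, "audit")$n_input))
  if (layer == "IEC_F1") {
    imp <- imprinting_control_report(filt, study$truth$imprint_controls)
    write.table(imp, "results/qc/imprinting_controls.tsv", sep = "\t",
                quote = FALSE, row.names = FALSE)
    cat("Imprinting controls:",
        paste(sprintf("%s=%s", imp$locus, imp$class), collapse = ", "),
        "\n")
  }
}
audit <- do.call(rbind, audits)
write.table(audit, "results/qc/filter_audit.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote results/qc/filter_audit.tsv\n")
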