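# On-disk representation of a simulated study: Bismark coverage files,
# GTF/BED annotation tracks, TSV count matrices, a TSV sample sheet and a
# JSON ground truth.

#' Write a simulated study to disk
#'
#' @param sim A [simulate_study()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation_tracks(sim$annotation, file.path(dir, "annotation"))

  sheets <- list()
  for (layer in names(sim$methylation)) {
    m <- sim$methylation[[layer]]
    ldir <- file.path(dir, "methylation", layer)
    dir.create(ldir, showWarnings = FALSE, recursive = TRUE)
    for (sid in m$samples$sample_id)
      write_bismark_coverage(m, sid, file.path(ldir, paste0(sid, ".cov")))
    sheets[[paste0("meth_", layer)]] <-
      cbind(m$samples, assay = "RRBS", layer = layer)
  }
  for (layer in names(sim$expression)) {
    e <- sim$expression[[layer]]
    edir <- file.path(dir, "expression")
    dir.create(edir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      data.frame(gene_id = rownames(e$counts), e$counts,
                 check.names = FALSE),
      file.path(edir, paste0(layer, "_counts.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    sheets[[paste0("expr_", layer)]] <-
      cbind(e$samples, assay = "RNASeq", layer = layer)
  }
  sheet <- do.call(rbind, c(sheets, list(make.row.names = FALSE)))
  utils::write.table(sheet, file.path(dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  imp <- sim$truth$imprint_controls
  utils::write.table(
    data.frame(imp$chrom, imp$start, imp$end, imp$gene_id),
    file.path(dir, "annotation", "imprint_controls.bed"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a simulated study back from disk
#'
#' Inverse of [write_simulation()] (ground truth and annotation are read
#' from their JSON/GTF/BED representations; methylation layers are
#' re-assembled from the Bismark coverage files).
#'
#' @param dir Directory written by [write_simulation()].
#' @param promoter_window Promoter window used to re-derive promoters
#'   from the GTF.
#' @return List with `features`, `methylation`, `expression`, `truth`,
#'   `sample_sheet`.
#' @export
read_simulation <- function(dir, promoter_window = c(2000L, 500L)) {
  sheet <- utils::read.table(file.path(dir, "sample_sheet.tsv"),
                             sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  features <- read_annotation_tracks(
    file.path(dir, "annotation", "genes.gtf"),
    bed_tracks = Filter(file.exists, list(
      CGI = file.path(dir, "annotation", "cgi.bed"),
      CTCF = file.path(dir, "annotation", "ctcf.bed"))),
    promoter_window = promoter_window)

  meth <- list()
  msheet <- sheet[sheet$assay == "RRBS", ]
  for (layer in unique(msheet$layer)) {
    ss <- msheet[msheet$layer == layer, ]
    calls <- lapply(ss$sample_id, function(sid)
      read_bismark_coverage(file.path(dir, "methylation", layer,
                                      paste0(sid, ".cov"))))
    names(calls) <- ss$sample_id
    meth[[layer]] <- calls_to_matrix(
      calls, ss[c("sample_id", "generation", "tissue", "group")])
  }
  expr <- list()
  esheet <- sheet[sheet$assay == "RNASeq", ]
  for (layer in unique(esheet$layer)) {
    ss <- esheet[esheet$layer == layer, ]
    tab <- utils::read.table(
      file.path(dir, "expression", paste0(layer, "_counts.tsv")),
      sep = "\t", header = TRUE, check.names = FALSE,
      stringsAsFactors = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- tab$gene_id
    expr[[layer]] <- expr_matrix(
      counts[, ss$sample_id, drop = FALSE],
      ss[c("sample_id", "generation", "tissue", "group")])
  }
  truth <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  # empty truth tables come back as bare lists; restore their shape
  empty <- list(
    inherited_genes = data.frame(gene_id = character(0),
                                 direction = character(0)),
    dm_sites = data.frame(chrom = character(0), pos = integer(0),
                          gene_id = character(0), direction = character(0),
                          delta = numeric(0), layers = character(0)),
    imprint_controls = data.frame(gene_id = character(0),
                                  class = character(0),
                                  chrom = character(0), start = numeric(0),
                                  end = numeric(0)),
    de_genes = data.frame(gene_id = character(0), sign = numeric(0),
                          layer = character(0)))
  for (nm in names(empty))
    if (!is.data.frame(truth[[nm]])) truth[[nm]] <- empty[[nm]]
  list(features = features, methylation = meth, expression = expr,
       truth = truth, sample_sheet = sheet)
}
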