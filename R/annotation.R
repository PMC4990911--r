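# Mapping CpG sites to genomic features: interval index, precedence-based
# category assignment, gene-level collapse of DM sites, and GTF/BED I/O.

CATEGORY_PRECEDENCE <- c("promoter", "CGI", "CGI_shore", "CTCF",
                         "enhancer", "gene_body", "intergenic")

#' Build a queryable feature interval index
#'
#' Wraps a feature catalogue (0-based half-open intervals, as produced by
#' [simulate_annotation()] or [read_annotation_tracks()]) in a
#' GenomicRanges index for point queries.
#'
#' @param features Data frame with `chrom`, `start`, `end` (0-based
#'   half-open), `kind`, `gene_id`, `strand`, `tss` (1-based, promoters
#'   and genes).
#' @return A `feature_index` object.
#' @export
build_feature_index <- function(features) {
  stopifnot(all(c("chrom", "start", "end", "kind") %in% names(features)))
  if (any(features$start < 0) || any(features$start >= features$end))
    stop("build_feature_index: intervals must satisfy 0 <= start < end")
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1,
                              end = features$end),  # to 1-based closed
    kind = features$kind,
    gene_id = if ("gene_id" %in% names(features)) features$gene_id
              else NA_character_,
    tss = if ("tss" %in% names(features)) features$tss else NA_real_)
  obj <- list(gr = gr, features = features)
  class(obj) <- "feature_index"
  obj
}

#' Annotate CpG sites with features, a primary gene and a category
#'
#' Each 1-based site position is queried against the index; the site's
#' category is the highest-precedence overlapping feature kind
#' (promoter > CGI > CGI_shore > CTCF > enhancer > gene_body >
#' intergenic). The primary gene is the overlapping promoter's gene
#' (nearest TSS on ties), else the first overlapping gene body. Sites on
#' chromosomes absent from the index are flagged and excluded from the
#' category proportions.
#'
#' @param sites Data frame with `chrom` and 1-based `pos`.
#' @param index A [build_feature_index()] object.
#' @return Data frame (class `annotated_sites`): chrom, pos, category,
#'   primary_gene, unknown_chrom; attribute `"proportions"` holds the
#'   category proportions (summing to 1 over non-flagged sites).
#' @export
annotate_sites <- function(sites, index) {
  stopifnot(inherits(index, "feature_index"))
  known <- if (nrow(index$features) == 0L) rep(TRUE, nrow(sites))
           else sites$chrom %in% unique(index$features$chrom)
  q <- GenomicRanges::GRanges(
    seqnames = sites$chrom[known],
    ranges = IRanges::IRanges(start = sites$pos[known],
                              width = 1))
  hits <- GenomicRanges::findOverlaps(q, index$gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  kind <- index$gr$kind[sh]
  kind[kind == "gene"] <- "gene_body"

  n_known <- sum(known)
  category <- rep("intergenic", n_known)
  primary_gene <- rep(NA_character_, n_known)
  if (length(qh) > 0L) {
    rank <- match(kind, CATEGORY_PRECEDENCE)
    ord <- order(qh, rank)
    first <- !duplicated(qh[ord])
    category[qh[ord][first]] <- kind[ord][first]

    # promoter assignment wins; nearest-TSS tie-break
    is_prom <- kind == "promoter"
    if (any(is_prom)) {
      d <- abs(sites$pos[known][qh[is_prom]] - index$gr$tss[sh[is_prom]])
      op <- order(qh[is_prom], d)
      fp <- !duplicated(qh[is_prom][op])
      primary_gene[qh[is_prom][op][fp]] <-
        index$gr$gene_id[sh[is_prom]][op][fp]
    }
    is_body <- kind == "gene_body" & !is.na(index$gr$gene_id[sh])
    if (any(is_body)) {
      ob <- order(qh[is_body], sh[is_body])
      fb <- !duplicated(qh[is_body][ob])
      body_gene <- rep(NA_character_, n_known)
      body_gene[qh[is_body][ob][fb]] <- index$gr$gene_id[sh[is_body]][ob][fb]
      take <- is.na(primary_gene) & !is.na(body_gene)
      primary_gene[take] <- body_gene[take]
    }
  }
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    category = NA_character_,
                    primary_gene = NA_character_,
                    unknown_chrom = !known, stringsAsFactors = FALSE)
  out$category[known] <- category
  out$primary_gene[known] <- primary_gene
  props <- table(factor(category, levels = CATEGORY_PRECEDENCE))
  props <- props / max(1, sum(props))
  attr(out, "proportions") <- props
  class(out) <- c("annotated_sites", "data.frame")
  out
}

#' Collapse significant DM sites to a gene-level DM set
#'
#' The gene set is the union of primary genes of significant sites
#' (direction != "ns"). Each gene's direction is taken from its most
#' significant site (smallest q, then largest |delta|); genes whose sites
#' disagree in direction are flagged "mixed".
#'
#' @param dm A [call_dm()] result.
#' @param annotated An [annotate_sites()] result aligned to the same site
#'   keys (matched on chrom, pos).
#' @return Data frame: gene_id, direction, mixed, n_sites, best_q,
#'   best_delta.
#' @export
dm_genes <- function(dm, annotated) {
  key_dm <- paste(dm$chrom, dm$pos)
  key_an <- paste(annotated$chrom, annotated$pos)
  gene <- annotated$primary_gene[match(key_dm, key_an)]
  sig <- dm$direction != "ns" & !is.na(gene)
  if (!any(sig))
    return(data.frame(gene_id = character(0), direction = character(0),
                      mixed = logical(0), n_sites = integer(0),
                      best_q = numeric(0), best_delta = numeric(0),
                      stringsAsFactors = FALSE))
  d <- data.frame(gene_id = gene[sig], direction = dm$direction[sig],
                  q = dm$q[sig], delta = dm$delta[sig],
                  stringsAsFactors = FALSE)
  d <- d[order(d$gene_id, d$q, -abs(d$delta)), ]
  first <- !duplicated(d$gene_id)
  res <- d[first, c("gene_id", "direction")]
  res$mixed <- vapply(res$gene_id, function(g)
    length(unique(d$direction[d$gene_id == g])) > 1, logical(1))
  res$n_sites <- as.integer(table(d$gene_id)[res$gene_id])
  res$best_q <- d$q[first]
  res$best_delta <- d$delta[first]
  rownames(res) <- NULL
  res
}

# ---- annotation I/O (1-based GTF, 0-based half-open BED) -----------------

#' Write the gene catalogue as GTF and interval tracks as BED
#'
#' @param ann A [simulate_annotation()] result.
#' @param dir Output directory; writes `genes.gtf`, `cgi.bed`, `ctcf.bed`,
#'   `promoters.bed`.
#' @return The directory, invisibly.
#' @export
write_annotation_tracks <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- ann$features
  genes <- f[f$kind == "gene", ]
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = genes$strand,
    type = "gene", gene_id = genes$gene_id)
  rtracklayer::export(gr, file.path(dir, "genes.gtf"), format = "gtf")
  for (kd in c("CGI", "CTCF", "promoter")) {
    fk <- f[f$kind == kd, ]
    if (nrow(fk) == 0L) next
    grb <- GenomicRanges::GRanges(
      seqnames = fk$chrom,
      ranges = IRanges::IRanges(start = fk$start + 1, end = fk$end),
      strand = if (kd == "promoter") fk$strand else "*")
    if (kd == "promoter") grb$name <- fk$gene_id
    fn <- c(CGI = "cgi.bed", CTCF = "ctcf.bed", promoter = "promoters.bed")
    rtracklayer::export(grb, file.path(dir, fn[[kd]]), format = "bed")
  }
  invisible(dir)
}

#' Read a gene GTF and BED tracks into a feature catalogue
#'
#' GTF genes are converted from 1-based inclusive to the internal 0-based
#' half-open convention on read; BED tracks are already 0-based half-open.
#' Promoters are derived from gene TSSs with `promoter_window` unless a
#' promoter BED is supplied.
#'
#' @param gtf Path to a gene GTF.
#' @param bed_tracks Named list of BED paths; names become feature kinds
#'   (e.g. `CGI`, `CTCF`, `enhancer`, `CGI_shore`).
#' @param promoter_window Integer `(upstream, downstream)` pair used to
#'   derive promoters from gene TSSs.
#' @return Feature data frame as consumed by [build_feature_index()].
#' @export
read_annotation_tracks <- function(gtf, bed_tracks = list(),
                                   promoter_window = c(2000L, 500L)) {
  g <- rtracklayer::import(gtf, format = "gtf")
  g <- g[g$type == "gene"]
  strand <- as.character(GenomicRanges::strand(g))
  start0 <- GenomicRanges::start(g) - 1
  end0 <- GenomicRanges::end(g)
  tss <- ifelse(strand == "+", start0 + 1, end0)
  genes <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                      start = start0, end = end0, kind = "gene",
                      gene_id = g$gene_id, strand = strand, tss = tss,
                      stringsAsFactors = FALSE)
  prom <- promoter_interval(tss, strand, promoter_window)
  promoters <- data.frame(chrom = genes$chrom, start = prom$start,
                          end = prom$end, kind = "promoter",
                          gene_id = genes$gene_id, strand = strand,
                          tss = tss, stringsAsFactors = FALSE)
  tracks <- lapply(names(bed_tracks), function(kd) {
    b <- rtracklayer::import(bed_tracks[[kd]], format = "bed")
    data.frame(chrom = as.character(GenomicRanges::seqnames(b)),
               start = GenomicRanges::start(b) - 1,
               end = GenomicRanges::end(b), kind = kd,
               gene_id = NA_character_, strand = "*", tss = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(genes, promoters), tracks))
  out <- out[order(out$chrom, out$start, out$end), ]
  rownames(out) <- NULL
  out
}
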