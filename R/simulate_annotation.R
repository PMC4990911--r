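# Synthetic genome annotation: non-overlapping genes with strand-aware
# promoters, CpG islands, CTCF regions, and a CpG site catalogue with a
# ground-truth category per site.
#
# All internal coordinates are 0-based half-open; CpG site positions are
# 1-based (as in bisulfite coverage files). Conversion happens only at I/O.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generator calls do not
#' disturb the caller's RNG stream.
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Strand-aware promoter interval around a TSS
#'
#' For a 1-based TSS coordinate `t` and window `(up, down)` the promoter is
#' the 0-based half-open interval `[t - up, t + down)` on the plus strand
#' and its mirror `[t - 1 - down, t - 1 + up)` on the minus strand.
#'
#' @param tss 1-based TSS coordinates.
#' @param strand Character vector of "+"/"-".
#' @param window Integer `(upstream, downstream)` pair.
#' @return Data frame with 0-based half-open `start`, `end`.
#' @export
promoter_interval <- function(tss, strand, window) {
  up <- window[1]; down <- window[2]
  start <- ifelse(strand == "+", tss - up, tss - 1 - down)
  end <- ifelse(strand == "+", tss + down, tss - 1 + up)
  data.frame(start = pmax(0, start), end = pmax(0, end))
}

#' Simulate a genome annotation and CpG site catalogue
#'
#' Places non-overlapping genes on each chromosome, derives strand-aware
#' promoters, scatters CpG islands (CGIs) over a subset of promoters plus
#' standalone positions, adds CTCF-binding regions, and then places CpG
#' sites in RRBS-like clusters: promoter clusters (the bulk), gene-body,
#' CGI, CTCF and intergenic sites. Each CpG site carries its true category
#' under the fixed precedence promoter > CGI > CTCF > gene_body >
#' intergenic, computed by a direct interval scan.
#'
#' @param cfg A [sim_config()].
#' @return List with `features` (data frame: chrom, start, end 0-based
#'   half-open, kind, gene_id, strand, tss), `cpg_sites` (data frame:
#'   chrom, pos 1-based, true_category, gene_id), `chrom_lengths` (named),
#'   and `promoter_cpgs` (list of CpG row indices per gene promoter).
#' @export
simulate_annotation <- function(cfg) {
  validate_sim_config(cfg)
  with_rng_seed(cfg$seed, simulate_annotation_impl(cfg))
}

simulate_annotation_impl <- function(cfg) {
  L <- cfg$genome_length_per_chrom
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  chrom_lengths <- stats::setNames(rep(L, cfg$n_chromosomes), chroms)

  n_per <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chromosomes + 1)))
  genes <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    n <- n_per[ci]
    if (n == 0L) return(NULL)
    lens <- round(stats::runif(n, 2000, 10000))
    gaps <- round(stats::runif(n, 4000, 9000))
    starts <- 10000 + cumsum(gaps) + c(0, cumsum(lens))[seq_len(n)]
    ends <- starts + lens
    if (max(ends) + 10000 > L)
      stop(sprintf(paste0("genome_length_per_chrom = %.3g too small to place ",
                          "%d genes on %s (need >= %.3g bp)"),
                   L, n, chroms[ci], max(ends) + 10000))
    data.frame(chrom = chroms[ci], start = starts, end = ends,
               strand = sample(c("+", "-"), n, replace = TRUE))
  }))
  genes$gene_id <- sprintf("gene%05d", seq_len(nrow(genes)))
  genes$tss <- ifelse(genes$strand == "+", genes$start + 1, genes$end)

  prom <- promoter_interval(genes$tss, genes$strand, cfg$promoter_window)
  promoters <- data.frame(chrom = genes$chrom, start = prom$start,
                          end = prom$end, strand = genes$strand,
                          gene_id = genes$gene_id, tss = genes$tss)

  # CGIs: over ~half the promoters, plus standalone islands
  cgi_genes <- sort(sample(nrow(genes), size = floor(nrow(genes) / 2)))
  cgi_len <- round(stats::runif(length(cgi_genes), 300, 1500))
  cgi_start <- pmax(0, genes$tss[cgi_genes] - cgi_len %/% 2)
  n_standalone <- max(3L, cfg$n_genes %/% 50L)
  sa_chrom <- sample(chroms, n_standalone, replace = TRUE)
  sa_start <- round(stats::runif(n_standalone, 0, L - 2000))
  sa_len <- round(stats::runif(n_standalone, 300, 1500))
  cgis <- data.frame(
    chrom = c(genes$chrom[cgi_genes], sa_chrom),
    start = c(cgi_start, sa_start),
    end = c(cgi_start + cgi_len, sa_start + sa_len))

  # CTCF-binding regions scattered genome-wide
  n_ctcf <- max(5L, cfg$n_cpg_sites %/% 80L)
  ct_chrom <- sample(chroms, n_ctcf, replace = TRUE)
  ct_start <- round(stats::runif(n_ctcf, 0, L - 1000))
  ct_len <- round(stats::runif(n_ctcf, 200, 500))
  ctcf <- data.frame(chrom = ct_chrom, start = ct_start,
                     end = ct_start + ct_len)

  features <- rbind(
    data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
               kind = "gene", gene_id = genes$gene_id,
               strand = genes$strand, tss = genes$tss),
    data.frame(chrom = promoters$chrom, start = promoters$start,
               end = promoters$end, kind = "promoter",
               gene_id = promoters$gene_id, strand = promoters$strand,
               tss = promoters$tss),
    data.frame(chrom = cgis$chrom, start = cgis$start, end = cgis$end,
               kind = "CGI", gene_id = NA_character_, strand = "*",
               tss = NA_real_),
    data.frame(chrom = ctcf$chrom, start = ctcf$start, end = ctcf$end,
               kind = "CTCF", gene_id = NA_character_, strand = "*",
               tss = NA_real_))
  features <- features[order(features$chrom, features$start, features$end), ]
  rownames(features) <- NULL

  cpg <- place_cpg_sites(cfg, genes, promoters, cgis, ctcf, chrom_lengths)
  truth <- annotate_sites_brute(cpg, features)
  cpg$true_category <- truth$category
  cpg$gene_id <- truth$gene_id

  prom_idx <- which(cpg$true_category == "promoter" & !is.na(cpg$gene_id))
  promoter_cpgs <- split(prom_idx, cpg$gene_id[prom_idx])

  list(features = features, cpg_sites = cpg, chrom_lengths = chrom_lengths,
       promoter_cpgs = promoter_cpgs)
}

place_cpg_sites <- function(cfg, genes, promoters, cgis, ctcf, chrom_lengths) {
  n <- cfg$n_cpg_sites
  quota <- c(promoter = 0.55, body = 0.20, cgi = 0.10, ctcf = 0.07,
             intergenic = 0.08)
  n_q <- round(n * quota)
  n_q["promoter"] <- n - sum(n_q[-1])

  # promoter clusters of 4-8 CpGs on randomly chosen genes
  pchrom <- character(0); ppos <- numeric(0)
  order_genes <- sample(nrow(genes))
  gi <- 1L
  while (length(ppos) < n_q["promoter"]) {
    g <- order_genes[((gi - 1L) %% nrow(genes)) + 1L]; gi <- gi + 1L
    k <- sample(4:8, 1)
    k <- min(k, n_q["promoter"] - length(ppos))
    lo <- promoters$start[g]; hi <- promoters$end[g]
    pos0 <- unique(round(stats::runif(k, lo, hi - 1)))
    pchrom <- c(pchrom, rep(promoters$chrom[g], length(pos0)))
    ppos <- c(ppos, pos0)
  }

  pick_within <- function(df, k) {
    idx <- sample(nrow(df), k, replace = TRUE)
    pos0 <- round(stats::runif(k, df$start[idx],
                               pmax(df$start[idx], df$end[idx] - 1)))
    data.frame(chrom = df$chrom[idx], pos0 = pos0)
  }
  body <- pick_within(genes, n_q[["body"]])
  in_cgi <- pick_within(cgis, n_q[["cgi"]])
  in_ct <- pick_within(ctcf, n_q[["ctcf"]])
  ig_chrom <- sample(names(chrom_lengths), n_q[["intergenic"]], replace = TRUE)
  ig <- data.frame(chrom = ig_chrom,
                   pos0 = round(stats::runif(n_q[["intergenic"]], 0,
                                             chrom_lengths[ig_chrom] - 1)))

  cpg <- rbind(data.frame(chrom = pchrom, pos0 = ppos),
               body, in_cgi, in_ct, ig)
  cpg$pos <- as.integer(cpg$pos0 + 1)  # 1-based
  cpg <- cpg[!duplicated(cpg[c("chrom", "pos")]), c("chrom", "pos")]
  cpg <- cpg[order(cpg$chrom, cpg$pos), ]
  rownames(cpg) <- NULL
  cpg
}

# --- brute-force interval machinery (generator truth + test oracle) -------

# Membership of 0-based positions in the union of [start, end) intervals.
in_union <- function(pos0, starts, ends) {
  if (length(starts) == 0L) return(rep(FALSE, length(pos0)))
  ord <- order(starts, ends)
  s <- starts[ord]; e <- cummax(ends[ord])
  # merge overlapping/adjacent-sorted intervals
  new_grp <- c(TRUE, s[-1] > e[-length(e)])
  grp <- cumsum(new_grp)
  ms <- s[new_grp]
  me <- as.numeric(tapply(ends[ord], grp, max))
  idx <- findInterval(pos0, ms)
  idx > 0 & pos0 < me[pmax(idx, 1)]
}

# For each position, indices of covering intervals (windowed backward scan;
# assumes bounded interval width). Returns a list.
covering_intervals <- function(pos0, starts, ends) {
  out <- vector("list", length(pos0))
  if (length(starts) == 0L) return(out)
  ord <- order(starts)
  s <- starts[ord]; e <- ends[ord]
  maxw <- max(e - s)
  j <- findInterval(pos0, s)
  for (i in seq_along(pos0)) {
    k <- j[i]; hits <- integer(0)
    while (k >= 1L && s[k] > pos0[i] - maxw - 1) {
      if (e[k] > pos0[i]) hits <- c(hits, ord[k])
      k <- k - 1L
    }
    out[[i]] <- hits
  }
  out
}

# Direct interval-scan annotation used for generator ground truth (and as a
# brute-force oracle in tests). Independent of the GenomicRanges-backed
# index in build_feature_index().
annotate_sites_brute <- function(sites, features) {
  precedence <- c("promoter", "CGI", "CGI_shore", "CTCF", "enhancer", "gene")
  n <- nrow(sites)
  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  pos0 <- sites$pos - 1
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    f <- features[features$chrom == ch, ]
    if (nrow(f) == 0L) next
    cat_ch <- rep("intergenic", length(si))
    for (k in rev(precedence)) {          # low precedence first, overwrite
      fk <- f[f$kind == k, ]
      if (nrow(fk) == 0L) next
      hit <- in_union(pos0[si], fk$start, fk$end)
      cat_ch[hit] <- if (k == "gene") "gene_body" else k
    }
    category[si] <- cat_ch

    # gene assignment: promoter wins (nearest-TSS tie-break), else gene body
    fp <- f[f$kind == "promoter", ]
    fg <- f[f$kind == "gene", ]
    cover_p <- covering_intervals(pos0[si], fp$start, fp$end)
    cover_g <- covering_intervals(pos0[si], fg$start, fg$end)
    for (i in seq_along(si)) {
      cp <- cover_p[[i]]
      if (length(cp) > 0L) {
        d <- abs(sites$pos[si[i]] - fp$tss[cp])
        gene_id[si[i]] <- fp$gene_id[cp[which.min(d)]]
      } else if (length(cover_g[[i]]) > 0L) {
        gene_id[si[i]] <- fg$gene_id[cover_g[[i]][1]]
      }
    }
  }
  data.frame(category = category, gene_id = gene_id,
             stringsAsFactors = FALSE)
}
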