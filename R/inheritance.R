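# Direction-concordant cross-set overlaps with a permutation null,
# exact-position overlaps, three-way intergenerational candidates, and
# methylation-expression quadrant integration.

#' Observed overlap between two gene-level result sets
#'
#' @param setA,setB Data frames with `gene_id` and `direction`
#'   (hypo/hyper or up/down), or plain character vectors.
#' @param universe Character vector of all eligible genes; both sets must
#'   be subsets.
#' @param concordant_only If `TRUE`, only genes with identical direction
#'   in both sets count as overlapping.
#' @param labels Length-2 character vector naming the sets in reports.
#' @return An `overlap_result` list: labels, universe size, set sizes,
#'   observed count, member table with per-set directions, per-direction
#'   counts, and the `direction_constrained` flag. Complete it with
#'   [permutation_null()].
#' @export
gene_overlap <- function(setA, setB, universe, concordant_only = FALSE,
                         labels = c("A", "B")) {
  as_df <- function(s) {
    if (is.data.frame(s)) {
      stopifnot("gene_id" %in% names(s))
      if (!"direction" %in% names(s)) s$direction <- NA_character_
      s[c("gene_id", "direction")]
    } else data.frame(gene_id = as.character(s),
                      direction = NA_character_,
                      stringsAsFactors = FALSE)
  }
  A <- as_df(setA); B <- as_df(setB)
  for (s in list(A, B))
    if (!all(s$gene_id %in% universe))
      stop("gene_overlap: set member(s) outside the universe")
  common <- intersect(A$gene_id, B$gene_id)
  members <- data.frame(
    gene_id = common,
    direction_A = A$direction[match(common, A$gene_id)],
    direction_B = B$direction[match(common, B$gene_id)],
    stringsAsFactors = FALSE)
  members$concordant <- !is.na(members$direction_A) &
    members$direction_A == members$direction_B
  if (concordant_only) members <- members[members$concordant, , drop = FALSE]
  res <- list(labels = labels,
              universe_size = length(unique(universe)),
              set_sizes = c(nrow(A), nrow(B)),
              observed = nrow(members),
              members = members,
              direction_counts = c(table(members$direction_A)),
              direction_constrained = concordant_only)
  class(res) <- "overlap_result"
  res
}

#' Complete an overlap result with a permutation null
#'
#' Each permutation draws sets of the original sizes uniformly without
#' replacement from the universe, independently, and records the size of
#' their common intersection. The empirical p-value follows either the
#' plain convention `#(perm >= observed) / n_perm` (which can equal 0,
#' `p_convention = "paper"`) or the add-one convention
#' `(#(perm >= observed) + 1) / (n_perm + 1)`.
#'
#' @param observed An `overlap_result` from [gene_overlap()] (or a bare
#'   list with `observed` and `set_sizes`).
#' @param universe_size Number of genes in the universe.
#' @param set_sizes Integer vector (length >= 2) of set sizes to draw; by
#'   default taken from `observed`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed; results are reproducible bit-for-bit.
#' @param p_convention "paper" or "plus_one".
#' @return The `overlap_result` completed with `n_perm`, `perm_mean`,
#'   `perm_min`, `perm_max`, `p`, `p_convention`.
#' @export
permutation_null <- function(observed, universe_size = NULL,
                             set_sizes = NULL, n_perm = 10000L, seed = 1L,
                             p_convention = c("paper", "plus_one")) {
  p_convention <- match.arg(p_convention)
  if (is.null(universe_size)) universe_size <- observed$universe_size
  if (is.null(set_sizes)) set_sizes <- observed$set_sizes
  if (any(set_sizes > universe_size))
    stop("permutation_null: set size exceeds universe size")
  k <- length(set_sizes)
  perm <- with_rng_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      tab <- tabulate(unlist(lapply(set_sizes, function(sz)
        sample.int(universe_size, sz))), nbins = universe_size)
      sum(tab == k)
    }, integer(1))
  })
  n_ge <- sum(perm >= observed$observed)
  observed$n_perm <- n_perm
  observed$perm_mean <- mean(perm)
  observed$perm_min <- min(perm)
  observed$perm_max <- max(perm)
  observed$p <- if (p_convention == "paper") n_ge / n_perm
                else (n_ge + 1) / (n_perm + 1)
  observed$p_convention <- p_convention
  observed
}

#' Format an overlap result in "observed; mean [min, max]; p" style
#' @param x An `overlap_result` completed by [permutation_null()].
#' @return A one-line character summary.
#' @export
format_overlap <- function(x) {
  sprintf("%s vs %s: observed = %d; mean number after %d permutations = %s [%s, %s]; Permutation based p-value = %s",
          x$labels[1], x$labels[2], x$observed,
          x$n_perm, format(x$perm_mean, digits = 5),
          format(x$perm_min), format(x$perm_max), format(x$p, digits = 3))
}

#' @export
print.overlap_result <- function(x, ...) {
  if (!is.null(x$n_perm)) cat(format_overlap(x), "\n")
  else cat(sprintf("%s vs %s: observed overlap = %d (no permutation null yet)\n",
                   x$labels[1], x$labels[2], x$observed))
  invisible(x)
}

#' Exact-position overlap between two DM site lists
#'
#' Matches significant sites at identical (chrom, pos) coordinates only;
#' a 1-bp offset is a non-match. Direction concordance is annotated per
#' shared site.
#'
#' @param dmA,dmB [call_dm()] results (or data frames with chrom, pos,
#'   direction); only rows with direction != "ns" are compared.
#' @return Data frame: chrom, pos, direction_A, direction_B, concordant.
#' @export
positional_overlap <- function(dmA, dmB) {
  sigA <- dmA[dmA$direction != "ns", , drop = FALSE]
  sigB <- dmB[dmB$direction != "ns", , drop = FALSE]
  keyA <- paste(sigA$chrom, sigA$pos)
  keyB <- paste(sigB$chrom, sigB$pos)
  common <- intersect(keyA, keyB)
  iA <- match(common, keyA); iB <- match(common, keyB)
  out <- data.frame(chrom = sigA$chrom[iA], pos = sigA$pos[iA],
                    direction_A = sigA$direction[iA],
                    direction_B = sigB$direction[iB],
                    stringsAsFactors = FALSE)
  out$concordant <- out$direction_A == out$direction_B
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Three-way intergenerational inheritance candidates
#'
#' Genes differentially methylated with concordant direction in F0 sperm,
#' F1 sperm and F1 IECs, with a three-set permutation null on the
#' intersection size.
#'
#' @param f0_sperm_dm,f1_sperm_dm,f1_iec_dm Gene-level DM sets
#'   ([dm_genes()] output: `gene_id`, `direction`).
#' @param universe Gene universe for the permutation null.
#' @param n_perm,seed,p_convention Passed to [permutation_null()].
#' @return List with `candidates` (gene_id, direction) and `overlap` (the
#'   completed `overlap_result` for the three-way intersection).
#' @export
three_way_candidates <- function(f0_sperm_dm, f1_sperm_dm, f1_iec_dm,
                                 universe, n_perm = 10000L, seed = 1L,
                                 p_convention = "paper") {
  sets <- list(f0_sperm_dm, f1_sperm_dm, f1_iec_dm)
  for (s in sets)
    if (!all(s$gene_id %in% universe))
      stop("three_way_candidates: set member(s) outside the universe")
  common <- Reduce(intersect, lapply(sets, function(s) s$gene_id))
  dirs <- vapply(common, function(g)
    length(unique(vapply(sets, function(s)
      s$direction[match(g, s$gene_id)], character(1)))) == 1L, logical(1))
  candidates <- data.frame(
    gene_id = common[dirs],
    direction = vapply(common[dirs], function(g)
      sets[[1]]$direction[match(g, sets[[1]]$gene_id)], character(1)),
    stringsAsFactors = FALSE)
  rownames(candidates) <- NULL
  obs <- list(labels = c("F0_sperm_DM & F1_sperm_DM", "F1_IEC_DM"),
              universe_size = length(unique(universe)),
              set_sizes = vapply(sets, nrow, integer(1)),
              observed = nrow(candidates),
              members = candidates,
              direction_constrained = TRUE)
  class(obs) <- "overlap_result"
  ov <- permutation_null(obs, n_perm = n_perm, seed = seed,
                         p_convention = p_convention)
  list(candidates = candidates, overlap = ov)
}

#' Integrate sperm differential methylation with offspring expression
#'
#' Candidate genes are those differentially methylated with the same
#' direction in both F0 and F1 sperm and differentially expressed in F1
#' IECs. Each candidate gets a regulation quadrant from (methylation
#' direction, expression direction): hypo-up and hyper-down are
#' "negatively regulated"; hypo-down and hyper-up are "positively
#' regulated".
#'
#' @param sperm_dm_f0,sperm_dm_f1 Gene-level DM sets (`gene_id`,
#'   `direction` in hypo/hyper).
#' @param iec_de_f1 DE gene set (`gene_id` with `direction` in up/down, as
#'   from [de_test()] after filtering to significant genes, with `gene`
#'   renamed to `gene_id`, or any data frame with those columns).
#' @return Data frame (class `inheritance_candidates`): gene_id,
#'   meth_direction, expr_direction, quadrant, regulation.
#' @export
integrate_dm_de <- function(sperm_dm_f0, sperm_dm_f1, iec_de_f1) {
  concordant <- merge(sperm_dm_f0[c("gene_id", "direction")],
                      sperm_dm_f1[c("gene_id", "direction")],
                      by = "gene_id", suffixes = c("_f0", "_f1"))
  concordant <- concordant[concordant$direction_f0 ==
                             concordant$direction_f1, , drop = FALSE]
  de <- iec_de_f1
  if ("gene" %in% names(de) && !"gene_id" %in% names(de))
    names(de)[names(de) == "gene"] <- "gene_id"
  de <- de[de$direction %in% c("up", "down"), c("gene_id", "direction")]
  cand <- merge(concordant[c("gene_id", "direction_f0")], de,
                by = "gene_id")
  names(cand) <- c("gene_id", "meth_direction", "expr_direction")
  cand$quadrant <- paste(cand$meth_direction, cand$expr_direction,
                         sep = "-")
  cand$regulation <- ifelse(cand$quadrant %in% c("hypo-up", "hyper-down"),
                            "negatively regulated", "positively regulated")
  cand <- cand[order(cand$quadrant, cand$gene_id), ]
  rownames(cand) <- NULL
  class(cand) <- c("inheritance_candidates", "data.frame")
  cand
}

#' Quadrant counts of an integration result
#' @param cand An [integrate_dm_de()] result.
#' @return Named integer vector over the four quadrants.
#' @export
quadrant_counts <- function(cand) {
  lv <- c("hypo-up", "hyper-down", "hypo-down", "hyper-up")
  c(table(factor(cand$quadrant, levels = lv)))
}

#' Same-tissue DM/DE overlap with permutation null
#'
#' Overlap of differentially methylated and differentially expressed
#' genes within one tissue/generation (direction-unconstrained by
#' default), completed with the permutation null.
#'
#' @param iec_dm_f1 Gene-level DM set (`gene_id`, `direction`).
#' @param iec_de_f1 DE gene set (see [integrate_dm_de()]).
#' @param universe Gene universe.
#' @param n_perm,seed,p_convention Passed to [permutation_null()].
#' @param concordant_only Constrain to identical directions (default
#'   `FALSE`).
#' @return A completed `overlap_result`.
#' @export
dm_de_same_tissue_overlap <- function(iec_dm_f1, iec_de_f1, universe,
                                      n_perm = 10000L, seed = 1L,
                                      p_convention = "paper",
                                      concordant_only = FALSE) {
  de <- iec_de_f1
  if ("gene" %in% names(de) && !"gene_id" %in% names(de))
    names(de)[names(de) == "gene"] <- "gene_id"
  de <- de[de$direction %in% c("up", "down"), , drop = FALSE]
  ov <- gene_overlap(iec_dm_f1, de, universe,
                     concordant_only = concordant_only,
                     labels = c("F1_IEC_DM", "F1_IEC_DE"))
  permutation_null(ov, n_perm = n_perm, seed = seed,
                   p_convention = p_convention)
}
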