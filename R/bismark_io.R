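# Bismark coverage file I/O (chrom, start, end, %methylation,
# count methylated, count unmethylated; 1-based inclusive positions),
# plus assembly of per-sample call lists into a meth_matrix.

#' Read a Bismark coverage file
#'
#' Parses the six-column tab-separated coverage dialect. Counts are
#' authoritative; the percent-methylation column is cross-checked against
#' `n_meth / (n_meth + n_unmeth) * 100` and a warning is raised where it
#' disagrees by more than 0.5. Zero-coverage records are dropped with a
#' warning.
#'
#' @param path File path.
#' @return Data frame with `chrom`, 1-based `pos`, `n_meth`, `n_unmeth`.
#' @export
read_bismark_coverage <- function(path) {
  if (!file.exists(path)) stop("read_bismark_coverage: no such file: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = c("character", "integer", "integer",
                                     "numeric", "integer", "integer"),
                      col.names = c("chrom", "start", "end", "pct",
                                    "n_meth", "n_unmeth"),
                      quote = "", comment.char = ""),
    error = function(e)
      stop("read_bismark_coverage: parse error in ", path, ": ",
           conditionMessage(e)))
  bad <- which(is.na(df$start) | is.na(df$n_meth) | is.na(df$n_unmeth) |
                 df$n_meth < 0 | df$n_unmeth < 0)
  if (length(bad) > 0L)
    stop(sprintf("read_bismark_coverage: malformed line %d in %s",
                 bad[1], path))
  cov <- df$n_meth + df$n_unmeth
  zero <- cov == 0
  if (any(zero)) {
    warning(sprintf("%s: dropped %d zero-coverage record(s)",
                    basename(path), sum(zero)))
    df <- df[!zero, , drop = FALSE]
    cov <- cov[!zero]
  }
  mism <- abs(df$pct - df$n_meth / cov * 100) > 0.5
  if (any(mism))
    warning(sprintf(paste0("%s: %%methylation disagrees with counts at %d ",
                           "record(s); counts kept"),
                    basename(path), sum(mism)))
  data.frame(chrom = df$chrom, pos = df$start, n_meth = df$n_meth,
             n_unmeth = df$n_unmeth, stringsAsFactors = FALSE)
}

#' Write one sample of a meth_matrix as a Bismark coverage file
#'
#' @param m A [meth_matrix()].
#' @param sample_id Sample to write.
#' @param path Output path.
#' @export
write_bismark_coverage <- function(m, sample_id, path) {
  stopifnot(inherits(m, "meth_matrix"), sample_id %in% m$samples$sample_id)
  j <- match(sample_id, m$samples$sample_id)
  keep <- !is.na(m$meth[, j]) & (m$meth[, j] + m$unmeth[, j]) > 0
  nm <- m$meth[keep, j]; nu <- m$unmeth[keep, j]
  df <- data.frame(chrom = m$sites$chrom[keep], start = m$sites$pos[keep],
                   end = m$sites$pos[keep],
                   pct = round(nm / (nm + nu) * 100, 6),
                   n_meth = nm, n_unmeth = nu)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble per-sample methylation calls into a meth_matrix
#'
#' Takes the union of sites across samples; sites missing from a sample
#' are `NA` (complete-case handling happens in [filter_sites()]).
#'
#' @param calls Named list of per-sample call data frames as returned by
#'   [read_bismark_coverage()]; names are sample ids.
#' @param samples Sample sheet data frame (`sample_id`, `generation`,
#'   `tissue`, `group`), one row per element of `calls`.
#' @return A [meth_matrix()].
#' @export
calls_to_matrix <- function(calls, samples) {
  stopifnot(length(calls) == nrow(samples),
            all(names(calls) == samples$sample_id))
  all_sites <- unique(do.call(rbind,
    lapply(calls, function(d) d[c("chrom", "pos")])))
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), ]
  key <- paste(all_sites$chrom, all_sites$pos)
  n <- nrow(all_sites)
  meth <- matrix(NA_integer_, n, length(calls))
  unmeth <- matrix(NA_integer_, n, length(calls))
  for (j in seq_along(calls)) {
    idx <- match(paste(calls[[j]]$chrom, calls[[j]]$pos), key)
    meth[idx, j] <- calls[[j]]$n_meth
    unmeth[idx, j] <- calls[[j]]$n_unmeth
  }
  meth_matrix(meth, unmeth, all_sites, samples)
}
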