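# Per-CpG differential methylation between an exposed (DSS) and a control
# group: pooled two-sided exact test (or replicate-aware binomial
# regression), BH adjustment, and direction calls under the
# |delta| > 0.20 effect-size rule. "hypo" = lower methylation in the
# exposed group than in controls.

#' Two-sided exact p-value for a pooled 2x2 methylation table
#'
#' Conditional on the margins, sums the hypergeometric probabilities of
#' all tables as or less probable than the observed one (the same
#' two-sided rule as Fisher's exact test).
#'
#' @param a,b Methylated / unmethylated reads, control group (pooled).
#' @param c_,d Methylated / unmethylated reads, exposed group (pooled).
#' @return Two-sided p-value.
#' @export
fisher_pooled_p <- function(a, b, c_, d) {
  m <- a + c_          # total methylated
  n <- b + d           # total unmethylated
  k <- a + b           # control margin
  if (m + n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Test one CpG site for differential methylation
#'
#' `delta` is always the pooled exposed fraction minus the pooled control
#' fraction. With `method = "fisher_pooled"` replicate counts are pooled
#' into one 2x2 table and tested exactly; with `method = "logistic"` a
#' per-site binomial regression of methylated/unmethylated counts on group
#' is fitted and a likelihood-ratio p-value returned (replicate-aware).
#'
#' @param ctrl_meth,ctrl_unmeth Integer vectors of per-replicate counts,
#'   control group.
#' @param exp_meth,exp_unmeth Same for the exposed group.
#' @param method "fisher_pooled" (default) or "logistic".
#' @return List with `delta` and `p`, or `NULL` (with attribute "reason")
#'   when a group has zero total coverage.
#' @export
dm_test_site <- function(ctrl_meth, ctrl_unmeth, exp_meth, exp_unmeth,
                         method = c("fisher_pooled", "logistic")) {
  method <- match.arg(method)
  a <- sum(ctrl_meth); b <- sum(ctrl_unmeth)
  cc <- sum(exp_meth); d <- sum(exp_unmeth)
  if (a + b == 0 || cc + d == 0) return(NULL)  # skipped: a group has
                                               # zero total coverage
  delta <- cc / (cc + d) - a / (a + b)
  if (method == "fisher_pooled") {
    p <- fisher_pooled_p(a, b, cc, d)
  } else {
    meth <- c(ctrl_meth, exp_meth)
    unmeth <- c(ctrl_unmeth, exp_unmeth)
    grp <- factor(c(rep("Ctrl", length(ctrl_meth)),
                    rep("DSS", length(exp_meth))), levels = c("Ctrl", "DSS"))
    fit1 <- stats::glm(cbind(meth, unmeth) ~ grp, family = stats::binomial())
    fit0 <- stats::glm(cbind(meth, unmeth) ~ 1, family = stats::binomial())
    p <- stats::pchisq(fit0$deviance - fit1$deviance, df = 1,
                       lower.tail = FALSE)
  }
  list(delta = delta, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; order-preserving, with `q >= p` pointwise.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("bh_adjust: p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially methylated CpG sites for one contrast
#'
#' Tests every retained site of one tissue-by-generation layer between two
#' groups, adjusts across all tested sites with Benjamini-Hochberg, and
#' classifies direction: a site is "hyper" when significant with
#' `delta > delta_threshold`, "hypo" when significant with
#' `delta < -delta_threshold`, otherwise "ns". Significance uses adjusted
#' p-values by default (`p_mode = "adjusted"`); `p_mode = "raw"` applies
#' the threshold to unadjusted p-values instead.
#'
#' @param m A filtered [meth_matrix()].
#' @param contrast List with `tissue`, `generation`, and `groups` (length-2
#'   character, control first). Defaults select all samples, requiring the
#'   matrix to hold exactly one layer.
#' @param method Per-site test, see [dm_test_site()].
#' @param q_threshold Significance threshold (default 0.05).
#' @param delta_threshold Methylation-difference threshold (default 0.20).
#' @param p_mode "adjusted" (default) or "raw".
#' @return Data frame (class `dm_result`) with chrom, pos, delta, p, q,
#'   direction; attribute `"summary"` holds n_tested, n_hypo, n_hyper.
#' @export
call_dm <- function(m, contrast = NULL,
                    method = c("fisher_pooled", "logistic"),
                    q_threshold = 0.05, delta_threshold = 0.20,
                    p_mode = c("adjusted", "raw")) {
  method <- match.arg(method)
  p_mode <- match.arg(p_mode)
  stopifnot(inherits(m, "meth_matrix"))
  s <- m$samples
  sel <- rep(TRUE, nrow(s))
  groups <- c("Ctrl", "DSS")
  if (!is.null(contrast)) {
    if (!is.null(contrast$tissue)) sel <- sel & s$tissue == contrast$tissue
    if (!is.null(contrast$generation))
      sel <- sel & s$generation == contrast$generation
    if (!is.null(contrast$groups)) groups <- contrast$groups
  }
  ctrl_j <- which(sel & s$group == groups[1])
  exp_j <- which(sel & s$group == groups[2])
  if (length(ctrl_j) == 0L || length(exp_j) == 0L)
    stop("call_dm: contrast must select samples in both groups")

  a <- rowSums(m$meth[, ctrl_j, drop = FALSE])
  b <- rowSums(m$unmeth[, ctrl_j, drop = FALSE])
  cc <- rowSums(m$meth[, exp_j, drop = FALSE])
  d <- rowSums(m$unmeth[, exp_j, drop = FALSE])
  testable <- (a + b) > 0 & (cc + d) > 0
  delta <- rep(NA_real_, nrow(m$sites))
  p <- rep(NA_real_, nrow(m$sites))
  delta[testable] <- cc[testable] / (cc + d)[testable] -
    a[testable] / (a + b)[testable]
  if (method == "fisher_pooled") {
    idx <- which(testable)
    p[idx] <- vapply(idx, function(i) fisher_pooled_p(a[i], b[i], cc[i], d[i]),
                     numeric(1))
  } else {
    for (i in which(testable)) {
      r <- dm_test_site(m$meth[i, ctrl_j], m$unmeth[i, ctrl_j],
                        m$meth[i, exp_j], m$unmeth[i, exp_j],
                        method = "logistic")
      p[i] <- r$p
    }
  }
  res <- data.frame(chrom = m$sites$chrom, pos = m$sites$pos,
                    delta = delta, p = p, q = NA_real_,
                    direction = "ns", stringsAsFactors = FALSE)
  res <- res[testable, , drop = FALSE]
  # stable BH ranking: ties resolved by (p, chrom, pos)
  res <- res[order(res$p, res$chrom, res$pos), ]
  res$q <- bh_adjust(res$p)
  sig <- if (p_mode == "adjusted") res$q < q_threshold else res$p < q_threshold
  res$direction[sig & res$delta > delta_threshold] <- "hyper"
  res$direction[sig & res$delta < -delta_threshold] <- "hypo"
  res <- res[order(res$chrom, res$pos), ]
  rownames(res) <- NULL
  attr(res, "summary") <- data.frame(
    n_tested = nrow(res),
    n_skipped = sum(!testable),
    n_hypo = sum(res$direction == "hypo"),
    n_hyper = sum(res$direction == "hyper"))
  class(res) <- c("dm_result", "data.frame")
  res
}

#' @export
print.dm_result <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("dm_result: %d sites tested, %d hypo- and %d hyper-methylated\n",
              s$n_tested, s$n_hypo, s$n_hyper))
  NextMethod()
}

#' Write a DM result table as TSV (with a JSON summary sidecar)
#' @param res A [call_dm()] result.
#' @param path Output TSV path; `<path>.summary.json` is written alongside.
#' @export
write_dm_result <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(as.list(attr(res, "summary")),
                       paste0(path, ".summary.json"), auto_unbox = TRUE)
  invisible(path)
}
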