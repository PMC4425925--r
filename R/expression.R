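#' Is a locus expressed?
#'
#' A locus counts as expressed when its FPKM exceeds the cutoff in at
#' least one sample (strictly greater; the default cutoff of 1 means
#' FPKM = 1.0 everywhere is *not* expressed).
#'
#' @param row numeric FPKM vector across samples.
#' @param cutoff FPKM threshold (default 1).
#' @return logical.
#' @export
isExpressed <- function(row, cutoff = 1) {
  if (!length(row)) stop("empty FPKM row")
  if (any(row < 0)) stop("FPKM values must be non-negative")
  max(row) > cutoff
}

#' Tissue specificity of an expression row
#'
#' Maximum fractional expression in one sample relative to the sum over
#' all samples: 1 for fully specific expression, 1/n for perfectly
#' uniform expression over n samples.
#'
#' @param row numeric FPKM vector.
#' @return fraction in \[1/n, 1\].
#' @export
tissueSpecificity <- function(row) {
  if (any(row < 0)) stop("FPKM values must be non-negative")
  s <- sum(row)
  if (s <= 0) stop("tissue specificity undefined for an all-zero row")
  max(row) / s
}

## Paired Wilcoxon signed-rank with the all-zero-differences convention
## (p = 1) and exact null for small n without ties/zeros.
.pairedWilcoxon <- function(x, y, exact_max = 25) {
  d <- x - y
  if (all(d == 0)) return(list(statistic = 0, p = 1))
  nz <- d[d != 0]
  use_exact <- length(nz) <= exact_max && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    wilcox.test(x, y, paired = TRUE, exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Compare relics with their counterparts on level or specificity
#'
#' Two-sided Wilcoxon signed-rank test over relic-counterpart pairs, one
#' summary value per pair: `level` is the mean log2(FPKM + 1) across
#' samples, `specificity` is [tissueSpecificity()]. Tests whether relic
#' expression differs systematically from the still-functional ortholog.
#'
#' @param relic_mat,counterpart_mat FPKM matrices with pairs in matching
#'   rows (relic i vs counterpart i).
#' @param metric `"level"` or `"specificity"`.
#' @return list with `metric`, per-pair `relic_value` /
#'   `counterpart_value`, `statistic`, `p`.
#' @export
compareRelicsToCounterparts <- function(relic_mat, counterpart_mat,
                                        metric = c("level", "specificity")) {
  metric <- match.arg(metric)
  stopifnot(nrow(relic_mat) == nrow(counterpart_mat))
  if (nrow(relic_mat) == 0L) stop("no relic-counterpart pairs")
  f <- if (metric == "level")
    function(r) mean(log2(r + 1)) else tissueSpecificity
  rv <- apply(relic_mat, 1, f)
  cv <- apply(counterpart_mat, 1, f)
  wt <- .pairedWilcoxon(rv, cv)
  list(metric = metric, relic_value = rv, counterpart_value = cv,
       statistic = wt$statistic, p = wt$p)
}

#' Expression-pattern correlation of relics with their counterparts
#'
#' A relic whose expression profile tracks its counterpart's across
#' samples (Pearson R on log2(FPKM+1) above the cutoff at FDR
#' significance) is suspected of mere promoter leakage rather than
#' independent regulation. Pairs whose counterpart shows no expression
#' signature, or with a zero-variance profile, are `not_testable` and
#' skip the test (they remain in the relic set).
#'
#' @param relic_mat,counterpart_mat FPKM matrices, pairs in matching rows
#'   over the same ordered samples.
#' @param r_cutoff Pearson R threshold (default 0.6).
#' @param alpha FDR level (default 0.05).
#' @param fpkm_cutoff expression cutoff used for counterpart testability.
#' @return data.frame: `relic`, `counterpart`, `r`, `p` (two-tailed t on
#'   n-2 df), `q` (BH over testable pairs), `verdict` in
#'   `pattern_similar` / `pattern_distinct` / `not_testable`.
#' @export
correlateRelicCounterpart <- function(relic_mat, counterpart_mat,
                                      r_cutoff = 0.6, alpha = 0.05,
                                      fpkm_cutoff = 1) {
  stopifnot(nrow(relic_mat) == nrow(counterpart_mat),
            ncol(relic_mat) == ncol(counterpart_mat))
  n <- ncol(relic_mat)
  res <- data.frame(
    relic = if (!is.null(rownames(relic_mat))) rownames(relic_mat)
            else as.character(seq_len(nrow(relic_mat))),
    counterpart = if (!is.null(rownames(counterpart_mat)))
            rownames(counterpart_mat)
            else as.character(seq_len(nrow(counterpart_mat))),
    r = NA_real_, p = NA_real_, q = NA_real_,
    verdict = "not_testable", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(relic_mat))) {
    x <- log2(relic_mat[i, ] + 1); y <- log2(counterpart_mat[i, ] + 1)
    if (!isTRUE(try(isExpressed(counterpart_mat[i, ], fpkm_cutoff),
                    silent = TRUE))) next
    if (sd(x) == 0 || sd(y) == 0) next
    r <- cor(x, y)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    res$r[i] <- r
    res$p[i] <- 2 * pt(-abs(tt), df = n - 2)
  }
  testable <- !is.na(res$p)
  res$q[testable] <- p.adjust(res$p[testable], method = "BH")
  res$verdict[testable] <- ifelse(
    res$r[testable] > r_cutoff & res$q[testable] < alpha,
    "pattern_similar", "pattern_distinct")
  res
}

#' Fallback differential-expression test across sample pairs
#'
#' Simple replacement for an external DE caller when no q-value table is
#' supplied: for every sample pair, per-locus differences of
#' log2(FPKM+1) are standardized by a pooled (robust) dispersion
#' estimated across loci and referred to the normal; BH across loci
#' within each pair. A locus is flagged DE when any pair reaches
#' q < alpha. Externally computed q-value tables are preferred when
#' available.
#'
#' @param fpkm FPKM matrix (loci x samples, >= 2 samples).
#' @param alpha FDR level for the flag (default 0.05).
#' @return list with `p` and `q` matrices (loci x sample pairs, columns
#'   named `i.vs.j`) and logical `de` per locus.
#' @export
differentialExpressionFallback <- function(fpkm, alpha = 0.05) {
  if (ncol(fpkm) < 2L) stop("at least two samples required")
  L <- log2(fpkm + 1)
  pairs <- utils::combn(ncol(fpkm), 2)
  p <- matrix(NA_real_, nrow(fpkm), ncol(pairs),
              dimnames = list(rownames(fpkm),
                              apply(pairs, 2, paste, collapse = ".vs.")))
  for (k in seq_len(ncol(pairs))) {
    d <- L[, pairs[1, k]] - L[, pairs[2, k]]
    s <- stats::mad(d)
    if (s == 0) s <- sd(d)
    if (is.na(s) || s == 0) { p[, k] <- 1; next }
    z <- d / s
    p[, k] <- 2 * pnorm(-abs(z))
  }
  q <- apply(p, 2, p.adjust, method = "BH")
  if (is.null(dim(q))) q <- matrix(q, ncol = ncol(p), dimnames = dimnames(p))
  list(p = p, q = q, de = apply(q < alpha, 1, any))
}
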