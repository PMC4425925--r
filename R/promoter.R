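#' Extract the putative promoter of a locus
#'
#' The up-to-`length`-bp intergenic region immediately 5' of the locus
#' start, strand-aware, truncated at the nearest upstream annotated gene
#' boundary or the chromosome edge. A zero-length promoter (locus
#' abutting a neighbour) is returned with `length = 0` and should be
#' excluded downstream.
#'
#' @param locus list with `chrom`, `start`, `end` (0-based half-open) and
#'   `strand`.
#' @param annotations annotation data.frame of the species.
#' @param genome named character vector of chromosome sequences.
#' @param length promoter window in bp (default 2000).
#' @return list with `chrom`, `start`, `end`, `strand`, `length` and
#'   `seq` (forward-strand sequence of the interval).
#' @export
extractPromoter <- function(locus, annotations, genome, length = 2000) {
  stopifnot(locus$strand %in% c("+", "-"))
  chrom_len <- nchar(genome[[locus$chrom]])
  ann <- annotations[annotations$chrom == locus$chrom, , drop = FALSE]
  ann <- ann[!(ann$start == locus$start & ann$end == locus$end), , drop = FALSE]
  if (locus$strand == "+") {
    lo <- max(0, locus$start - length)
    up <- ann$end[ann$end <= locus$start]
    if (any(up > lo)) lo <- max(up[up > lo])
    s <- lo; e <- locus$start
  } else {
    hi <- min(chrom_len, locus$end + length)
    dn <- ann$start[ann$start >= locus$end]
    if (any(dn < hi)) hi <- min(dn[dn < hi])
    s <- locus$end; e <- hi
  }
  list(chrom = locus$chrom, start = s, end = e, strand = locus$strand,
       length = e - s,
       seq = if (e > s) substring(genome[[locus$chrom]], s + 1, e) else "")
}

#' Neutral substitution rate for a set of species
#'
#' Sum of branch lengths of the substitutions/site tree pruned to the
#' species present in an alignment column: the substitutions a neutrally
#' evolving site would be expected to accumulate over that subtree.
#'
#' @param stree [SpeciesTree-class] with branch lengths in
#'   substitutions/site.
#' @param present species present (>= 2).
#' @return total tree length of the pruned tree.
#' @export
neutralRate <- function(stree, present) {
  tr <- treeOf(stree)
  if (length(present) < 2L) stop("need >= 2 present species")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  sub <- ape::keep.tip(tr, present)
  sum(sub$edge.length)
}

## Fitch parsimony count for one column: minimum number of substitutions
## on the (pruned) tree explaining the observed leaf states.
.fitchCount <- function(tr, states) {
  n_tip <- length(tr$tip.label)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  count <- 0L
  setOf <- function(node) {
    if (node <= n_tip) return(states[[tr$tip.label[node]]])
    ch <- kids[[as.character(node)]]
    s <- setOf(ch[1])
    for (c2 in ch[-1]) {
      s2 <- setOf(c2)
      inter <- intersect(s, s2)
      if (length(inter)) s <- inter
      else { s <- union(s, s2); count <<- count + 1L }
    }
    s
  }
  setOf(n_tip + 1L)   # root
  count
}

#' Per-column Fitch substitution counts for an alignment
#'
#' @param aln named character vector: equal-length aligned sequences,
#'   names are tree tips.
#' @param stree [SpeciesTree-class].
#' @param min_species columns with fewer ungapped species are
#'   uninformative (`NA`); default 3.
#' @return integer vector of per-column minimal substitution counts (`NA`
#'   where uninformative).
#' @export
fitchColumnCounts <- function(aln, stree, min_species = 3) {
  tr <- treeOf(stree)
  stopifnot(all(names(aln) %in% tr$tip.label))
  w <- unique(nchar(aln))
  if (length(w) != 1L) stop("alignment rows must have equal length")
  mat <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(mat) <- names(aln)
  vapply(seq_len(w), function(j) {
    col <- mat[, j]
    ok <- col %in% c("A", "C", "G", "T")
    if (sum(ok) < min_species) return(NA_integer_)
    sub <- ape::keep.tip(tr, names(col)[ok])
    .fitchCount(sub, as.list(col[ok]))
  }, integer(1))
}

#' Rejected-substitution conservation profile of a promoter alignment
#'
#' Per column, the rejected substitutions RS = neutral rate of the tree
#' pruned to the column's ungapped species minus the observed (Fitch
#' minimal) substitution count. High RS marks purifying constraint; a
#' fully conserved column attains RS equal to the pruned tree length.
#' Columns with fewer than `min_species` ungapped species are excluded
#' from the summary.
#'
#' @param aln named character vector of aligned promoter sequences
#'   (focal species plus counterpart species).
#' @param stree [SpeciesTree-class], branch lengths in
#'   substitutions/site.
#' @param min_species informativeness threshold (default 3).
#' @return list with per-column `rs`, `neutral` and `observed` vectors
#'   (`NA` at uninformative columns) and `mean_rs` over informative
#'   columns.
#' @export
gerpScores <- function(aln, stree, min_species = 3) {
  tr <- treeOf(stree)
  w <- unique(nchar(aln))
  if (length(w) != 1L) stop("alignment rows must have equal length")
  mat <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(mat) <- names(aln)
  rs <- neutral <- obs <- rep(NA_real_, w)
  prune_cache <- new.env(parent = emptyenv())
  for (j in seq_len(w)) {
    col <- mat[, j]
    ok <- col %in% c("A", "C", "G", "T")
    if (sum(ok) < min_species) next
    present <- sort(names(col)[ok])
    key <- paste(present, collapse = "|")
    if (is.null(prune_cache[[key]]))
      prune_cache[[key]] <- ape::keep.tip(tr, present)
    sub <- prune_cache[[key]]
    Nj <- sum(sub$edge.length)
    oj <- .fitchCount(sub, as.list(col[ok]))
    neutral[j] <- Nj; obs[j] <- oj; rs[j] <- Nj - oj
  }
  if (all(is.na(rs))) stop("all columns uninformative")
  list(rs = rs, neutral = neutral, observed = obs,
       mean_rs = mean(rs, na.rm = TRUE))
}

#' Test relic promoters for conservation against the coding background
#'
#' One-sided (greater) Wilcoxon rank-sum test of each relic promoter's
#' per-column RS values against the pooled per-column RS distribution of
#' protein-coding gene promoters in the same species, BH-corrected
#' across relics. A significantly conserved promoter suggests the
#' relic's transcription is residual promoter activity rather than a new
#' function.
#'
#' @param relic_profiles named list of per-column RS vectors (NA columns
#'   dropped), one per relic.
#' @param background_profiles list of per-column RS vectors for
#'   background protein-coding promoters (>= 30 expected).
#' @param alpha FDR level (default 0.05).
#' @return data.frame: `relic`, `mean_rs`, `p`, `q`, `conserved`.
#' @export
testPromoterConservation <- function(relic_profiles, background_profiles,
                                     alpha = 0.05) {
  if (!length(background_profiles)) stop("empty background")
  if (length(background_profiles) < 30)
    warning("background has fewer than 30 gene promoter profiles")
  pool <- unlist(background_profiles, use.names = FALSE)
  pool <- pool[!is.na(pool)]
  res <- data.frame(relic = names(relic_profiles),
                    mean_rs = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(relic_profiles)) {
    x <- relic_profiles[[i]]
    x <- x[!is.na(x)]
    res$mean_rs[i] <- mean(x)
    res$p[i] <- suppressWarnings(
      wilcox.test(x, pool, alternative = "greater", exact = FALSE,
                  correct = TRUE)$p.value)
  }
  res$q <- p.adjust(res$p, method = "BH")
  res$conserved <- res$q < alpha
  res
}
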