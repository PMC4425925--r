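#' Penalty score of a miRNA against a candidate target site
#'
#' Global gapped alignment of the miRNA (5'->3') against the reverse of
#' the site (antiparallel pairing): Watson-Crick pairs are free, G:U
#' wobbles cost `wobble`, other pairs `mismatch`, indels `indel`, and
#' every penalty is doubled within the functionally critical miRNA
#' 5' region (positions `dbl_lo`-`dbl_hi` from the miRNA 5' end), the
#' plant target-recognition convention. 0 is a perfect target.
#'
#' @param mirna miRNA sequence (RNA or DNA alphabet).
#' @param site candidate site sequence.
#' @param mismatch,wobble,indel base penalties (defaults 1, 0.5, 2).
#' @param dbl_lo,dbl_hi doubled-penalty window (defaults 2 and 13).
#' @return total penalty of the best alignment (>= 0).
#' @examples
#' scoreTargetSite("AGGUAG", "CTACCT")  # 0: perfect complement
#' @export
scoreTargetSite <- function(mirna, site, mismatch = 1, wobble = 0.5,
                            indel = 2, dbl_lo = 2, dbl_hi = 13) {
  if (!.isNucleotide(mirna) || !.isNucleotide(site))
    stop("sequences must be nucleotide (IUPAC ACGTUN)")
  cpp_score_target_site(toupper(mirna), toupper(site),
                        mismatch, wobble, indel,
                        as.integer(dbl_lo), as.integer(dbl_hi), 2.0)
}

#' Predict miRNA response elements on a host sequence
#'
#' Scores every window of length `len(miRNA) - 2` to `len(miRNA) + 2` at
#' every offset with [scoreTargetSite()] and reports sites at or below
#' the penalty cutoff. Overlapping candidates for the same miRNA are
#' resolved to the best-scoring site (leftmost on ties).
#'
#' @param host host sequence (>= 20 nt).
#' @param mirnas named character vector of miRNA sequences.
#' @param cutoff maximum penalty (default 4).
#' @param ... penalty parameters passed to [scoreTargetSite()].
#' @return data.frame: `mirna`, `start` (0-based), `end` (half-open),
#'   `score`; zero rows when nothing passes.
#' @export
predictMres <- function(host, mirnas, cutoff = 4, ...) {
  host <- toupper(host)
  n <- nchar(host)
  out <- list()
  for (mid in names(mirnas)) {
    mir <- toupper(mirnas[[mid]])
    L <- nchar(mir)
    cand <- list()
    for (w in (L - 2):(L + 2)) {
      if (w < 1 || w > n) next
      starts <- 0:(n - w)
      for (s in starts) {
        sc <- scoreTargetSite(mir, substring(host, s + 1, s + w), ...)
        if (sc <= cutoff)
          cand[[length(cand) + 1L]] <- c(start = s, end = s + w, score = sc)
      }
    }
    if (!length(cand)) next
    cd <- as.data.frame(do.call(rbind, cand))
    cd <- cd[order(cd$score, cd$start, cd$end - cd$start), , drop = FALSE]
    keep <- logical(nrow(cd))
    for (i in seq_len(nrow(cd))) {
      if (!any(keep & .overlapsHalfOpen(cd$start[i], cd$end[i],
                                        cd$start, cd$end)))
        keep[i] <- TRUE
    }
    cd <- cd[keep, , drop = FALSE]
    cd <- cd[order(cd$start), , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(mirna = mid, cd,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(mirna = character(), start = numeric(),
                      end = numeric(), score = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Should a relic-partner pair be kept, or dropped as homologous?
#'
#' Shared response elements between homologous sequences reflect common
#' descent, not decoy function. A partner is dropped when it belongs to
#' the relic's own orthologous group, or when local DNA alignment of the
#' two sequences reaches `min_identity` over at least `min_length` nt
#' (an out-paralog style relationship).
#'
#' @param relic_group ortholog group id of the relic (or `NA`).
#' @param partner_gene partner gene id.
#' @param relic_seq,partner_seq nucleotide sequences.
#' @param groups ortholog groups ([readOrthologGroups()]).
#' @param min_identity,min_length homology thresholds (defaults 0.6 and
#'   100).
#' @return `TRUE` to keep the pair, `FALSE` to drop it.
#' @export
excludeHomologs <- function(relic_group, partner_gene, relic_seq,
                            partner_seq, groups,
                            min_identity = 0.6, min_length = 100) {
  if (!is.na(relic_group) && relic_group %in% names(groups)) {
    members <- unlist(groups[[relic_group]], use.names = FALSE)
    if (partner_gene %in% members) return(FALSE)
  }
  if (nchar(relic_seq) >= min_length && nchar(partner_seq) >= min_length) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(relic_seq)),
      Biostrings::DNAString(toupper(partner_seq)),
      type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    w <- Biostrings::nchar(pa)
    if (w >= min_length && Biostrings::pid(pa) / 100 >= min_identity)
      return(FALSE)
  }
  TRUE
}

#' Call relics acting as miRNA decoys (ceRNAs)
#'
#' For every (relic, gene) pair sharing a response element for the same
#' miRNA — the relic site anywhere on the relic transcript, the gene
#' site in its 3' UTR — and surviving the homology exclusion, the pair's
#' expression profiles are tested for significantly positive Pearson
#' correlation on log2(FPKM+1) (one-sided, BH across all tested pairs).
#' A decoy call requires R > 0 and q < alpha.
#'
#' @param relic_mres MRE table for relics: data.frame with `host` and
#'   `mirna` columns (e.g. [predictMres()] output per relic, with a
#'   `host` column added).
#' @param utr_mres MRE table for gene 3' UTRs, same shape.
#' @param fpkm FPKM matrix containing both relic and gene rows.
#' @param groups ortholog groups.
#' @param relic_groups named vector mapping relic id -> its ortholog
#'   group id.
#' @param relic_seqs,utr_seqs named sequence vectors for the homology
#'   screen.
#' @param alpha FDR level (default 0.05).
#' @param ... passed to [excludeHomologs()].
#' @return data.frame: `relic`, `mirna`, `group`, `gene`, `r`, `p`, `q`,
#'   `called`; zero rows when no pair shares an MRE.
#' @export
callCerna <- function(relic_mres, utr_mres, fpkm, groups, relic_groups,
                      relic_seqs, utr_seqs, alpha = 0.05, ...) {
  empty <- data.frame(relic = character(), mirna = character(),
                      group = character(), gene = character(),
                      r = numeric(), p = numeric(), q = numeric(),
                      called = logical())
  if (!nrow(relic_mres) || !nrow(utr_mres)) return(empty)
  pairs <- merge(unique(relic_mres[, c("host", "mirna")]),
                 unique(utr_mres[, c("host", "mirna")]),
                 by = "mirna", suffixes = c(".relic", ".gene"))
  if (!nrow(pairs)) return(empty)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    relic <- pairs$host.relic[i]; gene <- pairs$host.gene[i]
    grp <- unname(relic_groups[relic])
    if (!(relic %in% rownames(fpkm)) || !(gene %in% rownames(fpkm))) next
    if (!excludeHomologs(grp, gene, relic_seqs[[relic]], utr_seqs[[gene]],
                         groups, ...)) next
    x <- log2(fpkm[relic, ] + 1); y <- log2(fpkm[gene, ] + 1)
    if (sd(x) == 0 || sd(y) == 0) next   # zero-variance pair: skipped
    r <- cor(x, y)
    n <- length(x)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    rows[[length(rows) + 1L]] <- data.frame(
      relic = relic, mirna = pairs$mirna[i],
      group = ifelse(is.null(grp), NA_character_, grp), gene = gene,
      r = r, p = pt(tt, df = n - 2, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  res <- unique(do.call(rbind, rows))
  res$q <- p.adjust(res$p, method = "BH")
  res$called <- res$r > 0 & res$q < alpha
  rownames(res) <- NULL
  res
}
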