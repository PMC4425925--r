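.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Frameshift-aware local alignment of a protein to a DNA locus
#'
#' Aligns a counterpart protein against genomic DNA with a local dynamic
#' program in which a residue may be matched to a normal codon (3 nt) or,
#' at a frameshift penalty, to a frameshifted codon of 1, 2, 4 or 5 nt
#' (so indels of 1-2 nt in either direction are single lesions); in-frame
#' stop codons inside the alignment are retained at a stop penalty rather
#' than breaking the alignment. Frame changes and retained stops are the
#' two classes of ORF-disrupting site that identify a relic.
#'
#' @param protein amino-acid sequence (single string).
#' @param dna nucleotide sequence (single string).
#' @param gap_open,gap_ext affine gap penalties (defaults 11/1).
#' @param fs_penalty frameshift penalty (default 15).
#' @param stop_penalty penalty for an aligned in-frame stop (default 10).
#' @param submat substitution matrix (default BLOSUM62).
#' @param query name recorded for the query.
#' @return a [RelicAlignment-class]; its `start`/`end` are 0-based offsets
#'   within `dna`.
#' @examples
#' aln <- alignProteinToLocus("MKT", "ATGAAAACC")
#' queryCoverage(aln)  # 1
#' @export
alignProteinToLocus <- function(protein, dna, gap_open = 11, gap_ext = 1,
                                fs_penalty = 15, stop_penalty = 10,
                                submat = NULL, query = "query") {
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYXBZJU*]*$", toupper(protein)))
    stop("protein contains non-IUPAC characters")
  if (!.isNucleotide(dna)) stop("dna contains non-IUPAC characters")
  if (is.null(submat)) submat <- .blosum62()
  res <- cpp_align_protein_dna(toupper(protein), toupper(dna), submat,
                               gap_open, gap_ext, fs_penalty, stop_penalty)
  new("RelicAlignment", query = query, chrom = "", strand = "+",
      start = as.numeric(res$t_start), end = as.numeric(res$t_end),
      score = res$score, coverage = res$coverage, ops = res$ops)
}

#' ORF-disrupting sites of a relic alignment
#'
#' One `premature_stop` per internal aligned stop codon (a stop at the
#' final aligned codon is the gene's own terminator, not a lesion) and one
#' `frameshift` per frame-changing edit operation.
#'
#' @param aln a [RelicAlignment-class].
#' @return data.frame with columns `kind`, `protein_pos` (1-based query
#'   residue), `dna_pos` (0-based offset of the site within the aligned
#'   DNA), sorted by `dna_pos`. Zero rows for an intact match.
#' @export
findDisablers <- function(aln) {
  ops <- alignmentOps(aln)
  consuming <- ops$op %in% c("match", "stop", "frameshift")
  last_idx <- if (any(consuming)) max(which(consuming)) else 0L
  keep <- (ops$op == "frameshift") |
          (ops$op == "stop" & seq_len(nrow(ops)) < last_idx)
  d <- data.frame(
    kind = ifelse(ops$op[keep] == "stop", "premature_stop", "frameshift"),
    protein_pos = ops$qpos[keep],
    dna_pos = ops$tpos[keep], stringsAsFactors = FALSE)
  d[order(d$dna_pos), , drop = FALSE]
}

## Seed hits of protein k-mers in one translated frame. Returns 1-based aa
## positions of exact k-mer matches.
.seedHits <- function(frame_aa, seeds) {
  hits <- integer(0)
  for (s in seeds) {
    m <- gregexpr(s, frame_aa, fixed = TRUE)[[1]]
    if (m[1] != -1L) hits <- c(hits, as.integer(m))
  }
  sort(unique(hits))
}

#' Scan a genome for homologous loci of a counterpart protein
#'
#' Seed-and-extend search: exact protein k-mer hits against the six-frame
#' translation of the genome nominate candidate windows, each refined by
#' [alignProteinToLocus()]. Every retained hit is labelled `genic`
#' (overlapping an annotated gene by >= 1 bp, half-open) or `intergenic`.
#'
#' @param protein counterpart protein sequence.
#' @param genome named character vector of chromosome sequences.
#' @param annotations annotation data.frame ([readAnnotations()]) for the
#'   scanned species.
#' @param k seed k-mer length in residues (default 5).
#' @param min_score,min_coverage thresholds below which a refined
#'   alignment is not reported as a hit (defaults 100 and 0.4, well
#'   above the score of chance local alignments in random sequence).
#' @param query query name recorded on the alignments.
#' @param ... passed to [alignProteinToLocus()].
#' @return list of hits, each a list with `aln` (a
#'   [RelicAlignment-class] whose coordinates are genomic, 0-based
#'   half-open, strand-aware) and `genic` (logical). Empty list when
#'   nothing aligns above threshold.
#' @export
scanGenome <- function(protein, genome, annotations, k = 5,
                       min_score = 100, min_coverage = 0.4,
                       query = "query", ...) {
  protein <- toupper(protein)
  plen <- nchar(protein)
  if (plen < k) return(list())
  seeds <- unique(substring(protein, seq_len(plen - k + 1),
                            seq_len(plen - k + 1) + k - 1))
  pad <- plen * 3 + 60
  hits <- list()
  for (chrom in names(genome)) {
    seq_fwd <- toupper(genome[[chrom]])
    clen <- nchar(seq_fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq_fwd else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_fwd)))
      nt_hits <- integer(0)
      for (f in 0:2) {
        sub <- substring(s, f + 1)
        aa <- suppressWarnings(as.character(Biostrings::translate(
          Biostrings::DNAString(substring(sub, 1, (nchar(sub) %/% 3) * 3)),
          if.fuzzy.codon = "X")))
        ah <- .seedHits(aa, seeds)
        if (length(ah)) nt_hits <- c(nt_hits, f + 3 * (ah - 1))  # 0-based
      }
      if (!length(nt_hits)) next
      nt_hits <- sort(nt_hits)
      grp <- cumsum(c(1, diff(nt_hits) > 3 * plen))
      for (g in unique(grp)) {
        pos <- nt_hits[grp == g]
        w0 <- max(0, min(pos) - pad)
        w1 <- min(clen, max(pos) + k * 3 + pad)
        window <- substring(s, w0 + 1, w1)
        aln <- alignProteinToLocus(protein, window, query = query, ...)
        if (alignmentScore(aln) < min_score ||
            queryCoverage(aln) < min_coverage) next
        # window offsets -> genomic, flipping for the minus strand
        if (strand == "+") {
          gs <- w0 + aln@start; ge <- w0 + aln@end
        } else {
          gs <- clen - w0 - aln@end; ge <- clen - w0 - aln@start
        }
        aln@chrom <- chrom; aln@strand <- strand
        aln@start <- gs; aln@end <- ge
        genic <- any(.overlapsHalfOpen(gs, ge, annotations$start,
                                       annotations$end) &
                     annotations$chrom == chrom)
        hits[[length(hits) + 1L]] <- list(aln = aln, genic = genic)
      }
    }
  }
  hits
}

#' Classify one candidate loss event from its genomic hits
#'
#' Filter precedence mirrors the discovery cascade: any genic hit removes
#' the candidate (likely incomplete annotation rather than true loss);
#' otherwise an intergenic hit that is disabler-free at sufficient query
#' coverage removes it as an intact ORF (likely an unannotated live
#' gene); otherwise an intergenic disabler-harbouring hit makes it
#' relic-retaining, recording the best-scoring such hit as the relic
#' locus; with no hits at all the state is unchanged and the event is
#' routed to synteny validation.
#'
#' @param event one-row events data.frame.
#' @param hits list from [scanGenome()].
#' @param intact_orf_coverage coverage threshold for the intact-ORF call
#'   (default 0.8).
#' @return the event row with updated `state`, relic locus columns and
#'   `n_disablers`.
#' @export
classifyCandidate <- function(event, hits, intact_orf_coverage = 0.8) {
  stopifnot(nrow(event) == 1L)
  if (length(hits) == 0L) return(event)
  if (any(vapply(hits, `[[`, logical(1), "genic"))) {
    event$state <- "genic_hit_removed"
    return(event)
  }
  ndis <- vapply(hits, function(h) nrow(findDisablers(h$aln)), integer(1))
  cov <- vapply(hits, function(h) queryCoverage(h$aln), numeric(1))
  if (any(ndis == 0L & cov >= intact_orf_coverage)) {
    event$state <- "intact_orf_removed"
    return(event)
  }
  harb <- which(ndis > 0L)
  if (length(harb)) {
    sc <- vapply(hits[harb], function(h) alignmentScore(h$aln), numeric(1))
    besth <- hits[[harb[which.max(sc)]]]
    event$state <- "relic_retaining"
    event$relic_chrom <- besth$aln@chrom
    event$relic_start <- besth$aln@start
    event$relic_end <- besth$aln@end
    event$relic_strand <- besth$aln@strand
    event$n_disablers <- nrow(findDisablers(besth$aln))
  }
  event
}
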