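## Anchor pairs relevant to one (source, target) species pair, as a map
## source gene -> target gene. Anchor tables are treated as symmetric.
.anchorMap <- function(anchors, source, target) {
  fwd <- anchors[anchors$species_a == source & anchors$species_b == target, ]
  rev <- anchors[anchors$species_b == source & anchors$species_a == target, ]
  src <- c(fwd$gene_a, rev$gene_b)
  tgt <- c(fwd$gene_b, rev$gene_a)
  setNames(tgt, src)
}

#' Infer the expected locus of a hit-less candidate from synteny
#'
#' For each source species holding a counterpart of the lost gene, the
#' nearest anchored genes upstream and downstream of that counterpart
#' (within a gene window) are projected through their anchor partners
#' into the target genome; the candidate locus is the span between the
#' two partners. Loci proposed by different sources must agree (same
#' chromosome, pairwise overlapping); the reported locus is their
#' intersection.
#'
#' @param event one-row events data.frame (state still `candidate`, no
#'   genomic hits).
#' @param groups ortholog groups ([readOrthologGroups()]).
#' @param anchors anchor table ([readAnchors()]).
#' @param annotations named list of per-species annotation data.frames.
#' @param target target species id (the species that lost the gene).
#' @param sources candidate source species (default: every other species
#'   with annotations and counterparts).
#' @param window how many genes away an anchored flank may be (default 20).
#' @return `NULL`, or a list with `chrom`, `start`, `end` (0-based
#'   half-open, target genome), `sources`, and `flanks` (per-source anchor
#'   gene pairs).
#' @export
inferLocus <- function(event, groups, anchors, annotations, target,
                       sources = NULL, window = 20) {
  grp <- groups[[event$group_id]]
  if (is.null(sources))
    sources <- setdiff(names(annotations), target)
  per_source <- list()
  for (src in sources) {
    cp <- grp[[src]]
    if (is.null(cp) || !length(cp)) next
    ann_s <- annotations[[src]]
    ann_t <- annotations[[target]]
    amap <- .anchorMap(anchors, src, target)
    known <- names(amap) %in% ann_s$gene_id & amap %in% ann_t$gene_id
    if (any(!known) && length(amap))
      warning("anchors referencing unknown genes skipped (", sum(!known), ")")
    amap <- amap[known]
    cp_row <- match(cp[1], ann_s$gene_id)
    if (is.na(cp_row)) next
    chr_genes <- ann_s[ann_s$chrom == ann_s$chrom[cp_row], , drop = FALSE]
    chr_genes <- chr_genes[order(chr_genes$start), , drop = FALSE]
    idx <- match(cp[1], chr_genes$gene_id)
    anchored <- chr_genes$gene_id %in% names(amap)
    up <- which(anchored & seq_len(nrow(chr_genes)) < idx)
    dn <- which(anchored & seq_len(nrow(chr_genes)) > idx)
    up <- up[idx - up <= window]
    dn <- dn[dn - idx <= window]
    if (!length(up) || !length(dn)) next
    gA <- chr_genes$gene_id[max(up)]
    gB <- chr_genes$gene_id[min(dn)]
    tA <- ann_t[match(amap[[gA]], ann_t$gene_id), ]
    tB <- ann_t[match(amap[[gB]], ann_t$gene_id), ]
    if (tA$chrom != tB$chrom) next
    lo <- min(tA$end, tB$end); hi <- max(tA$start, tB$start)
    if (lo >= hi) next
    per_source[[src]] <- list(chrom = tA$chrom, start = lo, end = hi,
                              flank = c(gA, gB))
  }
  if (!length(per_source)) return(NULL)
  chroms <- vapply(per_source, `[[`, "", "chrom")
  if (length(unique(chroms)) > 1L) return(NULL)   # synteny-inconsistent
  s <- max(vapply(per_source, `[[`, 0, "start"))
  e <- min(vapply(per_source, `[[`, 0, "end"))
  if (s >= e) return(NULL)                        # non-overlapping sources
  list(chrom = chroms[[1]], start = s, end = e,
       sources = names(per_source),
       flanks = lapply(per_source, `[[`, "flank"))
}

#' Runs of N in a chromosome sequence (assembly gaps)
#'
#' @param seq chromosome sequence.
#' @param min_n minimum run length called a gap (default 10).
#' @return data.frame with 0-based half-open `start`, `end`.
#' @export
findAssemblyGaps <- function(seq, min_n = 10) {
  m <- gregexpr(sprintf("N{%d,}", min_n), toupper(seq))[[1]]
  if (m[1] == -1L)
    return(data.frame(start = numeric(0), end = numeric(0)))
  data.frame(start = as.numeric(m) - 1,
             end = as.numeric(m) - 1 + attr(m, "match.length"))
}

#' Validate an inferred locus: relic-lacking or synteny-rejected
#'
#' A hit-less candidate is accepted as relic-lacking only when its
#' inferred interval is free of gene annotation and of assembly gaps —
#' otherwise the apparent absence could be an artefact of incomplete
#' sequence or annotation.
#'
#' @param locus list from [inferLocus()].
#' @param annotations annotation data.frame of the target species.
#' @param genome_seq target chromosome sequence (for N-run gap
#'   detection), or `NULL` to skip.
#' @param gaps optional explicit gap data.frame (`start`, `end`, 0-based
#'   half-open, same chromosome).
#' @param gap_min_n minimum N-run length treated as a gap (default 10).
#' @return list with `state` (`relic_lacking` or `synteny_rejected`) and
#'   `reason` (`NA`, `"gene"` or `"gap"`).
#' @export
validateLocus <- function(locus, annotations, genome_seq = NULL,
                          gaps = NULL, gap_min_n = 10) {
  on_chr <- annotations[annotations$chrom == locus$chrom, , drop = FALSE]
  if (any(.overlapsHalfOpen(locus$start, locus$end, on_chr$start, on_chr$end)))
    return(list(state = "synteny_rejected", reason = "gene"))
  allgaps <- if (is.null(gaps))
    data.frame(start = numeric(0), end = numeric(0)) else gaps
  if (!is.null(genome_seq)) {
    nr <- findAssemblyGaps(genome_seq, min_n = gap_min_n)
    allgaps <- rbind(allgaps, nr)
  }
  if (nrow(allgaps) &&
      any(.overlapsHalfOpen(locus$start, locus$end, allgaps$start, allgaps$end)))
    return(list(state = "synteny_rejected", reason = "gap"))
  list(state = "relic_lacking", reason = NA_character_)
}
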