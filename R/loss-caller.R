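## Leaves below each node of a phylo tree, as a list indexed by node id.
.leavesBelow <- function(tr) {
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  below <- vector("list", n_node)
  for (i in seq_len(n_tip)) below[[i]] <- tr$tip.label[i]
  ord <- ape::reorder.phylo(tr, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; chi <- ord$edge[k, 2]
    below[[par]] <- c(below[[par]], below[[chi]])
  }
  below
}

.mrcaNode <- function(tr, tips) {
  if (length(tips) == 1L) return(match(tips, tr$tip.label))
  ape::getMRCA(tr, tips)
}

#' Minimum Dollo loss count and placement for a presence pattern
#'
#' Under the Dollo model the character (the gene) arises exactly once, at
#' the most recent common ancestor of the species where it is present;
#' absences below that origin must be explained by losses. Because a loss
#' silences the entire clade below its branch, the minimal placement is
#' the set of maximal all-absent clades inside the origin subtree, and its
#' size is the minimal loss count. A single loss is the parsimony
#' signature of a unitary gene loss event.
#'
#' @param pattern named logical vector (species id -> present) covering
#'   all tree tips.
#' @param stree a [SpeciesTree-class].
#' @return list with `count` (integer) and `placements`, a list of
#'   character vectors, each the leaf set below one loss branch. The
#'   placements are disjoint and their union is the set of absent species
#'   below the origin.
#' @examples
#' st <- SpeciesTree(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
#' p <- c(A = TRUE, B = FALSE, C = TRUE, D = TRUE)
#' dolloMinLosses(p, st)$count  # 1
#' @export
dolloMinLosses <- function(pattern, stree) {
  tr <- treeOf(stree)
  stopifnot(setequal(names(pattern), tr$tip.label))
  present <- names(pattern)[pattern[names(pattern)]]
  if (length(present) == 0L)
    stop("all-absent pattern: loss count undefined without a single origin")
  if (all(pattern)) return(list(count = 0L, placements = list()))
  below <- .leavesBelow(tr)
  origin <- .mrcaNode(tr, present)
  children <- function(node) tr$edge[tr$edge[, 1] == node, 2]
  placements <- list()
  recurse <- function(node) {
    lv <- below[[node]]
    if (!any(pattern[lv])) {        # maximal all-absent clade -> one loss
      placements[[length(placements) + 1L]] <<- lv
      return(invisible(NULL))
    }
    for (ch in children(node)) recurse(ch)
  }
  for (ch in children(origin)) recurse(ch)
  list(count = length(placements), placements = placements)
}

.emptyEvents <- function() {
  data.frame(group_id = character(), branch = character(),
             state = character(), counterparts = character(),
             relic_chrom = character(), relic_start = numeric(),
             relic_end = numeric(), relic_strand = character(),
             n_disablers = integer(), stringsAsFactors = FALSE)
}

#' Call candidate unitary gene loss events
#'
#' A group yields a candidate event when (a) every outgroup species is
#' present — establishing the gene as long-established, so its absence is
#' loss rather than lineage-specific gain — and (b) the minimal Dollo
#' placement is a single loss branch lying inside the ingroup subtree.
#' All genes of the present species become the orthologous counterparts
#' of the lost gene. Events on internal ingroup branches (losses shared
#' by a clade, e.g. before the divergence of two sister species) are
#' emitted and labelled with the clade's leaf set.
#'
#' @param groups ortholog groups from [readOrthologGroups()].
#' @param stree [SpeciesTree-class] with designated outgroups.
#' @param verbose log the number of qualifying/skipped groups.
#' @return events data.frame: `group_id`, `branch` (loss-branch leaf set,
#'   `+`-joined), `state` (`candidate`), `counterparts` (`;`-joined gene
#'   ids), relic locus columns (NA until located), `n_disablers` (NA).
#' @export
callCandidateLosses <- function(groups, stree, verbose = FALSE) {
  sp <- speciesOf(stree)
  og <- outgroups(stree)
  ing <- ingroupSpecies(stree)
  if (length(og) == 0L) stop("tree has no designated outgroups")
  rows <- lapply(names(groups), function(g) {
    pat <- presencePattern(groups[[g]], sp)
    if (!all(pat[og])) return(NULL)
    if (all(pat)) return(NULL)
    dl <- dolloMinLosses(pat, stree)
    if (dl$count != 1L) return(NULL)
    lost <- dl$placements[[1]]
    if (!all(lost %in% ing)) return(NULL)
    cps <- unlist(groups[[g]][names(pat)[pat]], use.names = FALSE)
    data.frame(group_id = g,
               branch = paste(sort(lost), collapse = "+"),
               state = "candidate",
               counterparts = paste(cps, collapse = ";"),
               relic_chrom = NA_character_, relic_start = NA_real_,
               relic_end = NA_real_, relic_strand = NA_character_,
               n_disablers = NA_integer_, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  .msg(sprintf("loss caller: %d candidate event(s) from %d group(s)",
               length(rows), length(groups)), verbose = verbose)
  if (length(rows) == 0L) return(.emptyEvents())
  do.call(rbind, rows)
}

#' Remove contaminant candidate events
#'
#' Drops events whose counterparts are tagged as transposable elements or
#' mitochondrial/chloroplast-related genes — the classic sources of
#' spurious presence/absence signal in ortholog tables. Tag matching is
#' case-insensitive substring matching against a keyword list.
#'
#' @param events events data.frame from [callCandidateLosses()].
#' @param gene_tags named character vector: gene id -> free-text tags
#'   (e.g. the `tags` column of [readAnnotations()] keyed by `gene_id`).
#'   Counterparts with no entry are treated as untagged (with a warning).
#' @param keywords contaminant keywords.
#' @return list with `kept` and `removed` event data.frames; removed
#'   events get state `contaminant_removed`.
#' @export
filterContaminants <- function(events, gene_tags,
                               keywords = c("transposable", "transposon",
                                            "mitochondri", "chloroplast")) {
  if (nrow(events) == 0L) return(list(kept = events, removed = events))
  pat <- paste(tolower(keywords), collapse = "|")
  missing_any <- FALSE
  bad <- vapply(seq_len(nrow(events)), function(i) {
    cps <- strsplit(events$counterparts[i], ";", fixed = TRUE)[[1]]
    tg <- gene_tags[cps]
    if (anyNA(tg)) missing_any <<- TRUE
    tg <- tg[!is.na(tg)]
    any(grepl(pat, tolower(tg)))
  }, logical(1))
  if (missing_any)
    warning("some counterpart gene ids had no annotation tags; treated as untagged")
  removed <- events[bad, , drop = FALSE]
  if (nrow(removed)) removed$state <- "contaminant_removed"
  list(kept = events[!bad, , drop = FALSE], removed = removed)
}
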