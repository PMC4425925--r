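## Fixed 7-species design used throughout: four grasses as ingroup, three
## dicot outgroups. Terminal ingroup branch lengths give the divergence
## times used for death rates (brachypodium-rice 40 Myr, sorghum-maize
## 12 Myr); outgroups split > 160 Myr ago.
.INGROUP <- c("brachypodium", "rice", "sorghum", "maize")
.OUTGROUP <- c("arabidopsis", "poplar", "grape")
.TREE_MYR <- paste0(
  "(((maize:12,sorghum:12):38,(rice:40,brachypodium:40):10):110,",
  "(grape:117,(arabidopsis:108,poplar:108):9):43);")
.SUBST_PER_MYR <- 0.004

#' The default 7-species grass study tree
#'
#' @param unit `"Myr"` (divergence times) or `"subst"` (substitutions per
#'   site, a uniform-clock scaling of the Myr tree used for conservation
#'   scoring).
#' @return a [SpeciesTree-class] with outgroups designated.
#' @export
defaultSpeciesTree <- function(unit = c("Myr", "subst")) {
  unit <- match.arg(unit)
  tr <- ape::read.tree(text = .TREE_MYR)
  if (unit == "subst") tr$edge.length <- tr$edge.length * .SUBST_PER_MYR
  SpeciesTree(tr, outgroups = .OUTGROUP, unit = unit)
}

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

.randSeq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

.allCodons <- local({
  x <- as.vector(outer(as.vector(outer(.BASES, .BASES, paste0)),
                       .BASES, paste0))
  x[!x %in% .STOPS]
})

.randCds <- function(n_codons) {
  paste0("ATG", paste(sample(.allCodons, n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}

.codons <- function(seq) {
  substring(seq, seq(1, nchar(seq) - 2, 3), seq(3, nchar(seq), 3))
}

## Substitute sites at `rate`, then repair any internal stop codons so a
## noisy functional gene still translates end to end.
.mutateCds <- function(cds, rate) {
  if (rate <= 0) return(cds)
  b <- strsplit(cds, "")[[1]]
  hit <- which(runif(length(b)) < rate)
  hit <- hit[hit > 3 & hit <= length(b) - 3]   # keep start/stop codons
  for (i in hit) b[i] <- sample(setdiff(.BASES, b[i]), 1)
  cod <- .codons(paste(b, collapse = ""))
  internal <- seq(2, length(cod) - 1)
  bad <- internal[cod[internal] %in% .STOPS]
  for (i in bad) cod[i] <- sample(.allCodons, 1)
  paste(cod, collapse = "")
}

#' Mutate a CDS into a relic with known disablers
#'
#' Converts `n_stops` random internal codons to stop codons and applies
#' `n_frameshifts` random 1-2 nt indels at distinct, non-adjacent codons,
#' returning the exact planted positions so downstream detection can be
#' scored against truth.
#'
#' @param cds coding sequence (multiple of 3, `ATG...stop`).
#' @param n_frameshifts,n_stops how many lesions of each kind (their sum
#'   must be >= 1).
#' @param seed integer seed.
#' @param protect number of 5' codons left untouched (default 6; a
#'   lesion in the first few codons is indistinguishable from local
#'   alignment trimming, so lesions are kept clear of the 5' end).
#' @param protect_end number of 3' codons left untouched (default 8, so
#'   a lesion always has enough intact sequence downstream for a local
#'   alignment to extend across it).
#' @return list with `seq` (relic sequence) and `disablers` data.frame
#'   (`kind`, `codon` 1-based in the original CDS, `indel_len` signed nt
#'   change for frameshifts, 0 for stops).
#' @export
mutateToRelic <- function(cds, n_frameshifts = 1, n_stops = 1, seed = 1,
                          protect = 6, protect_end = 8) {
  L <- nchar(cds) %/% 3
  if (nchar(cds) %% 3 != 0) stop("cds length must be a multiple of 3")
  if (n_frameshifts + n_stops < 1) stop("at least one disabler required")
  if (nchar(cds) < 3 * (n_stops + 2)) stop("cds too short for requested stops")
  set.seed(.splitSeed(seed, 11))
  avail <- seq(protect + 1, max(protect + 1, L - protect_end))
  picks <- integer(0)
  for (k in seq_len(n_frameshifts + n_stops)) {
    ok <- setdiff(avail, c(picks, picks - 1L, picks + 1L))
    if (!length(ok)) stop("cds too short for requested non-adjacent disablers")
    picks <- c(picks, sample(ok, 1))
  }
  stop_at <- sort(picks[seq_len(n_stops)])
  fs_at <- sort(picks[n_stops + seq_len(n_frameshifts)])
  cod <- .codons(cds)
  for (i in stop_at) cod[i] <- sample(.STOPS, 1)
  dis <- data.frame(kind = character(0), codon = integer(0),
                    indel_len = integer(0))
  if (n_stops)
    dis <- rbind(dis, data.frame(kind = "premature_stop", codon = stop_at,
                                 indel_len = 0L))
  # apply indels 3' -> 5' so earlier codon indices stay valid
  for (i in rev(fs_at)) {
    k <- sample(1:2, 1)
    if (runif(1) < 0.5) {       # insertion of k nt after the codon
      cod[i] <- paste0(cod[i], .randSeq(k))
      dis <- rbind(dis, data.frame(kind = "frameshift", codon = i,
                                   indel_len = k))
    } else {                    # deletion of k nt from the codon
      cod[i] <- substring(cod[i], 1, 3 - k)
      dis <- rbind(dis, data.frame(kind = "frameshift", codon = i,
                                   indel_len = -k))
    }
  }
  list(seq = paste(cod, collapse = ""),
       disablers = dis[order(dis$codon), , drop = FALSE])
}

#' Simulate a log-normal FPKM matrix with planted structure
#'
#' Latent log2 expression is drawn i.i.d. normal per locus and sample;
#' planted pairwise correlations are imposed by empirical construction
#' (the realized latent sample correlation equals the target exactly),
#' planted copies duplicate a source row verbatim, and planted
#' differential expression adds a log2 fold change to chosen
#' locus/sample cells. FPKM = 2^latent.
#'
#' @param loci character vector of locus ids.
#' @param n_samples number of samples.
#' @param mean_log2 scalar or per-locus named vector of latent means.
#' @param sd_log2 latent standard deviation (default 0.8).
#' @param correlations data.frame (`locus_a`, `locus_b`, `r`), |r| < 1;
#'   a locus may serve as `locus_a` for several partners but may appear
#'   only once as `locus_b`.
#' @param copies data.frame (`locus`, `source`): rows copied exactly.
#' @param de data.frame (`locus`, `sample` index, `log2fc`).
#' @param seed integer seed.
#' @param sample_names optional sample names.
#' @return FPKM matrix (loci x samples).
#' @export
simulateExpression <- function(loci, n_samples, mean_log2 = 3,
                               sd_log2 = 0.8, correlations = NULL,
                               copies = NULL, de = NULL, seed = 1,
                               sample_names = NULL) {
  set.seed(.splitSeed(seed, 23))
  mu <- if (length(mean_log2) == 1L)
    setNames(rep(mean_log2, length(loci)), loci) else mean_log2[loci]
  Z <- matrix(rnorm(length(loci) * n_samples), length(loci), n_samples,
              dimnames = list(loci, sample_names %||%
                                paste0("S", seq_len(n_samples))))
  # fold changes go on the latent scale first, so a correlated partner
  # constructed afterwards co-inherits them and the realized correlation
  # stays exactly at target
  if (!is.null(de) && nrow(de))
    for (i in seq_len(nrow(de)))
      Z[de$locus[i], de$sample[i]] <-
        Z[de$locus[i], de$sample[i]] + de$log2fc[i] / sd_log2
  if (!is.null(correlations) && nrow(correlations)) {
    if (anyDuplicated(correlations$locus_b))
      stop("a locus may be correlation target only once ",
           "(non-positive-definite request)")
    if (any(abs(correlations$r) >= 1)) stop("|target R| must be < 1")
    for (i in seq_len(nrow(correlations))) {
      a <- correlations$locus_a[i]; b <- correlations$locus_b[i]
      r <- correlations$r[i]
      za <- as.numeric(scale(Z[a, ]))
      eb <- stats::residuals(stats::lm(Z[b, ] ~ Z[a, ]))
      eb <- as.numeric(scale(eb))
      Z[b, ] <- r * za + sqrt(1 - r^2) * eb
    }
  }
  L <- mu[loci] + sd_log2 * Z
  # copies come last so a copied row inherits planted fold changes too
  if (!is.null(copies) && nrow(copies))
    for (i in seq_len(nrow(copies)))
      L[copies$locus[i], ] <- L[copies$source[i], ]
  fpkm <- 2^L
  dimnames(fpkm) <- dimnames(Z)
  fpkm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a promoter multiple alignment by neutral site evolution
#'
#' Jukes-Cantor style evolution of an ancestral sequence along the tree:
#' each site on each branch substitutes with probability
#' 1 - exp(-(4/3) * multiplier * branch length), choosing uniformly
#' among the three other bases. No indels. Multiplier 0 reproduces the
#' ancestor at every tip (a perfectly conserved promoter); larger
#' multipliers approach saturation.
#'
#' @param ancestral ancestral sequence (or an integer length, in which
#'   case a random ancestor of that length is drawn).
#' @param stree [SpeciesTree-class] with substitutions/site branch
#'   lengths.
#' @param multiplier rate multiplier >= 0.
#' @param seed integer seed.
#' @param tips which tips to return (default all).
#' @return named character vector of aligned tip sequences.
#' @export
simulatePromoterMsa <- function(ancestral, stree, multiplier = 1,
                                seed = 1, tips = NULL) {
  stopifnot(multiplier >= 0)
  set.seed(.splitSeed(seed, 37))
  tr <- treeOf(stree)
  if (!is.null(tips)) tr <- ape::keep.tip(tr, tips)
  if (is.numeric(ancestral)) ancestral <- .randSeq(ancestral)
  n_tip <- length(tr$tip.label)
  seqs <- vector("list", n_tip + tr$Nnode)
  seqs[[n_tip + 1L]] <- strsplit(toupper(ancestral), "")[[1]]
  ord <- ape::reorder.phylo(tr, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; chi <- ord$edge[k, 2]
    bl <- ord$edge.length[k]
    p <- 1 - exp(-(4 / 3) * multiplier * bl)
    s <- seqs[[par]]
    hit <- which(runif(length(s)) < p)
    for (i in hit) s[i] <- sample(setdiff(.BASES, s[i]), 1)
    seqs[[chi]] <- s
  }
  out <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""), "")
  setNames(out, tr$tip.label)
}

## Pick a miRNA whose reverse complement, inserted in frame, introduces
## no stop codon (so planting it in a relic CDS leaves the planted
## disabler count intact).
.designMirna <- function(len = 21) {
  repeat {
    m <- .randSeq(len)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
    cod <- substring(rc, seq(1, len - 2, 3), seq(3, len, 3))
    if (!any(cod %in% .STOPS)) return(m)
  }
}

#' Simulate a complete input bundle with planted ground truth
#'
#' Builds internally consistent genomes, annotations, ortholog groups,
#' synteny anchors, expression matrices, promoter alignments, miRNA/UTR
#' sequences and a truth record for the full discovery pipeline. Planted
#' event classes: relic-retaining losses (mutated CDS left unannotated),
#' relic-lacking losses (CDS excised), contaminant groups (counterpart
#' tagged as a transposable element), genic-hit decoys (gene present and
#' annotated, ortholog row missing), intact-ORF decoys (gene present,
#' unannotated, undisabled), and gap-rejected losses (CDS replaced by an
#' N run). Expression planting covers unexpressed relics, leaky relics
#' (profile copied from the counterpart), a conserved-promoter relic,
#' and miRNA-decoy pairs with distractors (shared site without
#' correlation, correlation without site, homologous partner).
#'
#' @param n_groups total ortholog groups (default 50).
#' @param n_relic_retaining,n_relic_lacking planted losses per class
#'   (defaults 5 and 5).
#' @param n_contaminant,n_genic_hit,n_intact_orf,n_gap_rejected planted
#'   filter-stage decoys (defaults 2, 2, 2, 1).
#' @param n_samples expression samples (default 9, the nine-tissue
#'   design).
#' @param cds_codons codons per gene (default 100).
#' @param intergenic spacer length between genes, bp (default 400).
#' @param cds_noise per-site substitution rate between species copies of
#'   a CDS (default 0 = noise-free).
#' @param n_frameshifts,n_stops disablers planted per relic (defaults 1
#'   and 1).
#' @param n_unexpressed_relics,n_leaky,n_conserved_promoter,n_decoy
#'   expression/promoter/ceRNA planting counts (defaults 1, 1, 1, 2).
#' @param decoy_r target expression correlation of decoy pairs (default
#'   0.95).
#' @param msa_columns promoter alignment length (default 500).
#' @param n_background_promoters background gene promoter alignments per
#'   species (default 40).
#' @param relic_rate_multiplier promoter substitution-rate multiplier
#'   for non-conserved relic promoters (default 1.25; relic promoters
#'   degenerate faster than functional ones).
#' @param seed master seed; every sub-generator derives from it.
#' @return a `relicBundle` list: `species_tree` / `species_tree_subst`
#'   ([SpeciesTree-class]), `genomes`, `annotations`, `orthologs`,
#'   `anchors`, `fpkm` (per ingroup species), `samples`, `go_arabidopsis`,
#'   `go_background`, `go_term_names`, `mirnas`, `utrs`, `promoter_msas`,
#'   `background_msas`, and `truth`.
#' @export
simulateBundle <- function(n_groups = 50, n_relic_retaining = 5,
                           n_relic_lacking = 5, n_contaminant = 2,
                           n_genic_hit = 2, n_intact_orf = 2,
                           n_gap_rejected = 1, n_samples = 9,
                           cds_codons = 100, intergenic = 400,
                           cds_noise = 0, n_frameshifts = 1, n_stops = 1,
                           n_unexpressed_relics = 1, n_leaky = 1,
                           n_conserved_promoter = 1, n_decoy = 2,
                           decoy_r = 0.95, msa_columns = 500,
                           n_background_promoters = 40,
                           relic_rate_multiplier = 1.25, seed = 1) {
  n_special <- n_relic_retaining + n_relic_lacking + n_contaminant +
    n_genic_hit + n_intact_orf + n_gap_rejected
  if (n_special > n_groups)
    stop("more planted events than groups")
  n_expressed <- n_relic_retaining - n_unexpressed_relics
  if (n_leaky + n_conserved_promoter + n_decoy > n_expressed)
    stop("more expression/ceRNA plants than expressed relics")
  set.seed(.splitSeed(seed, 1))
  species <- c(.INGROUP, .OUTGROUP)
  stree <- defaultSpeciesTree("Myr")
  stree_subst <- defaultSpeciesTree("subst")

  groups_id <- sprintf("g%03d", seq_len(n_groups))
  rr <- groups_id[seq_len(n_relic_retaining)]
  off <- n_relic_retaining
  rl <- groups_id[off + seq_len(n_relic_lacking)]; off <- off + n_relic_lacking
  cont <- groups_id[off + seq_len(n_contaminant)]; off <- off + n_contaminant
  genich <- groups_id[off + seq_len(n_genic_hit)]; off <- off + n_genic_hit
  intact <- groups_id[off + seq_len(n_intact_orf)]; off <- off + n_intact_orf
  gapg <- if (n_gap_rejected)
    groups_id[off + seq_len(n_gap_rejected)] else character(0)
  rrTarget <- setNames(.INGROUP[(seq_along(rr) - 1) %% 4 + 1], rr)
  rlTarget <- setNames(.INGROUP[(seq_along(rl)) %% 4 + 1], rl)
  contTarget <- setNames(.INGROUP[(seq_along(cont) + 1) %% 4 + 1], cont)
  ghTarget <- setNames(.INGROUP[(seq_along(genich) + 2) %% 4 + 1], genich)
  ioTarget <- setNames(.INGROUP[(seq_along(intact) + 3) %% 4 + 1], intact)
  gapTarget <- setNames(.INGROUP[(seq_along(gapg)) %% 4 + 1], gapg)
  target_of <- c(rrTarget, rlTarget, contTarget, ghTarget, ioTarget, gapTarget)

  base_cds <- setNames(
    vapply(groups_id, function(g) .randCds(cds_codons), ""), groups_id)

  # relic expression/character plan
  relic_id <- setNames(paste0("relic_", rr), rr)
  expressed_rr <- rr[seq_len(n_expressed)]
  unexpressed_rr <- setdiff(rr, expressed_rr)
  leaky_rr <- expressed_rr[seq_len(n_leaky)]
  cons_rr <- expressed_rr[n_leaky + seq_len(n_conserved_promoter)]
  reliable_rr <- setdiff(expressed_rr, c(leaky_rr, cons_rr))
  decoy_rr <- reliable_rr[seq_len(n_decoy)]

  mirnas <- setNames(vapply(decoy_rr, function(g) .designMirna(21), ""),
                     paste0("mir_", decoy_rr))
  rcOf <- function(m)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))

  # per-species relic sequences (built from the target species' CDS copy)
  relic_seq <- list(); relic_disablers <- list()
  for (g in rr) {
    sp <- rrTarget[[g]]
    cds <- .mutateCds(base_cds[[g]], cds_noise)
    if (g %in% decoy_rr) {
      # plant the miRNA response element in frame at codons 5..11
      rc <- rcOf(mirnas[[paste0("mir_", g)]])
      cds <- paste0(substring(cds, 1, 12), rc, substring(cds, 34))
      mr <- mutateToRelic(cds, n_frameshifts, n_stops,
                          seed = .splitSeed(seed, 100 + match(g, groups_id)),
                          protect = 12)
    } else {
      mr <- mutateToRelic(cds, n_frameshifts, n_stops,
                          seed = .splitSeed(seed, 100 + match(g, groups_id)))
    }
    relic_seq[[g]] <- mr$seq
    relic_disablers[[g]] <- mr$disablers
  }

  # --- genomes + annotations + ortholog rows ----------------------------
  genomes <- list(); annotations <- list(); ortho_rows <- list()
  relic_locus <- list()
  for (sp in species) {
    parts <- list(.randSeq(500)); pos <- 500
    ann <- list()
    for (g in groups_id) {
      spacer <- .randSeq(intergenic)
      parts[[length(parts) + 1L]] <- spacer; pos <- pos + intergenic
      status <- "normal"
      if (g %in% names(target_of) && target_of[[g]] == sp) {
        status <- if (g %in% rr) "relic"
          else if (g %in% rl || g %in% cont) "absent"
          else if (g %in% gapg) "gap" else if (g %in% genich) "genic_hit"
          else if (g %in% intact) "intact_unannotated" else "normal"
      }
      gene_id <- paste0(sp, "_", g)
      if (status == "absent") next
      if (status == "gap") {
        parts[[length(parts) + 1L]] <- strrep("N", 50); pos <- pos + 50
        next
      }
      if (status == "relic") {
        s <- relic_seq[[g]]
        relic_locus[[g]] <- list(chrom = "chr1", start = pos,
                                 end = pos + nchar(s), strand = "+")
        parts[[length(parts) + 1L]] <- s; pos <- pos + nchar(s)
        next
      }
      cds <- if (status %in% c("genic_hit", "intact_unannotated"))
        base_cds[[g]] else .mutateCds(base_cds[[g]], cds_noise)
      parts[[length(parts) + 1L]] <- cds
      annotate <- status != "intact_unannotated"
      in_orth <- status == "normal"
      if (annotate) {
        tags <- if (g %in% cont && sp == "arabidopsis")
          "transposable_element" else ""
        ann[[length(ann) + 1L]] <- data.frame(
          gene_id = gene_id, chrom = "chr1", start = pos,
          end = pos + nchar(cds), strand = "+", type = "gene",
          tags = tags, stringsAsFactors = FALSE)
      }
      if (in_orth)
        ortho_rows[[length(ortho_rows) + 1L]] <- data.frame(
          group_id = g, species = sp, gene_id = gene_id,
          stringsAsFactors = FALSE)
      pos <- pos + nchar(cds)
    }
    parts[[length(parts) + 1L]] <- .randSeq(500)
    genomes[[sp]] <- setNames(paste(unlist(parts), collapse = ""), "chr1")
    annotations[[sp]] <- if (length(ann)) do.call(rbind, ann) else
      readAnnotations(textConnection("##gff-version 3"))
  }
  ortho_tab <- do.call(rbind, ortho_rows)
  groups <- lapply(split(ortho_tab, ortho_tab$group_id), function(g)
    lapply(split(g$gene_id, factor(g$species, levels = species)),
           as.character))
  groups <- groups[order(names(groups))]

  # anchors: every ingroup species pair, every group annotated in both
  anch <- list()
  pairs <- utils::combn(.INGROUP, 2)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    for (g in groups_id) {
      ga <- paste0(a, "_", g); gb <- paste0(b, "_", g)
      if (ga %in% annotations[[a]]$gene_id &&
          gb %in% annotations[[b]]$gene_id)
        anch[[length(anch) + 1L]] <- data.frame(
          species_a = a, gene_a = ga, species_b = b, gene_b = gb,
          stringsAsFactors = FALSE)
    }
  }
  anchors <- do.call(rbind, anch)

  # --- GO maps ----------------------------------------------------------
  set.seed(.splitSeed(seed, 41))
  dev_term <- "GO:0007275"
  other_terms <- c("GO:0008152", "GO:0005975", "GO:0006810", "GO:0009719")
  term_names <- setNames(
    c("multicellular organismal development", "metabolic process",
      "carbohydrate metabolic process", "transport",
      "response to endogenous stimulus"),
    c(dev_term, other_terms))
  lost_groups <- c(rr, rl)
  group_terms <- lapply(groups_id, function(g) {
    t <- sample(other_terms, sample(1:2, 1))
    if (g %in% lost_groups || runif(1) < 0.05) t <- c(dev_term, t)
    unique(t)
  })
  names(group_terms) <- groups_id
  go_ara <- setNames(group_terms, paste0("arabidopsis_", groups_id))
  # species backgrounds are drawn independently, with the planted term at
  # its genome-wide base rate (5%), the designed enrichment effect size
  go_bg <- lapply(.INGROUP, function(sp) {
    ids <- annotations[[sp]]$gene_id
    m <- setNames(lapply(ids, function(id)
      unique(sample(other_terms, sample(1:2, 1)))), ids)
    # the planted term is carried by exactly two background genes: the
    # background frequency is part of the designed effect size
    for (i in sample(seq_along(m), 2))
      m[[i]] <- unique(c(dev_term, m[[i]]))
    m
  })
  names(go_bg) <- .INGROUP

  # --- expression -------------------------------------------------------
  adjacent <- c(brachypodium = "rice", rice = "brachypodium",
                sorghum = "maize", maize = "sorghum")
  all_gene_loci <- unlist(lapply(.INGROUP, function(sp)
    annotations[[sp]]$gene_id), use.names = FALSE)
  relic_loci <- unname(relic_id)
  loci <- c(all_gene_loci, relic_loci)
  mu <- setNames(runif(length(loci), 2.5, 4.5), loci)
  mu[relic_id[unexpressed_rr]] <- -4
  corr <- NULL; copies <- NULL
  partner_of <- list(); distractors <- list()
  # decoy partners and distractors (attached to the first decoy relic)
  for (g in decoy_rr) {
    sp <- rrTarget[[g]]
    cand <- setdiff(annotations[[sp]]$gene_id,
                    paste0(sp, "_", c(lost_groups, genich, intact)))
    pt <- cand[match(g, decoy_rr)]
    partner_of[[g]] <- pt
    corr <- rbind(corr, data.frame(locus_a = relic_id[[g]], locus_b = pt,
                                   r = decoy_r))
  }
  g1 <- decoy_rr[1]; sp1 <- rrTarget[[g1]]
  cand1 <- setdiff(annotations[[sp1]]$gene_id,
                   c(paste0(sp1, "_", c(lost_groups, genich, intact)),
                     unlist(partner_of)))
  distractors$mre_only <- cand1[1]
  distractors$corr_only <- cand1[2]
  distractors$homolog <- cand1[3]
  corr <- rbind(corr,
                data.frame(locus_a = relic_id[[g1]],
                           locus_b = distractors$corr_only, r = decoy_r),
                data.frame(locus_a = relic_id[[g1]],
                           locus_b = distractors$homolog, r = decoy_r),
                data.frame(locus_a = relic_id[[g1]],
                           locus_b = distractors$mre_only, r = 0))
  # leaky relics copy their adjacent counterpart's profile verbatim
  for (g in leaky_rr) {
    cp <- paste0(adjacent[[rrTarget[[g]]]], "_", g)
    copies <- rbind(copies, data.frame(locus = relic_id[[g]], source = cp))
  }
  # independent (non-leaky) relics: exact zero correlation with their
  # counterpart so pattern similarity cannot arise by sampling accident
  for (g in setdiff(expressed_rr, leaky_rr)) {
    cp <- paste0(adjacent[[rrTarget[[g]]]], "_", g)
    if (cp %in% loci && !(cp %in% corr$locus_b))
      corr <- rbind(corr, data.frame(locus_a = relic_id[[g]],
                                     locus_b = cp, r = 0))
  }
  # leaky relics inherit the counterpart's fold change via the copy, so
  # their DE is planted on the counterpart; other relics get it directly
  de <- do.call(rbind, lapply(expressed_rr, function(g) {
    loc <- if (g %in% leaky_rr)
      paste0(adjacent[[rrTarget[[g]]]], "_", g) else relic_id[[g]]
    data.frame(locus = loc, sample = 1L, log2fc = 5)
  }))
  tissues <- c("leaf", "emerging_inflorescence", "early_inflorescence",
               "anther", "pistil", "seed_5dap", "seed_10dap",
               "embryo_25dap", "endosperm_25dap")
  samples <- head(tissues, n_samples)
  if (n_samples > length(tissues))
    samples <- c(tissues, paste0("sample_", seq_len(n_samples - length(tissues))))
  fpkm_all <- simulateExpression(loci, n_samples, mean_log2 = mu,
                                 correlations = corr, copies = copies,
                                 de = de, seed = .splitSeed(seed, 5),
                                 sample_names = samples)
  fpkm <- lapply(.INGROUP, function(sp) {
    ids <- c(annotations[[sp]]$gene_id,
             relic_id[rr[rrTarget[rr] == sp]])
    fpkm_all[intersect(ids, rownames(fpkm_all)), , drop = FALSE]
  })
  names(fpkm) <- .INGROUP

  # --- promoter alignments ----------------------------------------------
  promoter_msas <- list()
  for (g in expressed_rr) {
    sp_present <- setdiff(species, rrTarget[[g]])
    mult <- if (g %in% cons_rr) 0 else relic_rate_multiplier
    promoter_msas[[relic_id[[g]]]] <- simulatePromoterMsa(
      msa_columns, stree_subst, multiplier = mult,
      seed = .splitSeed(seed, 300 + match(g, groups_id)),
      tips = c(rrTarget[[g]], sp_present))
  }
  background_msas <- lapply(.INGROUP, function(sp) {
    lapply(seq_len(n_background_promoters), function(i)
      simulatePromoterMsa(msa_columns, stree_subst, multiplier = 1,
                          seed = .splitSeed(seed, 500 + i +
                                              match(sp, species) * 50)))
  })
  names(background_msas) <- .INGROUP

  # --- UTRs --------------------------------------------------------------
  set.seed(.splitSeed(seed, 71))
  utrs <- list()
  for (g in decoy_rr) {
    sp <- rrTarget[[g]]
    rc <- rcOf(mirnas[[paste0("mir_", g)]])
    pt <- partner_of[[g]]
    utrs[[pt]] <- paste0(.randSeq(90), rc, .randSeq(89))
  }
  utrs[[distractors$mre_only]] <-
    paste0(.randSeq(90), rcOf(mirnas[[paste0("mir_", g1)]]), .randSeq(89))
  utrs[[distractors$corr_only]] <- .randSeq(200)
  # homologous partner: its UTR embeds 150 nt of the relic around the MRE
  utrs[[distractors$homolog]] <-
    paste0(.randSeq(40), substring(relic_seq[[g1]], 1, 160), .randSeq(40))
  for (sp in .INGROUP) {
    extra <- setdiff(annotations[[sp]]$gene_id, names(utrs))
    for (gid in head(extra, 8)) utrs[[gid]] <- .randSeq(200)
  }

  truth <- list(
    seed = seed,
    relic_retaining = data.frame(group = rr, species = unname(rrTarget),
                                 relic_id = unname(relic_id),
                                 stringsAsFactors = FALSE),
    relic_lacking = data.frame(group = rl, species = unname(rlTarget),
                               stringsAsFactors = FALSE),
    contaminant = cont, genic_hit = genich, intact_orf = intact,
    gap_rejected = gapg,
    disablers = relic_disablers,
    relic_locus = relic_locus,
    expressed = relic_id[expressed_rr],
    unexpressed = relic_id[unexpressed_rr],
    leaky = relic_id[leaky_rr],
    conserved_promoter = relic_id[cons_rr],
    reliable = relic_id[reliable_rr],
    decoys = data.frame(relic = unname(relic_id[decoy_rr]),
                        mirna = paste0("mir_", decoy_rr),
                        partner = unlist(partner_of),
                        stringsAsFactors = FALSE),
    distractors = distractors,
    enriched_term = dev_term)

  structure(list(
    species = species, ingroup = .INGROUP, outgroup = .OUTGROUP,
    species_tree = stree, species_tree_subst = stree_subst,
    genomes = genomes, annotations = annotations, orthologs = groups,
    anchors = anchors, fpkm = fpkm, samples = samples,
    go_arabidopsis = go_ara, go_background = go_bg,
    go_term_names = term_names, mirnas = mirnas, utrs = utrs,
    promoter_msas = promoter_msas, background_msas = background_msas,
    truth = truth), class = "relicBundle")
}

#' Write a simulated bundle to a directory of standard-format files
#'
#' Emits FASTA genomes, GFF3 annotations, newick trees, TSV tables
#' (orthologs, anchors, FPKM, GO maps, samples), FASTA miRNA/UTR files,
#' multi-FASTA promoter alignments and a JSON truth file.
#'
#' @param bundle a `relicBundle` from [simulateBundle()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("genomes", "annotations", "expression", "promoters"))
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  ape::write.tree(treeOf(bundle$species_tree),
                  file.path(dir, "species_tree_myr.nwk"))
  ape::write.tree(treeOf(bundle$species_tree_subst),
                  file.path(dir, "species_tree_subst.nwk"))
  writeLines(bundle$outgroup, file.path(dir, "outgroups.txt"))
  writeLines(bundle$species, file.path(dir, "species.txt"))
  for (sp in bundle$species) {
    writeFastaSeqs(bundle$genomes[[sp]],
                   file.path(dir, "genomes", paste0(sp, ".fa")))
    writeAnnotations(bundle$annotations[[sp]],
                     file.path(dir, "annotations", paste0(sp, ".gff3")))
  }
  writeOrthologGroups(bundle$orthologs, file.path(dir, "orthologs.tsv"))
  write.table(bundle$anchors, file.path(dir, "anchors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (sp in names(bundle$fpkm))
    writeExpression(bundle$fpkm[[sp]],
                    file.path(dir, "expression", paste0(sp, "_fpkm.tsv")))
  write.table(data.frame(sample = bundle$samples, tissue = bundle$samples),
              file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  goa <- data.frame(
    gene_id = rep(names(bundle$go_arabidopsis),
                  lengths(bundle$go_arabidopsis)),
    term_id = unlist(bundle$go_arabidopsis, use.names = FALSE))
  goa$term_name <- unname(bundle$go_term_names[goa$term_id])
  write.table(goa, file.path(dir, "go_arabidopsis.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (sp in names(bundle$go_background)) {
    gb <- bundle$go_background[[sp]]
    tab <- data.frame(gene_id = rep(names(gb), lengths(gb)),
                      term_id = unlist(gb, use.names = FALSE))
    write.table(tab, file.path(dir, paste0("go_background_", sp, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeFastaSeqs(bundle$mirnas, file.path(dir, "mirnas.fa"))
  writeFastaSeqs(unlist(bundle$utrs), file.path(dir, "utrs.fa"))
  for (rid in names(bundle$promoter_msas))
    writeFastaSeqs(bundle$promoter_msas[[rid]],
                   file.path(dir, "promoters", paste0(rid, ".fa")))
  dir.create(file.path(dir, "promoters_background"), showWarnings = FALSE)
  for (sp in names(bundle$background_msas)) {
    msas <- bundle$background_msas[[sp]]
    for (i in seq_along(msas))
      writeFastaSeqs(msas[[i]],
                     file.path(dir, "promoters_background",
                               sprintf("%s_%03d.fa", sp, i)))
  }
  jsonlite::write_json(
    list(seed = bundle$truth$seed,
         relic_retaining = bundle$truth$relic_retaining,
         relic_lacking = bundle$truth$relic_lacking,
         contaminant = bundle$truth$contaminant,
         expressed = unname(bundle$truth$expressed),
         leaky = unname(bundle$truth$leaky),
         conserved_promoter = unname(bundle$truth$conserved_promoter),
         decoys = bundle$truth$decoys),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
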