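## Protein sequence of an annotated gene, translated from its genomic
## interval (truncated at the first stop).
.geneProtein <- function(bundle, sp, gene_id) {
  ann <- bundle$annotations[[sp]]
  i <- match(gene_id, ann$gene_id)
  if (is.na(i)) return(NULL)
  s <- substring(bundle$genomes[[sp]][[ann$chrom[i]]],
                 ann$start[i] + 1, ann$end[i])
  if (ann$strand[i] == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s <- substring(s, 1, (nchar(s) %/% 3) * 3)
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(s), if.fuzzy.codon = "X")))
  sub("\\*.*$", "", aa)
}

## Phylogenetically nearest species (among `candidates`) to `sp`.
.nearestSpecies <- function(stree, sp, candidates) {
  d <- ape::cophenetic.phylo(treeOf(stree))[sp, candidates, drop = TRUE]
  candidates[which.min(d)]
}

#' Run the full unitary-gene-loss discovery pipeline on a bundle
#'
#' Chains every stage on an in-memory input bundle (from
#' [simulateBundle()] or [readBundle()]): Dollo candidate calling,
#' contaminant removal, protein-to-genome relic search and
#' classification, synteny validation of hit-less candidates, death
#' rates, GO slim enrichment, expression vetting of relics (expression
#' call, DE, level/specificity comparison, pattern similarity), promoter
#' conservation, and ceRNA decoy calling. Per-stage candidate counts are
#' logged and returned.
#'
#' @param bundle a `relicBundle` (or a directory path readable by
#'   [readBundle()]).
#' @param config a [PipelineConfig-class]; defaults to the bundle's
#'   species design with standard thresholds.
#' @param outdir optional directory to write result TSVs and a JSON
#'   summary.
#' @param verbose log per-stage counts.
#' @return a `relicPipelineResult` list: `events`, `rates`, `mean_rate`,
#'   `enrichment` (per-species list), `expression` (per-relic table),
#'   `comparison` (level/specificity tests), `conservation`, `cerna`,
#'   `summary` (stage counts).
#' @export
runPipeline <- function(bundle, config = NULL, outdir = NULL,
                        verbose = FALSE) {
  if (is.character(bundle)) bundle <- readBundle(bundle)
  if (is.null(config))
    config <- pipelineConfig(bundle$ingroup, bundle$outgroup)
  if (length(intersect(config@ingroup, config@outgroup)))
    stop("config error: ingroup and outgroup overlap")
  th <- config@thresholds
  stree <- bundle$species_tree
  counts <- list()

  # stage 1: Dollo candidates
  events <- callCandidateLosses(bundle$orthologs, stree, verbose = verbose)
  counts$candidates <- nrow(events)

  # stage 2: contaminant filter
  tags <- unlist(lapply(bundle$annotations, function(a)
    setNames(a$tags, a$gene_id)))
  names(tags) <- sub("^[^.]*\\.", "", names(tags))
  fc <- suppressWarnings(filterContaminants(events, tags))
  events <- fc$kept
  counts$contaminant_removed <- nrow(fc$removed)
  counts$after_contaminant <- nrow(events)
  .msg(sprintf("contaminant filter: removed %d, kept %d",
               nrow(fc$removed), nrow(events)), verbose = verbose)

  # stage 3: relic search + classification
  for (i in seq_len(nrow(events))) {
    lost_sp <- strsplit(events$branch[i], "+", fixed = TRUE)[[1]]
    target <- lost_sp[1]
    grp <- bundle$orthologs[[events$group_id[i]]]
    with_gene <- names(grp)[lengths(grp) > 0]
    src <- .nearestSpecies(stree, target, setdiff(with_gene, lost_sp))
    prot <- .geneProtein(bundle, src, grp[[src]][1])
    if (is.null(prot) || nchar(prot) < 10) next
    hits <- scanGenome(prot, bundle$genomes[[target]],
                       bundle$annotations[[target]],
                       query = grp[[src]][1])
    events[i, ] <- classifyCandidate(
      events[i, , drop = FALSE], hits,
      intact_orf_coverage = th[["intact_orf_coverage"]])
  }
  counts$genic_hit_removed <- sum(events$state == "genic_hit_removed")
  counts$intact_orf_removed <- sum(events$state == "intact_orf_removed")
  counts$relic_retaining <- sum(events$state == "relic_retaining")
  .msg(sprintf(
    "relic search: %d genic, %d intact-ORF, %d relic-retaining, %d hit-less",
    counts$genic_hit_removed, counts$intact_orf_removed,
    counts$relic_retaining, sum(events$state == "candidate")),
    verbose = verbose)

  # stage 4: synteny for the hit-less
  for (i in which(events$state == "candidate")) {
    target <- strsplit(events$branch[i], "+", fixed = TRUE)[[1]][1]
    loc <- suppressWarnings(inferLocus(
      events[i, , drop = FALSE], bundle$orthologs, bundle$anchors,
      bundle$annotations[intersect(bundle$ingroup, names(bundle$annotations))],
      target))
    if (is.null(loc)) {
      events$state[i] <- "synteny_rejected"
      next
    }
    v <- validateLocus(loc, bundle$annotations[[target]],
                       genome_seq = bundle$genomes[[target]][[loc$chrom]],
                       gap_min_n = th[["gap_min_n"]])
    events$state[i] <- v$state
    if (v$state == "relic_lacking") {
      events$relic_chrom[i] <- loc$chrom
      events$relic_start[i] <- loc$start
      events$relic_end[i] <- loc$end
    }
  }
  counts$relic_lacking <- sum(events$state == "relic_lacking")
  counts$synteny_rejected <- sum(events$state == "synteny_rejected")
  final <- events[events$state %in% c("relic_retaining", "relic_lacking"), ,
                  drop = FALSE]
  counts$final_events <- nrow(final)
  .msg(sprintf("synteny: %d relic-lacking, %d rejected; %d final events",
               counts$relic_lacking, counts$synteny_rejected, nrow(final)),
       verbose = verbose)

  # stage 5: death rates (terminal-branch events over terminal branch time)
  tr <- treeOf(stree)
  term_len <- setNames(
    tr$edge.length[match(seq_along(tr$tip.label), tr$edge[, 2])],
    tr$tip.label)
  rates <- do.call(rbind, lapply(bundle$ingroup, function(sp)
    computeDeathRate(sum(final$branch == sp), term_len[[sp]], species = sp)))
  mean_rate <- meanDeathRate(rates)

  # stage 6: GO slim enrichment per species
  lost_terms <- annotateLostFunctions(final, bundle$go_arabidopsis)
  enrichment <- lapply(bundle$ingroup, function(sp) {
    idx <- final$branch == sp
    if (!any(idx)) return(NULL)
    enrichGoSlim(lost_terms[final$group_id[idx]],
                 bundle$go_background[[sp]],
                 term_names = bundle$go_term_names)
  })
  names(enrichment) <- bundle$ingroup

  # stage 7: expression vetting of relics
  adjacent <- vapply(bundle$ingroup, function(sp)
    .nearestSpecies(stree, sp, setdiff(bundle$ingroup, sp)), "")
  rr <- final[final$state == "relic_retaining", , drop = FALSE]
  expr <- NULL; rel_rows <- NULL; cp_rows <- NULL
  for (i in seq_len(nrow(rr))) {
    sp <- strsplit(rr$branch[i], "+", fixed = TRUE)[[1]][1]
    rid <- paste0("relic_", rr$group_id[i])
    m <- bundle$fpkm[[sp]]
    if (!(rid %in% rownames(m))) next
    cp_sp <- adjacent[[sp]]
    cp_gene <- bundle$orthologs[[rr$group_id[i]]][[cp_sp]][1]
    cp_m <- bundle$fpkm[[cp_sp]]
    row <- m[rid, ]
    ex <- isExpressed(row, th[["fpkm_cutoff"]])
    expr <- rbind(expr, data.frame(
      relic = rid, species = sp, group = rr$group_id[i],
      expressed = ex,
      specificity = if (sum(row) > 0) tissueSpecificity(row) else NA_real_,
      counterpart = cp_gene %||% NA_character_,
      stringsAsFactors = FALSE))
    if (ex && !is.null(cp_gene) && cp_gene %in% rownames(cp_m)) {
      rel_rows <- rbind(rel_rows, m[rid, , drop = FALSE])
      cp_rows <- rbind(cp_rows, cp_m[cp_gene, , drop = FALSE])
    }
  }
  counts$expressed_relics <- sum(expr$expressed %||% logical(0))
  comparison <- NULL; corr_res <- NULL
  if (!is.null(rel_rows) && nrow(rel_rows) > 0) {
    comparison <- list(
      level = compareRelicsToCounterparts(rel_rows, cp_rows, "level"),
      specificity = compareRelicsToCounterparts(rel_rows, cp_rows,
                                                "specificity"))
    ps <- c(comparison$level$p, comparison$specificity$p)
    qs <- p.adjust(ps, method = "BH")
    comparison$level$q <- qs[1]; comparison$specificity$q <- qs[2]
    corr_res <- correlateRelicCounterpart(
      rel_rows, cp_rows, r_cutoff = th[["pearson_r_cutoff"]],
      alpha = th[["fdr_level"]], fpkm_cutoff = th[["fpkm_cutoff"]])
  }
  # DE flags (fallback test) for expressed relics, per species matrix
  de_flags <- character(0)
  for (sp in bundle$ingroup) {
    m <- bundle$fpkm[[sp]]
    if (is.null(m) || !nrow(m)) next
    de <- differentialExpressionFallback(m, alpha = th[["fdr_level"]])
    de_flags <- c(de_flags, rownames(m)[de$de])
  }
  if (!is.null(expr)) expr$de <- expr$relic %in% de_flags

  # stage 8: promoter conservation of expressed relics
  conservation <- NULL
  if (!is.null(expr) && any(expr$expressed)) {
    cons_list <- list()
    for (sp in unique(expr$species[expr$expressed])) {
      rids <- expr$relic[expr$expressed & expr$species == sp]
      rids <- intersect(rids, names(bundle$promoter_msas))
      if (!length(rids) || is.null(bundle$background_msas[[sp]])) next
      prof <- lapply(bundle$promoter_msas[rids], function(a)
        gerpScores(a, bundle$species_tree_subst)$rs)
      bg <- lapply(bundle$background_msas[[sp]], function(a)
        gerpScores(a, bundle$species_tree_subst)$rs)
      cons_list[[sp]] <- cbind(
        species = sp,
        testPromoterConservation(prof, bg, alpha = th[["fdr_level"]]))
    }
    if (length(cons_list)) conservation <- do.call(rbind, cons_list)
  }

  # reliable expressed relics: expressed minus (pattern-similar or
  # conserved-promoter)
  similar <- if (!is.null(corr_res))
    corr_res$relic[corr_res$verdict == "pattern_similar"] else character(0)
  conserved <- if (!is.null(conservation))
    conservation$relic[conservation$conserved] else character(0)
  reliable <- if (!is.null(expr))
    setdiff(expr$relic[expr$expressed], c(similar, conserved)) else character(0)
  if (!is.null(expr)) {
    expr$pattern_similar <- expr$relic %in% similar
    expr$conserved_promoter <- expr$relic %in% conserved
    expr$reliable <- expr$relic %in% reliable
  }
  counts$pattern_similar <- length(similar)
  counts$conserved_promoter <- length(conserved)
  counts$reliable_relics <- length(reliable)
  .msg(sprintf("expression vetting: %d expressed, %d similar, %d conserved, %d reliable",
               counts$expressed_relics %||% 0, length(similar),
               length(conserved), length(reliable)), verbose = verbose)

  # stage 9: ceRNA decoys among reliable relics
  cerna <- NULL
  if (length(reliable) && length(bundle$mirnas)) {
    relic_mres <- NULL; relic_seqs <- list(); relic_groups <- character(0)
    fpkm_rows <- NULL
    for (rid in reliable) {
      g <- sub("^relic_", "", rid)
      sp <- expr$species[match(rid, expr$relic)]
      ev <- final[final$group_id == g, , drop = FALSE]
      if (!nrow(ev) || is.na(ev$relic_chrom[1])) next
      seqs <- substring(bundle$genomes[[sp]][[ev$relic_chrom[1]]],
                        ev$relic_start[1] + 1, ev$relic_end[1])
      if (ev$relic_strand[1] %in% "-")
        seqs <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(seqs)))
      relic_seqs[[rid]] <- seqs
      relic_groups[rid] <- g
      mre <- predictMres(seqs, bundle$mirnas, cutoff = th[["mre_cutoff"]])
      if (nrow(mre)) relic_mres <- rbind(relic_mres, cbind(host = rid, mre))
      fpkm_rows <- rbind(fpkm_rows,
                         bundle$fpkm[[sp]][rid, , drop = FALSE])
    }
    utr_mres <- NULL
    for (gid in names(bundle$utrs)) {
      mre <- predictMres(bundle$utrs[[gid]], bundle$mirnas,
                         cutoff = th[["mre_cutoff"]])
      if (nrow(mre)) utr_mres <- rbind(utr_mres, cbind(host = gid, mre))
    }
    fpkm_all <- do.call(rbind, lapply(names(bundle$fpkm), function(sp) {
      m <- bundle$fpkm[[sp]]
      m[setdiff(rownames(m), rownames(fpkm_rows %||% matrix(0, 0, 0))), ,
        drop = FALSE]
    }))
    fpkm_comb <- rbind(fpkm_rows, fpkm_all)
    if (!is.null(relic_mres) && !is.null(utr_mres))
      cerna <- callCerna(relic_mres, utr_mres, fpkm_comb,
                         bundle$orthologs, relic_groups,
                         relic_seqs, bundle$utrs,
                         alpha = th[["fdr_level"]])
  }
  counts$cerna_calls <- if (!is.null(cerna)) sum(cerna$called) else 0L
  counts$cerna_relics <- if (!is.null(cerna))
    length(unique(cerna$relic[cerna$called])) else 0L

  res <- structure(list(
    events = events, final = final, rates = rates, mean_rate = mean_rate,
    enrichment = enrichment, expression = expr, comparison = comparison,
    correlation = corr_res, conservation = conservation, cerna = cerna,
    reliable = reliable, summary = counts, config = config),
    class = "relicPipelineResult")
  if (!is.null(outdir)) writePipelineResult(res, outdir)
  res
}

#' Write pipeline result tables and a JSON summary
#'
#' @param res a `relicPipelineResult`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writePipelineResult <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) if (!is.null(x))
    write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(res$events, "events.tsv")
  wt(res$rates, "death_rates.tsv")
  enr <- do.call(rbind, lapply(names(res$enrichment), function(sp) {
    e <- res$enrichment[[sp]]
    if (is.null(e)) NULL else cbind(species = sp, e)
  }))
  wt(enr, "enrichment.tsv")
  wt(res$expression, "expression.tsv")
  wt(res$conservation, "conservation.tsv")
  wt(res$cerna, "cerna.tsv")
  jsonlite::write_json(
    c(res$summary, list(mean_death_rate = res$mean_rate$mean_vd)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.relicPipelineResult <- function(x, ...) {
  cat("relicPipelineResult\n")
  for (nm in names(x$summary))
    cat(sprintf("  %-22s %s\n", nm, x$summary[[nm]]))
  invisible(x)
}

#' Read a bundle directory written by [writeBundle()]
#'
#' @param dir bundle directory.
#' @return a `relicBundle` list (truth omitted: truth travels in
#'   `truth.json`, which the pipeline never reads).
#' @export
readBundle <- function(dir) {
  outg <- readLines(file.path(dir, "outgroups.txt"))
  stree <- readSpeciesTree(file.path(dir, "species_tree_myr.nwk"),
                           outgroups = outg, unit = "Myr")
  stree_s <- readSpeciesTree(file.path(dir, "species_tree_subst.nwk"),
                             outgroups = outg, unit = "subst")
  species <- if (file.exists(file.path(dir, "species.txt")))
    readLines(file.path(dir, "species.txt")) else speciesOf(stree)
  genomes <- lapply(species, function(sp)
    readFastaSeqs(file.path(dir, "genomes", paste0(sp, ".fa"))))
  names(genomes) <- species
  annotations <- lapply(species, function(sp)
    readAnnotations(file.path(dir, "annotations", paste0(sp, ".gff3"))))
  names(annotations) <- species
  ingroup <- setdiff(species, outg)
  fpkm <- lapply(ingroup, function(sp)
    readExpression(file.path(dir, "expression", paste0(sp, "_fpkm.tsv"))))
  names(fpkm) <- ingroup
  go_bg <- lapply(ingroup, function(sp)
    readGoMap(file.path(dir, paste0("go_background_", sp, ".tsv"))))
  names(go_bg) <- ingroup
  goa <- readGoMap(file.path(dir, "go_arabidopsis.tsv"))
  pm_files <- list.files(file.path(dir, "promoters"), pattern = "\\.fa$",
                         full.names = TRUE)
  pm <- lapply(pm_files, readFastaSeqs)
  names(pm) <- sub("\\.fa$", "", basename(pm_files))
  bg_files <- list.files(file.path(dir, "promoters_background"),
                         pattern = "\\.fa$", full.names = TRUE)
  bg_msas <- NULL
  if (length(bg_files)) {
    bg_sp <- sub("_[0-9]+\\.fa$", "", basename(bg_files))
    bg_msas <- lapply(split(bg_files, bg_sp), function(fs)
      lapply(fs, readFastaSeqs))
  }
  samples <- read.delim(file.path(dir, "samples.tsv"))$sample
  utr_v <- readFastaSeqs(file.path(dir, "utrs.fa"))
  structure(list(
    species = species, ingroup = ingroup, outgroup = outg,
    species_tree = stree, species_tree_subst = stree_s,
    genomes = genomes, annotations = annotations,
    orthologs = readOrthologGroups(file.path(dir, "orthologs.tsv"),
                                   species = species),
    anchors = readAnchors(file.path(dir, "anchors.tsv")),
    fpkm = fpkm, samples = samples,
    go_arabidopsis = goa, go_background = go_bg,
    go_term_names = attr(goa, "term_names"),
    mirnas = readFastaSeqs(file.path(dir, "mirnas.fa")),
    utrs = as.list(utr_v),
    promoter_msas = pm,
    background_msas = bg_msas), class = "relicBundle")
}
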