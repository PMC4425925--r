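#' @import methods
#' @useDynLib geneRelics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor dhyper fisher.test p.adjust pnorm pt rbinom rnorm
#'   runif sd setNames var wilcox.test quantile
#' @importFrom utils read.delim write.table head tail
NULL

#' SpeciesTree: a rooted species tree with designated outgroups
#'
#' Thin S4 wrapper around an [ape::read.tree()] `phylo` object that carries
#' the designated outgroup leaf set and the unit of the branch lengths
#' (millions of years for rate work, substitutions/site for conservation
#' work). Loss calling requires the ingroup (all non-outgroup leaves) to
#' form a clade.
#'
#' @slot tree a rooted `phylo` object with unique tip labels.
#' @slot outgroups character vector of outgroup tip labels.
#' @slot unit branch-length unit, `"Myr"` or `"subst"` (or `"none"`).
#' @exportClass SpeciesTree
setClass("SpeciesTree",
  representation(tree = "ANY", outgroups = "character", unit = "character"))

setValidity("SpeciesTree", function(object) {
  tr <- object@tree
  if (!inherits(tr, "phylo")) return("@tree must be a 'phylo' object")
  if (anyDuplicated(tr$tip.label)) return("tip labels must be unique")
  if (!all(object@outgroups %in% tr$tip.label))
    return("outgroups must all be tip labels")
  ing <- setdiff(tr$tip.label, object@outgroups)
  if (length(ing) == 0L) return("ingroup is empty")
  if (length(object@outgroups) > 0L && length(ing) > 1L) {
    if (!ape::is.monophyletic(tr, ing))
      return("ingroup tips must form a clade")
  }
  if (!object@unit %in% c("Myr", "subst", "none"))
    return("unit must be 'Myr', 'subst' or 'none'")
  TRUE
})

#' Construct a SpeciesTree
#'
#' @param tree a `phylo` object or path to a newick file.
#' @param outgroups character vector of outgroup tip labels.
#' @param unit branch length unit: `"Myr"`, `"subst"` or `"none"`.
#' @return a [SpeciesTree-class] object.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' st <- SpeciesTree(tr, outgroups = "C")
#' @export
SpeciesTree <- function(tree, outgroups = character(), unit = "none") {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  new("SpeciesTree", tree = tree, outgroups = outgroups, unit = unit)
}

#' @describeIn SpeciesTree-class read a newick file into a SpeciesTree
#' @param path newick file path.
#' @param outgroups,unit passed to the constructor.
#' @export
readSpeciesTree <- function(path, outgroups = character(), unit = "none") {
  SpeciesTree(ape::read.tree(path), outgroups = outgroups, unit = unit)
}

#' @rdname SpeciesTree-accessors
#' @param x a SpeciesTree.
#' @return `speciesOf()` all tip labels; `outgroups()` the outgroup labels;
#'   `ingroupSpecies()` the non-outgroup labels; `treeOf()` the `phylo`.
#' @export
speciesOf <- function(x) x@tree$tip.label

#' @rdname SpeciesTree-accessors
#' @export
outgroups <- function(x) x@outgroups

#' @rdname SpeciesTree-accessors
#' @export
ingroupSpecies <- function(x) setdiff(x@tree$tip.label, x@outgroups)

#' @rdname SpeciesTree-accessors
#' @export
treeOf <- function(x) x@tree

setMethod("show", "SpeciesTree", function(object) {
  cat("SpeciesTree with", length(speciesOf(object)), "species",
      sprintf("(unit: %s)\n", object@unit))
  cat("  ingroup: ", paste(ingroupSpecies(object), collapse = ", "), "\n")
  cat("  outgroup:", paste(outgroups(object), collapse = ", "), "\n")
})

#' RelicAlignment: frameshift-aware protein-to-DNA alignment
#'
#' Result of aligning an orthologous-counterpart protein against a genomic
#' locus with a three-frame local dynamic program. Frame changes are
#' recorded as frameshift edit operations; in-frame stop codons inside the
#' alignment are retained and recorded, since both are the ORF-disrupting
#' lesions ("disablers") that mark a relic.
#'
#' @slot query query protein identifier.
#' @slot chrom,start,end,strand target locus (0-based half-open, genomic).
#' @slot score alignment score.
#' @slot coverage aligned query residues / query length, in \[0,1\].
#' @slot ops data.frame of edit operations: columns `op` (`match`,
#'   `frameshift`, `stop`, `qgap`, `tgap`), `qpos` (1-based protein
#'   position, NA for tgap), `tpos` (0-based offset of the first consumed
#'   nucleotide within the aligned DNA window), `len` (nucleotides
#'   consumed).
#' @exportClass RelicAlignment
setClass("RelicAlignment",
  representation(query = "character", chrom = "character",
                 start = "numeric", end = "numeric", strand = "character",
                 score = "numeric", coverage = "numeric",
                 ops = "data.frame"))

setValidity("RelicAlignment", function(object) {
  if (object@coverage < 0 || object@coverage > 1)
    return("coverage must lie in [0,1]")
  if (length(object@start) && object@start > object@end)
    return("start must not exceed end")
  TRUE
})

setMethod("show", "RelicAlignment", function(object) {
  cat(sprintf("RelicAlignment: %s vs %s:%d-%d(%s)\n", object@query,
              object@chrom, as.integer(object@start),
              as.integer(object@end), object@strand))
  cat(sprintf("  score %.1f, coverage %.2f, %d frameshift(s), %d internal stop(s)\n",
              object@score, object@coverage,
              sum(object@ops$op == "frameshift"),
              sum(object@ops$op == "stop")))
})

#' @rdname RelicAlignment-accessors
#' @param x a RelicAlignment.
#' @return `alignmentScore()` the score; `queryCoverage()` the covered
#'   fraction of the query; `alignmentOps()` the edit-operation table.
#' @export
alignmentScore <- function(x) x@score

#' @rdname RelicAlignment-accessors
#' @export
queryCoverage <- function(x) x@coverage

#' @rdname RelicAlignment-accessors
#' @export
alignmentOps <- function(x) x@ops

#' PipelineConfig: thresholds and species design for a run
#'
#' Holds the species design (ingroup/outgroups, tree file paths) and every
#' tunable threshold of the pipeline, defaulted to the study design values:
#' FPKM > 1 for expression, Pearson R > 0.6 for pattern similarity, FDR
#' level 0.05, 2 kb promoters, MRE penalty cutoff 4, intact-ORF coverage
#' 0.8.
#'
#' @slot ingroup,outgroup character vectors of species ids (disjoint,
#'   nonempty).
#' @slot thresholds named numeric vector of thresholds.
#' @slot seed integer random seed for the run.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(ingroup = "character", outgroup = "character",
                 thresholds = "numeric", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  if (length(object@ingroup) == 0L || length(object@outgroup) == 0L)
    return("ingroup and outgroup must be nonempty")
  if (length(intersect(object@ingroup, object@outgroup)) > 0L)
    return("ingroup and outgroup must be disjoint")
  th <- object@thresholds
  if (th[["fpkm_cutoff"]] < 0) return("fpkm_cutoff must be >= 0")
  if (th[["pearson_r_cutoff"]] <= -1 || th[["pearson_r_cutoff"]] >= 1)
    return("pearson_r_cutoff must lie in (-1,1)")
  if (th[["fdr_level"]] <= 0 || th[["fdr_level"]] >= 1)
    return("fdr_level must lie in (0,1)")
  if (th[["promoter_length"]] <= 0) return("promoter_length must be > 0")
  if (th[["intact_orf_coverage"]] < 0 || th[["intact_orf_coverage"]] > 1)
    return("intact_orf_coverage must lie in [0,1]")
  TRUE
})

#' Construct a PipelineConfig
#'
#' @param ingroup,outgroup species id vectors.
#' @param fpkm_cutoff FPKM threshold for calling a locus expressed
#'   (strictly greater-than; default 1).
#' @param pearson_r_cutoff R threshold for the pattern-similarity verdict
#'   (default 0.6).
#' @param fdr_level FDR significance level (default 0.05).
#' @param mre_cutoff maximum MRE penalty score (default 4).
#' @param promoter_length promoter window in bp (default 2000).
#' @param intact_orf_coverage query coverage required before a clean
#'   intergenic hit counts as an intact ORF (default 0.8).
#' @param gap_min_n minimum run of N called an assembly gap (default 10).
#' @param seed integer seed.
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(ingroup, outgroup,
                           fpkm_cutoff = 1, pearson_r_cutoff = 0.6,
                           fdr_level = 0.05, mre_cutoff = 4,
                           promoter_length = 2000,
                           intact_orf_coverage = 0.8,
                           gap_min_n = 10, seed = 1L) {
  new("PipelineConfig", ingroup = ingroup, outgroup = outgroup,
      thresholds = c(fpkm_cutoff = fpkm_cutoff,
                     pearson_r_cutoff = pearson_r_cutoff,
                     fdr_level = fdr_level, mre_cutoff = mre_cutoff,
                     promoter_length = promoter_length,
                     intact_orf_coverage = intact_orf_coverage,
                     gap_min_n = gap_min_n),
      seed = as.integer(seed))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat("  ingroup: ", paste(object@ingroup, collapse = ", "), "\n")
  cat("  outgroup:", paste(object@outgroup, collapse = ", "), "\n")
  th <- object@thresholds
  cat("  thresholds:", paste(names(th), th, sep = "=", collapse = ", "), "\n")
})
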