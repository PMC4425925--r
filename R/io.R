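#' Read gene annotations from GFF3
#'
#' Parses a GFF3 file and returns one row per `gene` (and, when present,
#' `pseudogene`) feature with internal 0-based half-open coordinates.
#' GFF3 is 1-based inclusive; the conversion (`start - 1`, `end`) happens
#' here and only here. Attribute tags needed downstream (the
#' transposable-element / organellar contaminant filter and biotype
#' labels) are kept in the `tags` column.
#'
#' @param path GFF3 file.
#' @param feature_types feature types to keep (default `gene` and
#'   `pseudogene`).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `type`, `tags` (semicolon-joined
#'   free-text classification tags, possibly empty).
#' @export
readAnnotations <- function(path, feature_types = c("gene", "pseudogene")) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop(sprintf("malformed GFF3 line %d: expected >= 8 tab-separated fields", i))
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e))
      stop(sprintf("malformed GFF3 line %d: non-numeric coordinates", i))
    if (e < s)
      stop(sprintf("malformed GFF3 line %d: end < start", i))
  }
  if (length(body) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), type = character(),
                      tags = character(), stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% feature_types
  gr <- gr[keep]
  if (length(gr) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), type = character(),
                      tags = character(), stringsAsFactors = FALSE))
  }
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  if (!is.null(gr$Name)) {
    miss <- is.na(ids); ids[miss] <- as.character(gr$Name)[miss]
  }
  tagcols <- intersect(c("biotype", "Note", "note", "classification"),
                       colnames(S4Vectors::mcols(gr)))
  tags <- rep("", length(gr))
  for (tc in tagcols) {
    v <- S4Vectors::mcols(gr)[[tc]]
    v <- vapply(as.list(v), function(z) paste(z, collapse = ";"), "")
    tags <- ifelse(nzchar(v), ifelse(nzchar(tags), paste(tags, v, sep = ";"), v), tags)
  }
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,  # -> 0-based half-open
             end = as.numeric(GenomicRanges::end(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             type = as.character(gr$type),
             tags = tags, stringsAsFactors = FALSE)
}

#' Write annotations to GFF3
#'
#' Inverse of [readAnnotations()]: internal 0-based half-open intervals are
#' converted back to 1-based inclusive GFF3 coordinates.
#'
#' @param ann annotation data.frame from [readAnnotations()].
#' @param path output file.
#' @export
writeAnnotations <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(ann)) {
    attr_str <- sprintf("ID=%s", ann$gene_id)
    has <- nzchar(ann$tags)
    attr_str[has] <- paste0(attr_str[has], ";Note=", ann$tags[has])
    writeLines(sprintf("%s\tgeneRelics\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       ann$chrom, ann$type, as.integer(ann$start + 1),
                       as.integer(ann$end), ann$strand, attr_str), con)
  }
  invisible(path)
}

#' Read ortholog groups
#'
#' Reads a long-format TSV (`group_id`, `species`, `gene_id`; one row per
#' gene) into a list of per-group species-to-genes maps. Duplicate
#' (group, gene) rows are deduplicated with a warning.
#'
#' @param path TSV file with the three columns above (header required).
#' @param species optional character vector of the configured species set;
#'   rows naming a species outside it are an error.
#' @return named list; element `g` is a named list mapping species id to a
#'   character vector of gene ids (possibly empty for configured species
#'   with no genes).
#' @export
readOrthologGroups <- function(path, species = NULL) {
  tab <- read.delim(path, header = TRUE, colClasses = "character")
  need <- c("group_id", "species", "gene_id")
  if (!all(need %in% colnames(tab)))
    stop("ortholog table must have columns: ", paste(need, collapse = ", "))
  if (!is.null(species)) {
    bad <- setdiff(unique(tab$species), species)
    if (length(bad))
      stop("unknown species id(s) in ortholog table: ",
           paste(bad, collapse = ", "))
  }
  key <- paste(tab$group_id, tab$species, tab$gene_id)
  if (anyDuplicated(key)) {
    warning("duplicate (group, gene) rows deduplicated")
    tab <- tab[!duplicated(key), , drop = FALSE]
  }
  sp_all <- if (is.null(species)) sort(unique(tab$species)) else species
  out <- lapply(split(tab, tab$group_id), function(g) {
    m <- split(g$gene_id, factor(g$species, levels = sp_all))
    lapply(m, as.character)
  })
  out[order(names(out))]
}

#' Write ortholog groups to TSV (inverse of [readOrthologGroups()])
#' @param groups list as returned by [readOrthologGroups()].
#' @param path output TSV.
#' @export
writeOrthologGroups <- function(groups, path) {
  rows <- do.call(rbind, lapply(names(groups), function(g) {
    m <- groups[[g]]
    sp <- rep(names(m), lengths(m))
    if (length(sp) == 0L) return(NULL)
    data.frame(group_id = g, species = sp, gene_id = unlist(m, use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(group_id = character(), species = character(),
                       gene_id = character())
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Presence pattern of an ortholog group
#'
#' A species is present when it has at least one annotated gene in the
#' group (paralog count does not matter).
#'
#' @param group one element of [readOrthologGroups()] output.
#' @param species the configured species set (pattern keys).
#' @return named logical vector over `species`.
#' @export
presencePattern <- function(group, species) {
  p <- vapply(species, function(s) {
    g <- group[[s]]
    !is.null(g) && length(g) > 0L
  }, logical(1))
  names(p) <- species
  p
}

#' Read synteny anchors
#'
#' @param path TSV with columns `species_a`, `gene_a`, `species_b`,
#'   `gene_b`.
#' @return data.frame of anchors.
#' @export
readAnchors <- function(path) {
  tab <- read.delim(path, header = TRUE, colClasses = "character")
  need <- c("species_a", "gene_a", "species_b", "gene_b")
  if (!all(need %in% colnames(tab)))
    stop("anchor table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Read an FPKM expression matrix
#'
#' @param path TSV; first column `locus`, remaining columns one per
#'   sample, values FPKM (non-negative).
#' @return numeric matrix, loci in rows, samples in columns.
#' @export
readExpression <- function(path) {
  tab <- read.delim(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("FPKM values must be non-negative")
  m
}

#' Write an FPKM expression matrix (inverse of [readExpression()])
#' @param m numeric matrix (loci x samples).
#' @param path output TSV.
#' @export
writeExpression <- function(m, path) {
  df <- data.frame(locus = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-GO-slim map
#'
#' @param path TSV with columns `gene_id`, `term_id` and optionally
#'   `term_name`.
#' @return named list mapping gene id to a character vector of term ids;
#'   attribute `term_names` carries the id-to-name map when present.
#' @export
readGoMap <- function(path) {
  tab <- read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("gene_id", "term_id") %in% colnames(tab)))
    stop("GO map must have columns gene_id, term_id")
  m <- lapply(split(tab$term_id, tab$gene_id), unique)
  if ("term_name" %in% colnames(tab)) {
    tn <- tab[!duplicated(tab$term_id), c("term_id", "term_name")]
    attr(m, "term_names") <- setNames(tn$term_name, tn$term_id)
  }
  m
}

#' Read a FASTA file as a named character vector of sequences
#' @param path FASTA file.
#' @param type `"DNA"` or `"AA"`.
#' @return named character vector.
#' @export
readFastaSeqs <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @param type `"DNA"` or `"AA"`.
#' @export
writeFastaSeqs <- function(seqs, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") Biostrings::DNAStringSet(seqs)
       else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
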