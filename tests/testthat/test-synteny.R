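## A two-species toy layout: the target (rice) lost gene g2; its rice
## neighbours g1 and g3 are anchored to maize partners.
toyAnnotations <- function() {
  maize <- data.frame(
    gene_id = c("maize_g1", "maize_g2", "maize_g3"),
    chrom = "chr1", start = c(100, 3000, 8000),
    end = c(600, 3500, 8500), strand = "+", type = "gene", tags = "",
    stringsAsFactors = FALSE)
  rice <- data.frame(
    gene_id = c("rice_g1", "rice_g3"),
    chrom = "chr1", start = c(1000, 5000), end = c(2000, 6000),
    strand = "+", type = "gene", tags = "", stringsAsFactors = FALSE)
  list(maize = maize, rice = rice)
}

toyEvent <- function() data.frame(
  group_id = "g2", branch = "rice", state = "candidate",
  counterparts = "maize_g2", relic_chrom = NA_character_,
  relic_start = NA_real_, relic_end = NA_real_,
  relic_strand = NA_character_, n_disablers = NA_integer_,
  stringsAsFactors = FALSE)

toyGroups <- function() list(
  g1 = list(maize = "maize_g1", rice = "rice_g1"),
  g2 = list(maize = "maize_g2", rice = character(0)),
  g3 = list(maize = "maize_g3", rice = "rice_g3"))

toyAnchors <- function() data.frame(
  species_a = "maize", gene_a = c("maize_g1", "maize_g3"),
  species_b = "rice", gene_b = c("rice_g1", "rice_g3"),
  stringsAsFactors = FALSE)

test_that("a flanked counterpart projects to the span between anchors", {
  loc <- inferLocus(toyEvent(), toyGroups(), toyAnchors(),
                    toyAnnotations(), target = "rice")
  expect_equal(loc$chrom, "chr1")
  expect_equal(loc$start, 2000)
  expect_equal(loc$end, 5000)
  expect_equal(loc$sources, "maize")
})

test_that("missing flank or inconsistent sources yield no locus", {
  # drop the downstream anchor: counterpart at the end of a block
  a <- toyAnchors()[1, , drop = FALSE]
  expect_null(inferLocus(toyEvent(), toyGroups(), a, toyAnnotations(),
                         target = "rice"))
  # second source proposing a disjoint interval: synteny-inconsistent
  ann <- toyAnnotations()
  ann$sorghum <- data.frame(
    gene_id = c("sorghum_g1", "sorghum_g2", "sorghum_g3"),
    chrom = "chr1", start = c(0, 400, 900), end = c(300, 700, 1200),
    strand = "+", type = "gene", tags = "", stringsAsFactors = FALSE)
  ann$rice <- rbind(ann$rice, data.frame(
    gene_id = c("rice_x1", "rice_x2"), chrom = "chr1",
    start = c(20000, 30000), end = c(21000, 31000), strand = "+",
    type = "gene", tags = "", stringsAsFactors = FALSE))
  groups <- toyGroups()
  groups$g1$sorghum <- "sorghum_g1"
  groups$g2$sorghum <- "sorghum_g2"
  groups$g3$sorghum <- "sorghum_g3"
  anchors <- rbind(toyAnchors(), data.frame(
    species_a = "sorghum", gene_a = c("sorghum_g1", "sorghum_g3"),
    species_b = "rice", gene_b = c("rice_x1", "rice_x2")))
  expect_null(inferLocus(toyEvent(), groups, anchors, ann,
                         target = "rice"))
})

test_that("anchors to unknown genes are skipped with a warning", {
  anchors <- rbind(toyAnchors(), data.frame(
    species_a = "maize", gene_a = "maize_ghost",
    species_b = "rice", gene_b = "rice_ghost"))
  expect_warning(
    loc <- inferLocus(toyEvent(), toyGroups(), anchors, toyAnnotations(),
                      target = "rice"),
    "unknown genes")
  expect_equal(loc$start, 2000)
})

test_that("locus validation rejects gene overlap and gaps, half-open", {
  ann <- toyAnnotations()$rice
  locus <- list(chrom = "chr1", start = 2000, end = 5000)
  clean <- paste(rep("ACGT", 2000), collapse = "")
  expect_equal(validateLocus(locus, ann, clean)$state, "relic_lacking")
  # 1-bp overlap with an annotated gene
  v <- validateLocus(list(chrom = "chr1", start = 1999, end = 5000),
                     ann, clean)
  expect_equal(v$state, "synteny_rejected")
  expect_equal(v$reason, "gene")
  # abutting (half-open) is not an overlap
  expect_equal(validateLocus(list(chrom = "chr1", start = 2000, end = 5000),
                             ann, clean)$state, "relic_lacking")
  # a 50-nt N run inside the interval
  gapped <- paste0(strrep("ACGT", 750), strrep("N", 50),
                   strrep("ACGT", 500))
  v2 <- validateLocus(locus, ann, gapped)
  expect_equal(v2$state, "synteny_rejected")
  expect_equal(v2$reason, "gap")
  # verdict does not depend on annotation row order
  expect_equal(validateLocus(locus, ann[rev(seq_len(nrow(ann))), ], clean),
               validateLocus(locus, ann, clean))
})

test_that("N-run detection honours the minimum length", {
  s <- paste0(strrep("A", 100), strrep("N", 9), strrep("C", 100),
              strrep("N", 10), strrep("G", 50))
  g <- findAssemblyGaps(s, min_n = 10)
  expect_equal(nrow(g), 1L)
  expect_equal(g$start, 209)
  expect_equal(g$end, 219)
})
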