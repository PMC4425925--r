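test_that("identity alignment: full coverage, no disablers", {
  cds <- randomCds(40, seed = 101)
  prot <- translateCds(cds)
  aln <- alignProteinToLocus(prot, cds)
  expect_equal(queryCoverage(aln), 1)
  expect_equal(nrow(findDisablers(aln)), 0L)
  expect_error(alignProteinToLocus("MK!T", cds), "non-IUPAC")
  expect_error(alignProteinToLocus(prot, "ACGT-ACGT"), "non-IUPAC")
})

test_that("a planted 1-nt insertion is reported as one frameshift at its codon", {
  cds <- randomCds(40, seed = 102)
  prot <- translateCds(cds)
  cds_fs <- paste0(substring(cds, 1, 30), "A", substring(cds, 31))
  d <- findDisablers(alignProteinToLocus(prot, cds_fs))
  expect_equal(nrow(d), 1L)
  expect_equal(d$kind, "frameshift")
  expect_equal(d$protein_pos, 10)
})

test_that("a planted internal stop is reported at its codon", {
  cds <- randomCds(40, seed = 103)
  prot <- translateCds(cds)
  cds_stop <- paste0(substring(cds, 1, 57), "TGA", substring(cds, 61))
  d <- findDisablers(alignProteinToLocus(prot, cds_stop))
  expect_equal(nrow(d), 1L)
  expect_equal(d$kind, "premature_stop")
  expect_equal(d$protein_pos, 20)
  # stop + frameshift together: both reported, sorted by position
  cds_both <- paste0(substring(cds_stop, 1, 30), "CA", substring(cds_stop, 31))
  d2 <- findDisablers(alignProteinToLocus(prot, cds_both))
  expect_equal(d2$kind, c("frameshift", "premature_stop"))
  expect_equal(sort(d2$dna_pos), d2$dna_pos)
})

test_that("no disablers are ever reported for a protein against its own CDS", {
  for (s in 1:8) {
    cds <- randomCds(sample(20:60, 1), seed = 200 + s)
    aln <- alignProteinToLocus(translateCds(cds), cds)
    expect_equal(nrow(findDisablers(aln)), 0L, info = paste("seed", s))
    expect_equal(queryCoverage(aln), 1)
  }
})

test_that("DP score equals the independent recursion oracle on small inputs", {
  set.seed(7)
  bases <- c("A", "C", "G", "T")
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:25) {
    prot <- paste(sample(aas, sample(3:8, 1), replace = TRUE), collapse = "")
    dna <- paste(sample(bases, sample(9:40, 1), replace = TRUE), collapse = "")
    got <- alignmentScore(alignProteinToLocus(prot, dna))
    want <- oracleAlignScore(prot, dna)
    expect_equal(got, want, info = paste("case", k, prot, dna))
  }
})

test_that("genome scan finds planted loci and labels genic overlap", {
  set.seed(31)
  cds <- randomCds(60, seed = 301)
  prot <- translateCds(cds)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
  # genome: annotated copy at 1000, intergenic relic (1 stop) at 2820
  relic <- paste0(substring(cds, 1, 87), "TAA", substring(cds, 91))
  genome <- c(chr1 = paste0(flank(1000), cds, flank(1820 - nchar(cds)),
                            relic, flank(800)))
  relic_at <- 2820
  ann <- data.frame(gene_id = "gene1", chrom = "chr1", start = 1000,
                    end = 1000 + nchar(cds), strand = "+", type = "gene",
                    tags = "")
  hits <- scanGenome(prot, genome, ann)
  expect_gte(length(hits), 2L)
  genic <- vapply(hits, `[[`, logical(1), "genic")
  expect_true(any(genic) && any(!genic))
  ig <- hits[[which(!genic)[1]]]$aln
  expect_true(ig@start >= relic_at - 60 &&
                ig@end <= relic_at + nchar(relic) + 60)
  # a random genome with no homology yields nothing
  expect_length(scanGenome(prot, c(chr1 = flank(5000)), ann[0, ]), 0L)
})

test_that("genome scan recovers a minus-strand copy at the right interval", {
  cds <- randomCds(60, seed = 302)
  prot <- translateCds(cds)
  set.seed(33)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
  genome <- c(chr1 = paste0(flank(700), revComp(cds), flank(700)))
  hits <- scanGenome(prot, genome, data.frame(
    gene_id = character(0), chrom = character(0), start = numeric(0),
    end = numeric(0), strand = character(0), type = character(0),
    tags = character(0)))
  expect_gte(length(hits), 1L)
  aln <- hits[[1]]$aln
  expect_equal(aln@strand, "-")
  expect_true(aln@start >= 700 - 5 && aln@end <= 700 + nchar(cds) + 5)
})

test_that("classification precedence: genic > intact ORF > relic", {
  ev <- data.frame(group_id = "g", branch = "rice", state = "candidate",
                   counterparts = "x", relic_chrom = NA_character_,
                   relic_start = NA_real_, relic_end = NA_real_,
                   relic_strand = NA_character_, n_disablers = NA_integer_,
                   stringsAsFactors = FALSE)
  mk <- function(genic, ndis, cov, score = 300) {
    ops <- data.frame(op = c(rep("match", 10),
                             rep("frameshift", ndis)),
                      qpos = 1:(10 + ndis), tpos = seq(0, by = 3,
                                                       length.out = 10 + ndis),
                      len = 3)
    list(aln = new("RelicAlignment", query = "q", chrom = "chr1",
                   start = 0, end = 100, strand = "+", score = score,
                   coverage = cov, ops = ops), genic = genic)
  }
  # genic beats a disabled intergenic hit
  e1 <- classifyCandidate(ev, list(mk(TRUE, 0, 1), mk(FALSE, 2, 1)))
  expect_equal(e1$state, "genic_hit_removed")
  # clean intergenic hit at coverage 0.95 -> intact ORF
  e2 <- classifyCandidate(ev, list(mk(FALSE, 0, 0.95)))
  expect_equal(e2$state, "intact_orf_removed")
  # disabled intergenic hit -> relic retained with locus and count
  e3 <- classifyCandidate(ev, list(mk(FALSE, 2, 0.9)))
  expect_equal(e3$state, "relic_retaining")
  expect_equal(e3$n_disablers, 2L)
  expect_equal(e3$relic_chrom, "chr1")
  # clean but short fragment is not an intact ORF; with no disabled hit
  # either, the event stays a candidate for the synteny stage
  e4 <- classifyCandidate(ev, list(mk(FALSE, 0, 0.5)))
  expect_equal(e4$state, "candidate")
  # no hits at all: unchanged
  expect_equal(classifyCandidate(ev, list())$state, "candidate")
})
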