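substTree <- function(text, outg = character(0))
  SpeciesTree(ape::read.tree(text = text), outgroups = outg, unit = "subst")

test_that("promoter extraction is strand-aware and truncates at neighbours", {
  genome <- c(chr1 = strrep("ACGT", 5000))
  ann0 <- data.frame(gene_id = character(0), chrom = character(0),
                     start = numeric(0), end = numeric(0),
                     strand = character(0), type = character(0),
                     tags = character(0))
  p <- extractPromoter(list(chrom = "chr1", start = 10000, end = 12000,
                            strand = "+"), ann0, genome)
  expect_equal(c(p$start, p$end, p$length), c(8000, 10000, 2000))
  expect_equal(p$seq, substring(genome[["chr1"]], 8001, 10000))
  m <- extractPromoter(list(chrom = "chr1", start = 10000, end = 12000,
                            strand = "-"), ann0, genome)
  expect_equal(c(m$start, m$end), c(12000, 14000))
  # upstream gene ending at 9500 truncates the window to 500 bp
  ann <- data.frame(gene_id = "up", chrom = "chr1", start = 9000,
                    end = 9500, strand = "+", type = "gene", tags = "")
  t1 <- extractPromoter(list(chrom = "chr1", start = 10000, end = 12000,
                             strand = "+"), ann, genome)
  expect_equal(c(t1$start, t1$end, t1$length), c(9500, 10000, 500))
  # abutting neighbour: zero-length promoter, flagged by length 0
  ann2 <- transform(ann, end = 10000)
  t2 <- extractPromoter(list(chrom = "chr1", start = 10000, end = 12000,
                             strand = "+"), ann2, genome)
  expect_equal(t2$length, 0)
})

test_that("neutral rate sums branch lengths of the pruned tree", {
  st <- substTree("((A:0.1,B:0.2):0.05,C:0.3);")
  expect_equal(neutralRate(st, c("A", "B", "C")), 0.65)
  expect_equal(neutralRate(st, c("A", "B")), 0.3)
  expect_equal(neutralRate(st, c("A", "C")), 0.1 + 0.05 + 0.3)
  expect_error(neutralRate(st, "A"), ">= 2")
  st_nolen <- SpeciesTree(ape::read.tree(text = "((A,B),C);"),
                          unit = "subst")
  expect_error(neutralRate(st_nolen, c("A", "B")), "branch lengths")
})

test_that("per-column RS: conserved column attains the pruned tree length", {
  st <- substTree("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  aln <- c(A = "AAAA", B = "AAAA", C = "AAAA", D = "AAAA")
  g <- gerpScores(aln, st)
  expect_equal(g$rs, rep(3, 4))          # observed 0 everywhere
  expect_equal(g$mean_rs, 3)
  # one deviant leaf on a star-ish tree: observed 1, RS = N - 1
  aln2 <- c(A = "A", B = "A", C = "A", D = "C")
  g2 <- gerpScores(aln2, st)
  expect_equal(g2$observed, 1)
  expect_equal(g2$rs, 3 - 1)
  # columns with < 3 ungapped species are uninformative
  aln3 <- c(A = "A-", B = "A-", C = "-A", D = "AA")
  g3 <- gerpScores(aln3, st)
  expect_true(is.na(g3$rs[2]))
  expect_error(gerpScores(c(A = "-", B = "-", C = "-", D = "-"), st),
               "uninformative")
})

test_that("Fitch column counts match brute-force minimal-mutation search", {
  set.seed(101)
  for (k in 1:12) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n, tip.label = LETTERS[1:n])
    st <- SpeciesTree(tr, unit = "subst")
    states <- setNames(as.list(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE)), LETTERS[1:n])
    aln <- setNames(unlist(states), names(states))
    got <- fitchColumnCounts(aln, st, min_species = 3)
    expect_equal(got, bruteForceFitch(tr, states), info = paste("case", k))
  }
})

test_that("RS never exceeds pruned tree length; equality iff monomorphic", {
  set.seed(55)
  st <- defaultSpeciesTree("subst")
  aln <- simulatePromoterMsa(300, st, multiplier = 2, seed = 3)
  g <- gerpScores(aln, st)
  N <- neutralRate(st, names(aln))
  expect_true(all(g$rs <= N + 1e-12, na.rm = TRUE))
  mono <- vapply(seq_len(300), function(j)
    length(unique(substring(aln, j, j))) == 1L, logical(1))
  expect_equal(g$rs == N, mono)
})

test_that("doubling branch lengths doubles N and leaves Fitch unchanged", {
  st <- defaultSpeciesTree("subst")
  tr2 <- treeOf(st); tr2$edge.length <- tr2$edge.length * 2
  st2 <- SpeciesTree(tr2, outgroups = outgroups(st), unit = "subst")
  aln <- simulatePromoterMsa(100, st, multiplier = 1.5, seed = 8)
  g1 <- gerpScores(aln, st); g2 <- gerpScores(aln, st2)
  expect_equal(g2$observed, g1$observed)
  expect_equal(g2$neutral, 2 * g1$neutral)
  expect_equal(g2$rs, 2 * g1$neutral - g1$observed)
})

test_that("a planted conserved promoter is the only one flagged", {
  st <- defaultSpeciesTree("subst")
  bg <- lapply(1:35, function(i)
    gerpScores(simulatePromoterMsa(200, st, multiplier = 1,
                                   seed = 1000 + i), st)$rs)
  relics <- c(
    list(conserved = gerpScores(
      simulatePromoterMsa(200, st, multiplier = 0, seed = 7), st)$rs),
    setNames(lapply(1:6, function(i)
      gerpScores(simulatePromoterMsa(200, st, multiplier = 1.3,
                                     seed = 2000 + i), st)$rs),
      paste0("fast", 1:6)))
  res <- testPromoterConservation(relics, bg)
  expect_true(res$conserved[res$relic == "conserved"])
  expect_false(any(res$conserved[res$relic != "conserved"]))
})
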