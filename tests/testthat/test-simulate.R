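test_that("relic mutagenesis plants the requested lesions at known codons", {
  cds <- randomCds(60, seed = 401)
  mr <- mutateToRelic(cds, n_frameshifts = 1, n_stops = 0, seed = 5)
  expect_equal(nrow(mr$disablers), 1L)
  expect_equal(mr$disablers$kind, "frameshift")
  expect_true(abs(mr$disablers$indel_len) %in% 1:2)
  expect_equal(nchar(mr$seq), nchar(cds) + mr$disablers$indel_len)
  ms <- mutateToRelic(cds, n_frameshifts = 0, n_stops = 1, seed = 5)
  i <- ms$disablers$codon
  expect_true(substring(ms$seq, 3 * i - 2, 3 * i) %in%
                c("TAA", "TAG", "TGA"))
  expect_equal(nchar(ms$seq), nchar(cds))      # codon-aligned replacement
  expect_error(mutateToRelic(cds, 0, 0), "at least one")
  expect_error(mutateToRelic("ATGTAA", 0, 3), "too short")
  # planted lesions are found by the aligner
  prot <- translateCds(cds)
  both <- mutateToRelic(cds, 1, 1, seed = 9)
  d <- findDisablers(alignProteinToLocus(prot, both$seq))
  expect_equal(sort(table(d$kind)),
               sort(table(c("frameshift", "premature_stop"))))
})

test_that("expression simulation realizes planted correlations exactly", {
  loci <- c("a", "b", "c")
  corr <- data.frame(locus_a = "a", locus_b = "b", r = 0.9)
  m <- simulateExpression(loci, 1000, correlations = corr, seed = 2)
  latent <- log2(m)
  expect_equal(cor(latent["a", ], latent["b", ]), 0.9, tolerance = 1e-10)
  # log2(FPKM + 1), the analysis scale, stays within +-0.03
  l1 <- log2(m + 1)
  expect_equal(cor(l1["a", ], l1["b", ]), 0.9, tolerance = 0.03)
  # independent loci: mean |r| near the null expectation sqrt(2/(pi n))
  set.seed(3)
  rs <- vapply(1:300, function(i) {
    mm <- simulateExpression(c("x", "y"), 50, seed = 5000 + i)
    cor(log2(mm["x", ]), log2(mm["y", ]))
  }, numeric(1))
  expect_lt(abs(mean(abs(rs)) - sqrt(2 / (pi * 50))), 0.025)
  expect_error(simulateExpression(loci, 9,
                                  correlations = data.frame(
                                    locus_a = c("a", "c"),
                                    locus_b = c("b", "b"), r = 0.5)),
               "positive-definite")
  expect_error(simulateExpression(loci, 9,
                                  correlations = data.frame(
                                    locus_a = "a", locus_b = "b", r = 1)),
               "< 1")
})

test_that("a planted fold change is recovered by the fallback DE test", {
  loci <- paste0("L", 1:300)
  de <- data.frame(locus = "L1", sample = 2L, log2fc = 4)
  m <- simulateExpression(loci, 4, de = de, seed = 6)
  res <- differentialExpressionFallback(m)
  expect_true(res$de[["L1"]])
  expect_lt(mean(res$de), 0.05)   # few false positives elsewhere
})

test_that("promoter alignment evolution matches the per-branch model", {
  st <- defaultSpeciesTree("subst")
  # multiplier 0: all rows identical to each other
  a0 <- simulatePromoterMsa(200, st, multiplier = 0, seed = 4)
  expect_equal(length(unique(a0)), 1L)
  # substitution fraction on a two-leaf tree matches the JC probability
  tr2 <- ape::read.tree(text = "(A:0.25,B:0.25);")
  st2 <- SpeciesTree(tr2, unit = "subst")
  a2 <- simulatePromoterMsa(2000, st2, multiplier = 1, seed = 8)
  p_one_branch <- 1 - exp(-(4 / 3) * 0.25)
  p_diff_expected <- 2 * p_one_branch * (1 - p_one_branch) +
    p_one_branch^2 * (2 / 3)   # both mutate, 2/3 chance of differing
  frac <- mean(strsplit(a2[["A"]], "")[[1]] != strsplit(a2[["B"]], "")[[1]])
  expect_equal(frac, p_diff_expected, tolerance = 3 * sqrt(0.25 / 2000) + 0.02)
  # saturation: mean RS decreases monotonically in the rate multiplier
  rs_at <- vapply(c(0, 1, 10), function(mult)
    gerpScores(simulatePromoterMsa(300, st, multiplier = mult, seed = 12),
               st)$mean_rs, numeric(1))
  expect_true(all(diff(rs_at) < 0))
})

test_that("bundles are deterministic in the seed and internally consistent", {
  b1 <- simulateBundle(n_groups = 12, n_relic_retaining = 2,
                       n_relic_lacking = 2, n_contaminant = 1,
                       n_genic_hit = 1, n_intact_orf = 1,
                       n_gap_rejected = 1, n_unexpressed_relics = 1,
                       n_leaky = 0, n_conserved_promoter = 0, n_decoy = 1,
                       n_background_promoters = 5, seed = 42)
  b2 <- simulateBundle(n_groups = 12, n_relic_retaining = 2,
                       n_relic_lacking = 2, n_contaminant = 1,
                       n_genic_hit = 1, n_intact_orf = 1,
                       n_gap_rejected = 1, n_unexpressed_relics = 1,
                       n_leaky = 0, n_conserved_promoter = 0, n_decoy = 1,
                       n_background_promoters = 5, seed = 42)
  expect_identical(b1$genomes, b2$genomes)
  expect_identical(b1$fpkm, b2$fpkm)
  expect_identical(b1$truth$decoys, b2$truth$decoys)
  # single-branch absence patterns match the planted loss count
  sp <- b1$species
  absences <- vapply(b1$orthologs, function(g) {
    pat <- presencePattern(g, sp)
    sum(!pat)
  }, numeric(1))
  expect_equal(sum(absences == 1),
               2 + 2 + 1 + 1 + 1 + 1)   # every planted single-species class
  expect_error(simulateBundle(n_groups = 3), "more planted")
})

test_that("bundle write/read round-trips the pipeline inputs", {
  b <- simulateBundle(n_groups = 12, n_relic_retaining = 2,
                      n_relic_lacking = 2, n_contaminant = 1,
                      n_genic_hit = 1, n_intact_orf = 1,
                      n_gap_rejected = 0, n_unexpressed_relics = 1,
                      n_leaky = 0, n_conserved_promoter = 0, n_decoy = 1,
                      n_background_promoters = 5, seed = 13)
  dir <- tempfile()
  writeBundle(b, dir)
  rb <- readBundle(dir)
  expect_identical(rb$genomes, b$genomes)
  expect_identical(rb$annotations, b$annotations)
  expect_identical(rb$orthologs, b$orthologs)
  expect_identical(rb$anchors, b$anchors)
  expect_equal(rb$fpkm, b$fpkm)
  expect_identical(rb$promoter_msas[names(b$promoter_msas)],
                   b$promoter_msas)
  expect_identical(sort(names(rb$utrs)), sort(names(b$utrs)))
  expect_identical(treeOf(rb$species_tree), treeOf(b$species_tree))
})
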