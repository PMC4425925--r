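test_that("target-site penalties: perfect, positional mismatch, wobble", {
  mir <- "UGGAGAAGCAGGGCACGUGCA"           # 21 nt
  site <- revComp(gsub("U", "T", mir))
  expect_equal(scoreTargetSite(mir, site), 0)
  # mismatch opposite miRNA position 5 costs 2 (doubled 5' region);
  # site position pairing miRNA pos k (ungapped) is len - k (0-based)
  mutAt <- function(site, k) {
    j <- nchar(site) - k
    b <- substring(site, j + 1, j + 1)
    comp_mir <- b   # current base pairs perfectly; replace by its complement
    repl <- setdiff(c("A", "C", "G", "T"),
                    c(b, chartr("ACGT", "TGCA", b)))[1]
    paste0(substring(site, 1, j), repl, substring(site, j + 2))
  }
  expect_equal(scoreTargetSite(mir, mutAt(site, 5)), 2.0)
  # G:U wobble opposite position 16 costs 0.5 (outside the doubled window)
  # find a position-16 pairing that can be made a wobble
  m16 <- substring(mir, 16, 16)
  j <- nchar(site) - 16
  wob <- if (m16 %in% c("G", "g")) "T" else if (m16 %in% c("U", "T")) "G"
         else NA
  if (!is.na(wob)) {
    s2 <- paste0(substring(site, 1, j), wob, substring(site, j + 2))
    expect_equal(scoreTargetSite(mir, s2), 0.5)
  }
  # G:U at a doubled position costs 1.0
  m5 <- substring(mir, 5, 5)
  if (m5 %in% c("G", "U", "T")) {
    j5 <- nchar(site) - 5
    s3 <- paste0(substring(site, 1, j5),
                 if (m5 == "G") "T" else "G", substring(site, j5 + 2))
    expect_equal(scoreTargetSite(mir, s3), 1.0)
  }
  expect_error(scoreTargetSite("AGX", "TTT"), "nucleotide")
})

test_that("an indel in the site costs the indel penalty", {
  mir <- "UGGAGAAGCAGGGCACGUGCA"
  site <- revComp(gsub("U", "T", mir))
  # delete one site nucleotide pairing the miRNA 3' region (outside the
  # doubled window): best alignment reinstates it as a gap, penalty 2
  s_del <- paste0(substring(site, 1, 2), substring(site, 4))
  expect_equal(scoreTargetSite(mir, s_del), 2.0)
})

test_that("MRE prediction finds a planted perfect site and honours the cutoff", {
  set.seed(61)
  mir <- c(mirX = "ACGGAUGCAUUACGGAUGCAU")
  host <- paste0(paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                       collapse = ""),
                 revComp(gsub("U", "T", mir[[1]])),
                 paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                       collapse = ""))
  m <- predictMres(host, mir, cutoff = 4)
  perfect <- m[m$score == 0, ]
  expect_equal(nrow(perfect), 1L)
  expect_equal(perfect$start, 300)
  expect_equal(perfect$end, 321)
  # cutoff 0 with one planted internal mismatch: empty
  site <- revComp(gsub("U", "T", mir[[1]]))
  b <- substring(site, 11, 11)
  repl <- setdiff(c("A", "C", "G", "T"),
                  c(b, chartr("ACGT", "TGCA", b)))[1]
  host2 <- paste0("AAAAA", substring(site, 1, 10), repl,
                  substring(site, 12), "AAAAA")
  expect_equal(nrow(predictMres(host2, mir, cutoff = 0)), 0L)
})

test_that("MRE prediction equals the all-offsets brute-force scorer", {
  set.seed(62)
  host <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                collapse = "")
  mirs <- c(m1 = "UGGAGAAGCAGGGCACGUGCA",
            m2 = paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
                       collapse = ""))
  # plant a near-perfect site so the comparison covers hits, overlaps
  # and the empty case alike
  host <- paste0(host, revComp(gsub("U", "T", mirs[["m1"]])), host)
  got <- predictMres(host, mirs, cutoff = 4)
  want <- bruteForceMres(host, mirs, cutoff = 4)
  expect_equal(got[order(got$mirna, got$start), ],
               want[order(want$mirna, want$start), ],
               ignore_attr = TRUE)
})

test_that("homology exclusion drops group members and aligned sequences", {
  groups <- list(g1 = list(rice = "rice_a", maize = "maize_a"))
  set.seed(63)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                  replace = TRUE), collapse = "")
  relic <- rnd(300)
  expect_false(excludeHomologs("g1", "maize_a", relic, rnd(300), groups))
  expect_true(excludeHomologs("g1", "other", relic, rnd(300), groups))
  # partner carrying a 150-nt copy of the relic: dropped
  partner <- paste0(rnd(50), substring(relic, 50, 199), rnd(50))
  expect_false(excludeHomologs("g1", "other", relic, partner, groups))
})

test_that("decoy calls need a shared MRE, homology clearance and positive correlation", {
  set.seed(64)
  n <- 9
  mk <- function(mu) 2^(mu + rnorm(n))
  relic_mres <- data.frame(host = c("relicA", "relicA"),
                           mirna = c("mir1", "mir2"), start = 0, end = 21,
                           score = 0)
  utr_mres <- data.frame(host = c("geneUp", "geneAnti", "geneHom"),
                         mirna = c("mir1", "mir1", "mir2"), start = 0,
                         end = 21, score = 0)
  base <- rnorm(n)
  fpkm <- rbind(relicA = 2^(3 + base),
                geneUp = 2^(3 + 0.97 * base + 0.1 * rnorm(n)),
                geneAnti = 2^(3 - base),
                geneHom = 2^(3 + base),
                geneNoMre = 2^(3 + base))
  colnames(fpkm) <- paste0("s", 1:n)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                  replace = TRUE), collapse = "")
  relic_seq <- c(relicA = rnd(300))
  utr_seqs <- list(geneUp = rnd(200), geneAnti = rnd(200),
                   geneHom = paste0(substring(relic_seq, 1, 150), rnd(50)))
  calls <- callCerna(relic_mres, utr_mres, fpkm,
                     groups = list(), relic_groups = c(relicA = "g9"),
                     relic_seqs = relic_seq, utr_seqs = utr_seqs)
  expect_true(calls$called[calls$gene == "geneUp"])
  expect_false(any(calls$called[calls$gene == "geneAnti"]))
  # homologous partner is never tested
  expect_false("geneHom" %in% calls$gene)
  # genes without a shared MRE are never tested
  expect_false("geneNoMre" %in% calls$gene)
  # output carries the five reported fields
  expect_true(all(c("relic", "mirna", "group", "gene", "r", "q") %in%
                    colnames(calls)))
})
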