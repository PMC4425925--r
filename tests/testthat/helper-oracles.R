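## Independent oracles and shared fixtures for the test suite. Every
## oracle re-derives its answer by a different route (brute force,
## enumeration, closed form) from the implementation it checks.

grassTree <- function(unit = "Myr") defaultSpeciesTree(unit)

## ---- Dollo oracle: enumerate all loss-branch subsets -----------------
## A subset of edges is a valid Dollo explanation when, assuming a single
## gain at the MRCA of present leaves, exactly the absent-below-origin
## leaves are covered by the chosen (disjoint) loss edges.
bruteForceDollo <- function(pattern, stree) {
  tr <- treeOf(stree)
  present <- names(pattern)[pattern]
  if (length(present) == 0L) stop("all-absent")
  below <- lapply(seq_len(length(tr$tip.label) + tr$Nnode), function(nd) {
    if (nd <= length(tr$tip.label)) return(tr$tip.label[nd])
    ape::extract.clade(tr, nd)$tip.label
  })
  origin <- if (length(present) == 1L) match(present, tr$tip.label)
            else ape::getMRCA(tr, present)
  in_origin <- below[[origin]]
  must_cover <- setdiff(in_origin, present)
  if (!length(must_cover)) return(0L)
  # candidate loss edges: any edge within the origin subtree whose leaf
  # set is entirely absent
  cand <- Filter(function(lv) all(lv %in% must_cover),
                 lapply(tr$edge[, 2], function(nd) below[[nd]]))
  cand <- Filter(function(lv) all(lv %in% in_origin), cand)
  best <- Inf
  n <- length(cand)
  for (mask in seq_len(2^n) - 1L) {
    sel <- cand[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    lv <- unlist(sel)
    if (anyDuplicated(lv)) next
    if (setequal(lv, must_cover)) best <- min(best, length(sel))
  }
  as.integer(best)
}

## ---- frameshift-DP oracle: top-down recursion over the same move set --
## Independent implementation: memoised suffix recursion with explicit
## gap states, written against the documented move set rather than the
## C++ matrices.
oracleAlignScore <- function(prot, dna, gap_open = 11, gap_ext = 1,
                             fs_pen = 15, stop_pen = 10) {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  SM <- BLOSUM62
  sub <- function(a, b) {
    if (!(a %in% rownames(SM)) || !(b %in% colnames(SM))) return(min(SM))
    SM[a, b]
  }
  gc <- Biostrings::GENETIC_CODE
  trans <- function(s) {
    if (grepl("[^ACGT]", s)) return("X")
    unname(gc[[s]])
  }
  m <- nchar(prot); n <- nchar(dna)
  P <- strsplit(prot, "")[[1]]; D <- strsplit(dna, "")[[1]]
  fsScore <- function(aa, jend, k) {
    best <- -Inf
    B <- c("A", "C", "G", "T")
    if (k == 1) {
      for (b2 in B) for (b3 in B) {
        t <- trans(paste0(D[jend], b2, b3))
        if (t != "*") best <- max(best, sub(aa, t))
      }
    } else if (k == 2) {
      for (b3 in B) {
        t <- trans(paste0(D[jend - 1], D[jend], b3))
        if (t != "*") best <- max(best, sub(aa, t))
      }
    } else {
      for (off in 0:(k - 3)) {
        p <- jend - k + off
        t <- trans(paste0(D[p + 1], D[p + 2], D[p + 3]))
        if (t != "*") best <- max(best, sub(aa, t))
      }
    }
    if (!is.finite(best)) best <- min(SM)
    best
  }
  memo <- new.env(parent = emptyenv())
  # best score of an alignment ENDING at (i, j) in the given state
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (state == "M") {
      if (i == 0) 0
      else {
        best <- -Inf
        aa <- P[i]
        for (k in 1:5) {
          if (j < k) next
          sc <- if (k == 3) {
            t <- trans(paste0(D[j - 2], D[j - 1], D[j]))
            if (t == "*") -stop_pen else sub(aa, t)
          } else fsScore(aa, j, k) - fs_pen
          pre <- max(rec(i - 1, j - k, "M"), rec(i - 1, j - k, "Ix"),
                     rec(i - 1, j - k, "Iy"), 0)
          best <- max(best, pre + sc)
        }
        best
      }
    } else if (state == "Ix") {
      if (i == 0) -Inf
      else max(rec(i - 1, j, "M") - gap_open, rec(i - 1, j, "Ix") - gap_ext)
    } else {
      if (j < 3) -Inf
      else max(rec(i, j - 3, "M") - gap_open, rec(i, j - 3, "Iy") - gap_ext)
    }
    memo[[key]] <- res
    res
  }
  best <- 0
  for (i in 0:m) for (j in 0:n)
    best <- max(best, rec(i, j, "M"))
  best
}

## ---- Fisher one-sided oracle: direct hypergeometric tail sum ----------
hypergeomTailP <- function(a, b, c, d) {
  # P(X >= a) where X ~ Hypergeom(white = a+b, black = c+d, drawn = a+c)
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  sum(dhyper(xs[xs >= a], m, n, k))
}

## ---- BH reference step-up --------------------------------------------
bhStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

## ---- Fitch oracle: enumerate internal-node state assignments ----------
bruteForceFitch <- function(tr, states) {
  n_tip <- length(tr$tip.label)
  n_node <- tr$Nnode
  alph <- unique(unlist(states))
  combos <- do.call(expand.grid,
                    c(rep(list(alph), n_node), stringsAsFactors = FALSE))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    assign_all <- c(unlist(states[tr$tip.label]), unlist(combos[r, ]))
    subs <- 0L
    for (k in seq_len(nrow(tr$edge)))
      if (assign_all[tr$edge[k, 1]] != assign_all[tr$edge[k, 2]])
        subs <- subs + 1L
    best <- min(best, subs)
  }
  as.integer(best)
}

## ---- MRE brute-force scorer ------------------------------------------
bruteForceMres <- function(host, mirnas, cutoff = 4) {
  host <- toupper(host); n <- nchar(host)
  out <- list()
  for (mid in names(mirnas)) {
    L <- nchar(mirnas[[mid]])
    cand <- list()
    for (w in (L - 2):(L + 2)) {
      if (w < 1 || w > n) next
      for (s in 0:(n - w)) {
        sc <- scoreTargetSite(mirnas[[mid]], substring(host, s + 1, s + w))
        if (sc <= cutoff)
          cand[[length(cand) + 1L]] <- data.frame(
            mirna = mid, start = s, end = s + w, score = sc)
      }
    }
    if (!length(cand)) next
    cd <- do.call(rbind, cand)
    cd <- cd[order(cd$score, cd$start, cd$end - cd$start), , drop = FALSE]
    keep <- logical(nrow(cd))
    for (i in seq_len(nrow(cd)))
      if (!any(keep & cd$start[i] < cd$end & cd$start < cd$end[i]))
        keep[i] <- TRUE
    cd <- cd[keep, , drop = FALSE]
    out[[length(out) + 1L]] <- cd[order(cd$start), , drop = FALSE]
  }
  if (!length(out))
    return(data.frame(mirna = character(), start = numeric(),
                      end = numeric(), score = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## ---- deterministic sequence helpers -----------------------------------
randomCds <- function(n_codons, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(as.vector(outer(bases, bases, paste0)),
                            bases, paste0))
  codons <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  paste0("ATG", paste(sample(codons, n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}

translateCds <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  sub("\\*.*$", "", aa)
}

revComp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## ---- shared, lazily computed pipeline run -----------------------------
.shared <- new.env(parent = emptyenv())

sharedBundle <- function() {
  if (is.null(.shared$bundle)) .shared$bundle <- simulateBundle(seed = 11)
  .shared$bundle
}

sharedResult <- function() {
  if (is.null(.shared$result)) .shared$result <- runPipeline(sharedBundle())
  .shared$result
}
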