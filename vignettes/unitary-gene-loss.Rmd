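---
title: "Discovering unitary gene loss and characterizing relics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering unitary gene loss and characterizing relics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneRelics)
```

## The problem

A *unitary gene loss* is the loss of coding potential of a gene that has
no surviving duplicate in the same genome: point mutations or deletions
disable the single functional copy, leaving the function unreplaced.
geneRelics implements a discovery-and-characterization pipeline for such
events in a comparative genomics design modelled on the grasses: four
ingroup species (brachypodium, rice, sorghum, maize) and three distant
outgroups (Arabidopsis, poplar, grape). Presence of orthologs in all
outgroups establishes a gene as *long-established* (conserved for over
160 million years), so its absence in a single ingroup lineage is
parsimoniously read as a loss there rather than a gain elsewhere.

The genomic scar of a loss — the *relic* — may or may not still be
detectable. The pipeline therefore splits candidates into
*relic-retaining* events (a homologous intergenic remnant carrying at
least one ORF-disrupting lesion, or *disabler*: a premature stop codon
or a frameshift-inducing indel) and *relic-lacking* events (no genomic
trace; the expected locus is instead pinned down by synteny and must be
free of annotation and assembly gaps). Downstream, relics are
characterized: lineage gene-death rates, GO slim enrichment of the lost
functions, expression vetting against the surviving orthologous
counterparts, promoter-conservation scoring, and identification of
expressed relics acting as microRNA decoys (ceRNAs).

## Loss calling: Dollo parsimony with an outgroup constraint

Each ortholog group yields a presence/absence pattern over the seven
species (presence = at least one annotated gene; how paralog
multiplicity should enter presence calling is not obvious, and "at least
one" is the conservative choice). Under the Dollo model the gene
originates exactly once, at the most recent common ancestor of the
present species, and absences below that origin are explained by losses
of whole clades. `dolloMinLosses()` returns the minimal number of loss
branches and their placement: the set of maximal all-absent clades
inside the origin subtree. A candidate event requires (i) every outgroup
present and (ii) a single loss branch inside the ingroup. Events on
internal ingroup branches (a loss shared by sister species) are emitted
and labelled with the clade. Loss counting is unweighted — no
branch-length rates are invented — and the caller is verified against a
brute-force enumeration of all loss-branch subsets on all 127 patterns
of the 7-leaf tree.

Groups whose counterparts are tagged as transposable elements or
mitochondrial/chloroplast-related are removed before any sequence work;
tags are matched case-insensitively against a configurable keyword list
(`transposable`, `transposon`, `mitochondri`, `chloroplast`), since the
categories are standard but no exact matching rule is.

## Finding relics: a frameshift-aware protein-to-DNA alignment

The counterpart protein from the phylogenetically nearest species with a
surviving gene is aligned against the losing genome. The aligner is a
local (Smith-Waterman-style) dynamic program in protein x nucleotide
space: a residue may consume a normal codon (BLOSUM62 score), or a
frameshifted codon of 1, 2, 4 or 5 nt at a frameshift penalty (default
15, scored against the best non-stop completion or in-register triplet,
so a 1-2 nt indel in either direction is a single lesion); in-frame
stop codons inside the alignment are retained at a stop penalty (default
10) rather than terminating it; gaps are affine (open 11, extend 1).
These defaults sit in the family of classical protein-to-genome aligner
settings and are all exposed. Introns are deliberately not modelled:
relics decay without splicing pressure, and a spliced aligner would add
machinery the synthetic evaluation cannot exercise. The DP is checked
against an independent recursion oracle on small inputs.

Candidate loci come from a seed-and-extend pre-filter (exact protein
5-mers against the six-frame translation), each refined by the DP. Hits
below score 100 or query coverage 0.4 are discarded — far above the
score of chance local alignments in random sequence, far below a true
remnant. Classification follows a strict precedence: any hit overlapping
an annotated gene removes the candidate (likely an annotation gap, not a
loss); otherwise a disabler-free intergenic hit with coverage >= 0.8
removes it as an intact ORF (the coverage floor stops short clean
fragments from being called intact genes); otherwise a
disabler-harbouring intergenic hit makes the event relic-retaining, and
the best-scoring such hit becomes the relic locus.

A caveat worth stating: a lesion in the first few codons of a remnant is
genuinely confoundable with alignment trimming — a local alignment may
prefer to start just downstream of a 5'-terminal frameshift rather than
pay its penalty. The synthetic generator therefore plants lesions at
least 6 codons from the 5' end and 8 from the 3' end; on real data,
lesions at the extreme ends of a remnant would be under-detected.

## Synteny validation of hit-less candidates

Candidates with no genomic hits are located by projection: in each
source species holding a counterpart, the nearest anchored genes up- and
downstream of the counterpart (within a 20-gene window; synteny tables
give anchors, not a search rule, so the window is ours) are mapped
through their anchor partners, and the target locus is the span between
the partners. Sources must agree — same chromosome, pairwise-overlapping
intervals — and the reported locus is the intersection; a single
consistent source suffices by default (requiring all neighbours would
discard candidates near block boundaries). The locus is accepted as
relic-lacking only if it overlaps no annotation and no assembly gap
(N-runs of >= 10 detected from the FASTA itself, plus any explicit gap
records); otherwise the event is synteny-rejected with the reason.

## Rates and enrichment

The gene death rate of a lineage is V_D = (species-specific events) /
(time since the latest divergence), in events per Myr; display rounds
half-up to one decimal while computation keeps full precision (half-up
matches how such tables are conventionally printed; banker's rounding
would disagree at .x5 values). Lost-gene function is annotated by the
union of the Arabidopsis counterparts' GO slim terms, and per-species
enrichment uses a one-sided Fisher's exact test (over-representation
only is asked) against the species' annotated background, with
Benjamini-Hochberg correction across the term family (every term with a
background gene); FDR methods are pluggable, BH being the standard
default when none is named.

## Expression vetting of relics

A relic counts as expressed when FPKM exceeds 1 in at least one sample
(strictly greater). Tissue specificity is max(row)/sum(row). Relic
versus counterpart comparisons use the two-sided Wilcoxon signed-rank
test on one summary per pair — mean log2(FPKM+1) for level,
tissue specificity for breadth — with the exact null for up to 25
untied pairs and the continuity-corrected normal approximation above;
all-zero difference sets return p = 1 by convention. Per-pair summaries
are used rather than per-sample values so each relic-counterpart pair
contributes one datum.

Two screens separate "functional" from "leaky" transcription. First,
expression-pattern similarity: Pearson R on log2(FPKM+1) across samples,
p from the t transform on n-2 df, BH across pairs; a relic with R > 0.6
and q < 0.05 tracks its counterpart too closely and is suspected of
residual promoter activity. Pairs whose counterpart is itself
unexpressed are `not_testable` and stay in the relic set (they skip the
test, they are not excluded by it). The corrected threshold is primary
throughout; where a display-level convention would use uncorrected
p < 0.05 both values are reported. Second, promoter conservation
(below). Expressed relics surviving both screens are the *reliable
expressed relics*.

When no external differential-expression q-values are supplied, a
fallback test is used and labelled as such: per sample pair, per-locus
differences of log2(FPKM+1) standardized by a robust pooled dispersion
(MAD across loci) and referred to the normal, BH across loci, DE if any
pair reaches q < 0.05. It is a deliberately simple stand-in for a
replicate-aware negative-binomial model and is calibrated under label
permutation in the test suite.

## Promoter conservation

The putative promoter is the up-to-2-kb intergenic interval immediately
5' of the locus, strand-aware, truncated at the nearest upstream gene.
Conservation is scored in the rejected-substitutions style: per
alignment column, RS = N - observed, where N is the branch-length sum of
the substitutions/site tree pruned to the column's ungapped species
(fewer than 3 ungapped species makes a column uninformative) and the
observed count is the Fitch parsimony minimum. Parsimony counting is a
deterministic, oracle-checkable stand-in for a maximum-likelihood rate
estimate; the interface keeps the estimator pluggable, and RS <= N
always holds with equality exactly at monomorphic columns. Each relic's
per-column RS distribution is tested one-sided (greater) against the
pooled column distribution of protein-coding promoters by Wilcoxon
rank-sum with BH across relics; one-sided because only *more* conserved
promoters argue for the leaky-promoter explanation. The significance
level defaults to 0.05 and is configurable.

## ceRNA decoy calling

MicroRNA response elements are scored by a penalty alignment in the
plant target-recognition style: the miRNA (5'->3') is globally aligned
to the reverse of the site; Watson-Crick pairs are free, G:U wobbles
cost 0.5, mismatches 1, indels 2, and every penalty doubles at miRNA
positions 2-13, the functionally critical 5' window (bounds
configurable). Sites scoring <= 4 are reported, best-scoring site per
miRNA among overlapping candidates (leftmost on ties). Free-energy
criteria are intentionally out of scope; the positional penalty score
alone decides. Because the penalty weights are positional, the score is
not invariant under reverse-complementing both sequences — the 5'
window moves — so the suite pins positional behaviour with explicit
examples instead of asserting that symmetry.

A decoy call requires: a reliable expressed relic and a protein-coding
gene sharing an MRE for the same miRNA (relic searched over its full
transcript, gene over its 3' UTR only); no homology between them
(partner in the relic's own ortholog group, or local alignment at >= 60%
identity over >= 100 nt, disqualifies the pair — shared sites must not
be explained by common descent); and significantly positive
co-expression (one-sided Pearson on log2(FPKM+1), BH across tested
pairs, R > 0 and q < 0.05). Sharing is interpreted as "both carry a
passing site for the same miRNA"; site-sequence identity is not
additionally required.

## The synthetic generator and what passing means

`simulateBundle()` emits a complete, internally consistent input bundle
with known truth: seven small genomes (one chromosome each, ~100-codon
genes spaced 400 bp apart), annotations, ortholog tables, synteny
anchors consistent with gene order, log-normal FPKM matrices over the
nine-tissue sample design, promoter alignments, and miRNA/UTR/relic
sequences. Planted classes cover every pipeline branch: relic-retaining
losses (mutated CDS left unannotated), relic-lacking losses (CDS
excised), contaminant groups (counterpart tagged as a transposable
element), genic-hit and intact-ORF decoys, gap-rejected loci (N-runs),
unexpressed relics, leaky relics (expression profile copied from the
counterpart), one conserved-promoter relic (rate multiplier 0), decoy
pairs (shared planted MRE plus correlation 0.95), and ceRNA distractors
(site without correlation, correlation without site, homologous
partner).

Planted correlations are imposed by empirical construction, so the
realized latent sample correlation equals the target exactly; planted
zero correlations are likewise exact, which is what makes "0 false
positives" a deterministic claim rather than an alpha-level gamble.
Non-conserved relic promoters evolve at 1.25x the neutral rate —
degenerating faster than functional promoters, which is the expected
biology of a dead locus — so the conservation screen's negatives are
genuine negatives. Promoter evolution is Jukes-Cantor substitution only
(per-branch site substitution probability 1 - exp(-(4/3) m t)); no
indels, no rate heterogeneity. Expression is log-normal with latent sd
0.8 and planted fold changes of 5 log2 units; real RNA-seq has
count-level noise, replicate structure and zero inflation that this
model does not attempt.

Problem sizes are chosen so the full pipeline runs in well under a
minute per bundle: 50 ortholog groups, 10 planted losses, 500-column
promoter alignments, 40 background promoters per species, 9 samples. A
single master seed drives every sub-generator through a documented
splitting scheme, making bundles byte-reproducible.

Passing the planted-truth suite shows the machinery is correct and the
thresholds behave as designed under the generator's assumptions —
near-identical cross-species sequence, clean annotations, normal
log-expression. It does not show that the defaults are tuned for real
grass genomes, where divergence, paralogy, fragmented assemblies and
expression noise all bite; every threshold is therefore surfaced in
`pipelineConfig()`.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open internally, converted only at the
GFF3 boundary. An all-absent presence pattern is an error (no single
origin exists). Zero-variance expression rows are `not_testable` for
correlation and skipped (with a flag) in decoy testing. A zero-length
promoter (locus abutting its neighbour) is flagged and excluded. Ties
among equally-scoring MRE sites break leftmost; ties among minimal
Dollo placements cannot arise for clade-shaped absences on a binary
tree but are guarded. Reported rates and ratios round half away from
zero; all statistics are computed unrounded.
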