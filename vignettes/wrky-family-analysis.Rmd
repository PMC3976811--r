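---
title: "Methods: genome-wide WRKY family analysis with wrkyscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide WRKY family analysis with wrkyscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkyscan)
```

## The analysis

WRKY transcription factors are one of the largest plant transcription
factor families. A WRKY gene is defined by its ~60-residue DNA-binding
domain: the near-invariant heptapeptide **WRKYGQK** followed by a
metal-chelating zinc finger. The family is classified by domain count
and finger chemistry: group I proteins carry two domains; group II one
domain with a C2H2 finger (`C-X(4,5)-C-X(22,23)-H-X-H`); group III one
domain with a C2HC finger (`C-X(5,8)-C-X(25,28)-H-X(1,2)-C`). Group II
subdivides into subgroups IIa-IIe (plus a provisional IIx for members
that cluster with no reference subgroup).

`wrkyscan` re-implements, as one testable pipeline, the family-level
analyses typically run after a genome release:

1. **Domain mining and classification** — a deterministic sequence
   grammar (not a profile HMM) scans proteins for heptapeptide variants
   and downstream zinc fingers, classifies groups/subgroups, filters
   weak candidates, and flags pseudogenes from the CDS.
2. **Genomic organization** — tandem/segmental duplication calls under
   the 70/70 rule and 200-kb gene-cluster calls.
3. **Gene structure** — intron phases and conserved R-/V-type intron
   typing inside the domain.
4. **Phylogenetics** — Poisson/p distances, Neighbor-Joining, bootstrap
   supports, and a small progressive aligner.
5. **Selection** — GY94 codon site models M0/M3/M7/M8, likelihood-ratio
   tests, and naive empirical Bayes (NEB) positive-site posteriors.

A curated table of the 71 *Lotus japonicus* WRKY family members
(`load_ljwrky_table()`) anchors the family-level numbers, and a
synthetic-genome generator (`generate_genome()`) provides complete
planted ground truth so every stage is testable offline.

## The domain grammar

The heptapeptide pattern is `W[RKLSV][RKC]YG[QYELK]K`: the union of the
named natural variants (WRKY, WRRY, WSKY, WKRY, WVKY, WKKY) and the
single-residue substitutions observed in this family (R→K/L, K→C,
Q→Y/E/L/K). For each heptapeptide match the nearest downstream zinc
finger **starting within 50 residues** is attached; C2H2 is tried before
C2HC when both could match. The 50-residue window and the C2H2
precedence are this package's choices — the family literature states the
finger spacings but neither a search window nor a precedence rule.

Classification rules:

* two heptapeptide matches with ≥1 complete domain → **group I**
  (a group I gene with a degenerate C-terminal domain is *retained*,
  mirroring how such genes are treated in family surveys);
* one complete domain → **group II** (C2H2) or **group III** (C2HC);
* anything else → unclassified, and the candidate filter drops genes
  whose best complete domain spans under 40 residues (two thirds of the
  canonical ~60-aa domain).

Subgroup assignment uses the nearest labeled reference domain by
p-distance on a global alignment, ties broken by reference order, with
queries beyond a 0.6 p-distance of every reference labeled `unplaced`.
This is a deterministic, testable proxy for the customary
phylogeny-based assignment; users who want tree placement can build the
domain tree with `progressive_align()` + `bootstrap_support()`. The
observed finger spacings (e.g. `CX4CX22HXH`) are exposed by
`zinc_finger_spacing()` as a diagnostic only — spacing classes overlap
between subgroups, so they are never used for classification.

**Pseudogene** operationalization: `premature_stop` is any in-frame stop
codon before the final codon; `frameshift` is a CDS length not divisible
by 3. No alignment to an intact paralog is attempted — the package has
no procedure for locating the lesion, only for flagging it.

## Genomic organization

Two genes are **duplicates** when the alignable nucleotide sequence
covers more than 70% of the longer CDS *and* amino-acid identity
exceeds 70% — both strict inequalities (a pair at exactly 0.70 fails).
Same-chromosome pairs are tandem; everything else segmental; pairs with
an unplaced member cannot be called tandem and are labeled segmental
with a caveat flag. Alignments are global Needleman–Wunsch: BLOSUM62
with gap open 10 / extend 1 for proteins, match +2 / mismatch −3 with
gap open 5 / extend 2 for nucleotides. These scoring parameters are the
package's defaults (the duplication thresholds, not borderline scores,
decide the calls).

A **gene cluster** is ≥2 genes within 200 kb, implemented as
single-linkage chaining on each gene's representative coordinate:
consecutive genes on a chromosome join one cluster while the gap stays
≤ 200 kb. Chaining is the only reading consistent with a one-coordinate-
per-gene table; it is order-independent, partitions the genes, and is
monotone in the window. On the packaged *L. japonicus* table this rule
yields **4 clusters over 9 genes** (one each on chromosomes 1, 2, 4
and 5; the three neighbors on chromosome 2 chain into a single
3-member cluster; none on chromosomes 3 or 6). The pipeline log records
this per-chromosome breakdown alongside the cluster report.

## Gene structure

Intron phase is the cumulative coding length upstream of the junction
mod 3. Two conserved introns recur in WRKY domains:

* **R-type** — phase 2, splitting a codon that encodes R between the
  heptapeptide and the first zinc-finger cysteine. When several R
  codons precede the finger, any of them qualifies (the package checks
  the actual split codon, so ambiguity never arises in practice).
* **V-type** — phase 0, immediately before the codon six residues after
  the second cysteine of a **C2H2** finger (the position usually
  occupied by V). C2HC (group III) domains can only host R-type or
  untyped introns.

For two-domain (group I) proteins every complete domain is checked;
the conserved intron of such genes sits in the C-terminal domain. The
exon container holds *coding* exons only, so UTR structure never
affects phases.

## Phylogenetics

`p_distance()` offers p and Poisson-corrected (−ln(1−p)) protein
distances with pairwise deletion of gaps; Poisson is the default (the
distance model behind published NJ trees of this family is typically
unstated; both are offered). `nj_tree()` is a from-scratch Saitou–Nei
implementation with two determinism policies: Q-criterion ties break to
the smallest (i, j) index pair, and a negative branch length is clamped
to zero with the deficit moved to the sister branch (their sum — the
joined distance — is preserved). NJ's exact recovery of additive
(four-point-condition) distances is the primary oracle: 100 random
6-taxon additive matrices are recovered perfectly in the test suite.

`bootstrap_support()` resamples alignment columns with replacement
(1000 replicates by default, per the field's convention), rebuilds the
NJ tree, and reports the percentage of replicates containing each
bipartition of the full-data tree. Supports are attached to the one
full-data tree; no majority-rule consensus is constructed.

`progressive_align()` is intentionally basic: an identity-based UPGMA
guide tree and profile–profile Needleman–Wunsch merges (mean BLOSUM62
column score, linear gap penalty 8). It is meant for the short, highly
conserved domain sequences this pipeline aligns, not as a general
aligner.

## Codon site models

The GY94 rate matrix over the 61 universal-code sense codons sets
`q_ij = 0` for multi-nucleotide changes and
`q_ij = π_j · κ^[transition] · ω^[nonsynonymous]` otherwise. A single
matrix is normalized to one expected substitution per codon per unit
time; for site mixtures the *mixture-averaged* rate is normalized
(the convention of standard codon-model software), and the simulator
shares the convention, so branch lengths mean the same thing
everywhere. Codon frequencies default to F3x4 (data-estimated
positional nucleotide frequencies), with any frequency floored at
1e-10; F61-style custom frequencies can be passed explicitly.
Stop-containing codons are rejected at load — consistent with
pseudogene exclusion upstream.

Model fitting (`fit_site_model()`):

* **M0** — joint L-BFGS-B over log κ, log ω and all log branch
  lengths; three fixed starting points; bounds κ ∈ [0.1, 20],
  ω ∈ [1e-4, 50], t ∈ [1e-6, 20].
* **M3 (K = 3)** — ω classes parameterized as a base value plus
  non-negative increments (no label switching), weights by softmax.
* **M7** — beta(p, q) discretized into 10 equal-probability categories
  (category means at the quantile midpoints); p, q ∈ [0.05, 99].
* **M8** — the M7 categories at weight p0 plus one selection class with
  ω_s ∈ [1, 50] at weight 1 − p0.

For the mixture models the default keeps the M0-fitted branch lengths
up to one free scale multiplier while κ and the ω-distribution are
optimized (`optimize_branches = TRUE` restores the full joint fit).
This is a deliberate design choice: with numeric gradients the full
joint mixture fit costs several times more for negligible likelihood
gain at the alignment sizes this package targets, and every mixture fit
*starts from the nested null's optimum* (M3 from M0, M8 from M7 with
p0 = 1), so the nesting inequalities lnL(M3) ≥ lnL(M0) and
lnL(M8) ≥ lnL(M7) hold by construction, not just asymptotically.
Convergence is the optimizer's relative-improvement criterion
(factr = 1e8); a fit whose total tree length collapses to ~0 is
flagged as ω-unidentifiable rather than failing silently.

`lrt()` supports the two customary nested pairs — M0 vs M3 (df = 4) and
M7 vs M8 (df = 2) — with slightly negative statistics clamped to zero.
Positive-site identification is **NEB**: per-site posteriors over the
mixture classes at the MLEs, reporting sites whose ω > 1 class
posterior exceeds 0.95. NEB is the documented approximation to the
Bayes empirical Bayes procedure; BEB's integration over parameter
priors is out of scope here, and the family-level conclusion this
machinery supports (purifying selection, at most isolated positive
sites) is threshold-level, not sensitive to the difference.

The likelihood itself (Felsenstein pruning with per-node column
rescaling) is verified in the tests against an independent
matrix-exponential oracle to 1e-8 on 2–3-taxon instances, and the
pulley principle (re-rooting invariance under a reversible model) is
asserted directly.

## The synthetic genome: what it emulates, and what it does not

`generate_genome()` builds a gene family from hand-written,
grammar-conformant domain templates (one per class; synthetic sequences,
not real genes) embedded in random background drawn from a 17-letter
alphabet without W, C or H — so the planted domains are provably the
only grammar matches, and a rejection loop re-draws any gene whose
frameshift-garbled tail would change its expected call. Default
parameters are the study conditions the package is tested under:
61 genes split 12/5/8/13/5/9/2/7 across groups, 10 structurally
defective candidates, 9 pseudogenes (premature stops and 1-nt
frameshifts planted in the C-terminal tail), 48 genes placed
14/8/4/13/5/4 on chromosomes 1–6, sub-200-kb clusters on chromosomes
1/2/4/5, one 90%-identity tandem pair, and R-/V-type introns (R in
Ic/IIc/IId/IIe/III, V in IIa/IIb, none in In/IIx) with lengths around
600 bp — the reported average for conserved WRKY introns in this
genome.

What passing on this genome shows: the scanner, classifier, filter,
pseudogene flags, duplication and cluster callers, and intron typer are
*internally consistent* with the family's published architecture and
recover planted truth exactly. What it does not show: robustness to
real-genome phenomena the generator deliberately omits — profile-level
domain divergence beyond the grammar, alternative splicing, assembly
gaps, repeats, GC heterogeneity, and codon usage bias (the fixed
back-translation table means real CDS variation is understated).
Real-data classification should therefore be read as grammar-based
screening, not as a replacement for profile-HMM searches.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 100 random 6-taxon
additive matrices for NJ consistency; 300–1000 bootstrap replicates;
M0 recovery at 8 taxa × 500 codons (ω = 0.3, κ = 2); the full
M0/M3/M7/M8 ladder at 5–6 taxa × 120–250 codons. These sizes were
chosen so the whole suite runs comfortably on a single CPU while the
statistical checks (ω̂ within ±0.05 of truth, planted-site recovery,
nesting) remain sharp. Degenerate inputs are handled explicitly:
identical sequences give zero distances (NJ still returns a tree),
saturated pairs (p = 1) are an error under the Poisson correction
naming the pair, and gap-only pairwise comparisons are an error naming
the pair.

## Known limitations

* The domain grammar may over-accept relative to a curated profile HMM;
  it encodes the named variants and substitutions only.
* Subgroup assignment is nearest-reference, not tree placement; the
  packaged references are synthetic templates, so on real data users
  should supply curated reference domains.
* The published total of clustered genes for this genome is not
  reproducible from the printed per-gene coordinates under the printed
  200-kb rule (see the pipeline log); the package reports the
  rule-faithful result.
* BEB, branch models, branch-site models and synonymous-rate variation
  are out of scope; Table-style selection results on real data require
  the underlying sequence sets, which are not distributable here.
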