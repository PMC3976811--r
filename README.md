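# wrkyscan

Genome-wide analysis of the **WRKY transcription factor family** in R.

WRKY proteins are one of the largest plant transcription factor
families, defined by a ~60-residue DNA-binding domain: the conserved
heptapeptide **WRKYGQK** (with natural variants such as WKKY or WRRY)
plus a zinc finger. Family surveys after a genome release all follow the
same recipe — find the domains, classify the genes, map them, look for
duplications and clusters, type the conserved introns, build trees, and
test for selection. `wrkyscan` packages that recipe as composable,
tested functions:

* **Domain mining** — a deterministic grammar: heptapeptide
  `W[RKLSV][RKC]YG[QYELK]K` followed within 50 residues by a
  C2H2 (`C-X(4,5)-C-X(22,23)-H-X-H`) or C2HC
  (`C-X(5,8)-C-X(25,28)-H-X(1,2)-C`) zinc finger. Genes with two
  domains are group I; one domain with C2H2 is group II, with C2HC
  group III; group II subgroups (IIa–IIe, IIx) by nearest reference
  domain. Pseudogenes are flagged from the CDS (premature stop /
  frameshift).
* **Genomic organization** — duplicated pairs under the 70/70 rule
  (nucleotide coverage of the longer CDS > 70% **and** amino-acid
  identity > 70%; same chromosome = tandem, otherwise segmental), and
  gene clusters as ≥2 genes chained within 200 kb.
* **Gene structure** — intron phases from exon coordinates; conserved
  **R-type** (phase 2, splitting an R codon before the finger) and
  **V-type** (phase 0, before the codon at second-C + 6 of a C2H2
  finger) introns.
* **Phylogenetics** — p/Poisson distances, a from-scratch
  Neighbor-Joining implementation with deterministic tie-breaking,
  bootstrap supports, and a small progressive protein aligner.
* **Selection** — GY94 codon models, site models **M0/M3/M7/M8** fitted
  by maximum likelihood (Felsenstein pruning over the 61 sense codons,
  F3x4 frequencies), likelihood-ratio tests (M0 vs M3, df 4; M7 vs M8,
  df 2), and NEB posterior identification of sites with ω > 1.

The package ships a curated table of the **71 WRKY family members of
the *Lotus japonicus* genome** and a synthetic-genome generator with
complete planted ground truth (groups, subgroups, pseudogenes,
duplicate pairs, clusters, intron types), so the entire pipeline runs
and is testable with no downloads.

## Worked example

```r
library(wrkyscan)

# The curated family table: 71 genes, 61 classifiable
tab <- load_ljwrky_table()
summarize_family(tab[tab$group != "nd", ])
#>    I IIa IIb IIc IId IIe IIx III total
#> 1 12   5   8  13   5   9   2   7    61

sum(tab$pseudogene)
#> [1] 9

# Chromosomal organization
loci <- as_loci(tab)
chromosome_distribution(loci)[, 1:2]
#>   chromosome n_genes
#> 1          1      14
#> 2          2       8
#> 3          3       4
#> 4          4      13
#> 5          5       5
#> 6          6       4
#> 7   UNPLACED      23

detect_clusters(loci, window_bp = 200000)
#>   chromosome                    members n_members span_bp
#> 1          1            LjWRKY2,LjWRKY3         2   32212
#> 2          2 LjWRKY17,LjWRKY19,LjWRKY20         3  157942
#> 3          4          LjWRKY34,LjWRKY35         2  129106
#> 4          5          LjWRKY40,LjWRKY41         2   78283
```

Twelve genes carry two WRKY domains (group I), 42 one C2H2-finger
domain (group II, 13 of them in subgroup IIc), 7 one C2HC-finger domain
(group III); 48 genes map to chromosomes 1–6 and 9 are pseudogenes.
Under the 200-kb chaining rule the table yields four clusters over nine
genes — one each on chromosomes 1, 2, 4 and 5, none on 3 or 6; the
chromosome-4 pair (LjWRKY34/35) is also the family's one tandem
duplication.

Synthetic end-to-end run with planted truth:

```r
gen <- generate_genome(synth_config(seed = 42))     # 61 + 10 planted genes
cls <- classify_records(gen$proteins, gen$cds)
flt <- filter_candidates(cls)
summarize_family(flt$kept)
#>    I IIa IIb IIc IId IIe IIx III total
#> 1 12   5   8  13   5   9   2   7    61

detect_duplications(gen$records[!gen$truth$defective])
#>      id_a    id_b nt_coverage aa_identity   mode unplaced_member
#> 1 SYNW027 SYNW028           1         0.9 TANDEM           FALSE
```

Selection machinery on simulated codon data:

```r
tr <- ape::rtree(8, rooted = FALSE)
tr$edge.length <- runif(nrow(tr$edge), 0.1, 0.6)
sim <- simulate_codon_alignment(tr, kappa = 2, omegas = 0.3,
                                n_codons = 500, seed = 101)
fit <- fit_site_model(sim$aln, tr, "M0")
fit$omega_spec$omega   # ~0.29 (true 0.3)
```

A thin command-line front-end over these functions is included at
`inst/scripts/wrkyscan.R` (`fixture`, `simulate`, `pipeline`
subcommands).

## Scope

Profile-HMM scoring, BLAST search, de-novo motif discovery, BEB,
branch/branch-site models and genome download clients are out of scope.
See the methods vignette (`vignettes/wrky-family-analysis.Rmd`) for the
models, numerical choices and known limitations.
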