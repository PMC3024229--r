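# genedup

Census, ancient-origin dating, and selection analysis of duplicated
genes in multi-replicon bacterial genomes.

Many bacteria — classically the purple nonsulfur alpha-proteobacteria
with two chromosomes — carry a substantial load of duplicated genes,
and three questions recur whenever such a genome is analysed. How many
genes exist in two (or more) copies, and how are the pairs distributed
over chromosomes and plasmids and over COG functional categories? Did
each duplication happen before or after the species split from its
relatives? And what selective regime are the surviving pairs under?
`genedup` implements that entire workflow as a tested, reusable R
package, together with a codon-model genome simulator with known
duplication history so every stage can be validated against truth.

## The methods at its core

* **Duplicate census.** An exact affine-gap global alignment kernel
  (Needleman–Wunsch/Gotoh, BLOSUM62, gap open/extend 11/1, in C++)
  drives an all-vs-all protein search. Hits qualify at
  E = *K·m·n·e^(−λS)* ≤ 10⁻²⁰ and percent identity ≥ 30; edges must be
  reciprocal; homolog families are connected components of the
  reciprocal graph, and two-copy families are the duplicate pairs, each
  carrying divergence (100 − identity) and a replicon location class
  (CI-CI, CI-CII, CII-CII, C-P, P-P). COG distributions of the
  duplicated genes are tested against the genome background with a
  chi-square goodness of fit at the general (5 groups) and sub-group
  (25 letters) levels.
* **Quartet dating.** For each pair (P1, P2) plus one ortholog per copy
  (O1, O2), the three unrooted quartet topologies are fit by maximum
  likelihood under the WAG model (Felsenstein pruning, per-branch
  bounded scalar optimization, nonparametric bootstrap over columns).
  Type-A — ((P1,O1),(P2,O2)) or ((P1,O2),(P2,O1)) — means the
  duplication predates speciation; Type-B — ((P1,P2),(O1,O2)) — means
  the copies arose after it.
* **Selection.** Pair members are back-translated to codon alignments;
  Ka, Ks and ω = Ka/Ks are estimated with Nei–Gojobori counting (the
  transparent baseline) and a kappa- and frequency-corrected
  Yang–Nielsen-family method (the headline estimator); ω ≤ 0.3 marks
  purifying, ≥ 3 positive selection. A one-way ANOVA compares ω across
  strains on the pairs retained two-copy everywhere.
* **Strain comparison and HGT.** Each pair's first member is searched
  against related strains' proteomes (match counts 0/1/2/>2 summarize
  loss and retention), and externally predicted horizontal-transfer
  intervals (BED) are merged and intersected with replicons, genes, and
  the duplicate set.

## Worked example

Simulate a 40-family cohort with known history, run the full pipeline,
and compare calls against truth:

```r
library(genedup)

co  <- simulate_cohort(sim_config(n_families = 40, p_loss = 0.15,
                                  seed = 42))
dir <- tempfile(); write_cohort(co, dir)

cfg <- pipeline_config(
  focal       = file.path(dir, "focal"),
  strains     = list(strainA = file.path(dir, "strains", "strainA"),
                     strainB = file.path(dir, "strains", "strainB"),
                     strainC = file.path(dir, "strains", "strainC")),
  ortholog_db = file.path(dir, "ortholog_db"),
  hgt_bed     = file.path(dir, "hgt.bed"),
  out         = file.path(dir, "report"),
  seed        = 7)
cfg$quartet$bootstrap_n <- 20

res <- run_pipeline(cfg)
#> homology: 48 directed hits
#> families: 24 (copy classes 24/0/0/0)
#> pairs: 24 duplicate pairs
#> cog: general chi2 = 0.2433
#> quartets: 24 classified, 0 unresolvable
#> strains: 9 common pairs across 3 strains
#> selection: mean omega = 0.109, ANOVA p = 0.999

table(res$quartets$call)
#>
#> TypeA TypeB
#>    15     9
table(co$truth$type[co$truth$duplicated])
#>
#>  A  B
#> 15  9
```

Twenty-four of the forty families were simulated as duplicated; all
twenty-four pairs are recovered (the copy-class histogram `24/0/0/0`
counts 2/3/4/5+-copy families) with both directed hits per pair. The
quartet stage calls fifteen pairs Type-A and nine Type-B, exactly
matching the simulated pre-/post-speciation truth. Nine pairs are
retained as two copies in every strain; their ω estimates average 0.11
— the purifying regime the simulator draws from (family ω lognormal
with mean 0.13) — and the across-strain ANOVA finds no difference
between strains (p = 0.999), as expected since strains share each
family's true ω. The report directory holds the TSV tables (pairs,
quartets, COG and divergence distributions, match profiles, tree-type
matrix, summary statistics), each stamped with the configuration hash
and master seed.

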