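---
title: "Methods: censusing, dating, and constraining gene duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censusing, dating, and constraining gene duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(genedup)
```

# Scope

`genedup` analyses gene duplication in bacterial genomes that carry more
than one replicon — typically a large chromosome (CI), a second
chromosome (CII), and plasmids. Given a genome bundle (protein FASTA,
CDS FASTA, gene table), related strain bundles, and an ortholog database
of fully sequenced relative species, it answers three questions:

1. **How much duplication is there, and where?** An all-vs-all
   reciprocal protein similarity search yields homolog families; the
   two-copy families are the duplicate gene pairs, classified by
   replicon location and amino-acid divergence, and compared against the
   genome's COG functional background.
2. **How old are the duplications?** For each pair, a four-taxon
   maximum-likelihood tree over the two paralogs and one ortholog per
   copy distinguishes duplications that predate speciation (Type-A:
   each copy groups with its own ortholog) from those that postdate it
   (Type-B: the copies are sisters).
3. **What selection do the pairs experience?** Synonymous and
   nonsynonymous substitution rates per pair, per strain, with a
   one-way ANOVA on omega = Ka/Ks across strains.

A codon-model simulator generates cohorts with known duplication
history so that every stage can be validated against truth.

# Homology search

The alignment kernel is an exact global Needleman–Wunsch/Gotoh dynamic
program with affine gaps (a run of length $k$ costs
`gap_open + k * gap_ext`), BLOSUM62 scoring by default with gap
penalties 11/1. Global (not local) alignment is used deliberately: the
divergence statistic is defined as $100 - $ percent identity of
whole-protein alignments, so one alignment definition serves both
pairing and divergence. Percent identity uses the full alignment length
(gap columns included) as the denominator — the choice is stated because
published analyses rarely pin it down, and it is the conservative
option. Traceback ties break deterministically (paired column, then a
column consuming the first sequence, then the second), so outputs are
bit-stable.

Raw scores are converted to expectation values with the Karlin–Altschul
form $E = K m n e^{-\lambda S}$ using the published gapped-BLOSUM62
constants $\lambda = 0.267$, $K = 0.041$; these are configuration
values, not re-estimated. Hits qualify at $E \le 10^{-20}$ and identity
$\ge 30\%$, the threshold above which bacterial gene duplication is
considered reliably detectable. An edge survives only when the hit
qualifies in both directions; homolog families are the connected
components of the reciprocal graph (the transitive-closure rule is a
design choice — multi-copy classes are reported but no finer clustering
is defined). Curated pairs below threshold can be forced in via
`call_duplicate_pairs(..., forced_pairs = )`.

# Quartet dating

For each pair the best ortholog per paralog is selected from the
database by lowest $E$, then highest score; when both paralogs hit the
same database sequence — the expected situation for a post-speciation
duplication — the paralog with the weaker score is reassigned to its
next-best distinct ortholog. If two distinct orthologs cannot be found
the pair is reported `unresolvable` rather than guessed.

The four protein sequences are aligned by deterministic progressive
alignment (pairwise global distances, average-linkage guide tree,
profile–profile alignment with the same affine kernel). The three
unrooted quartet topologies are then fit under the WAG amino-acid model
(single rate category; the empirical exchangeabilities and frequencies
are embedded in the package and checked in tests for detailed balance
and unit expected rate). Likelihood uses Felsenstein pruning with gaps
marginalized as missing data. Branch lengths are optimized
coordinate-wise by bounded scalar search on $[10^{-8}, 10]$
substitutions/site, cycling until the per-cycle log-likelihood gain
falls below $10^{-6}$ (at most 50 cycles). Ties between topologies
(within $10^{-6}$) break toward the Type-A topologies in a fixed order,
and the tie is flagged.

Both non-sister-paralog topologies count as Type-A: the binary
age-class question only asks whether the paralogs are sisters.
Bootstrap support resamples alignment columns with replacement
(default 100 replicates), refits all three topologies per replicate
(warm-started from the full-data optimum), and reports the percentage
of replicates agreeing with the full-data topology. Each pair's
bootstrap seed is derived as master seed + pair index and recorded, so
any single pair can be replayed.

# Selection analysis

Protein alignments of pair members are back-translated onto their
source CDSs (columns with a gap in either row are dropped; a terminal
stop codon is tolerated) to form codon alignments.

Two estimators are implemented. `kaks_ng86()` is classic Nei–Gojobori
counting: per-codon synonymous site fractions with equal mutation
weights, differences averaged over all shortest mutational pathways
(stop-crossing pathways excluded and weights renormalized), and the
one-parameter Jukes–Cantor correction. It exists as the transparent,
independently checkable baseline. `kaks_myn()` is the headline
estimator in the Yang–Nielsen family: the transition/transversion ratio
$\kappa$ is estimated from fourfold-degenerate sites (falling back to
nondegenerate sites) with the K80 formula; mutational opportunity is
weighted by $\kappa^{\text{ts}}$ times position-specific
target-nucleotide frequencies; and each substitution class is corrected
with the two-parameter K80 distance using its own
transition/transversion split. Estimating $\kappa$ from fourfold sites
matters: pooling all sites inflates $\kappa$ under purifying selection
(synonymous transitions dominate the observed differences), which
propagates into an upward omega bias of roughly 15% in our
calibrations. With $\kappa = 1$ and uniform frequencies the counting
collapses onto Nei–Gojobori, which the tests assert within 5% relative.

Proportions beyond the correctable range ($p \ge 3/4$ for
Jukes–Cantor, non-positive logarithm arguments for K80) flag the
estimate `saturated` with an undefined value; nothing is extrapolated.
Omega labels use the reference marks 0.3 / 1 / 3 for purifying /
neutral / positive selection, echoed in output tables.

The cross-strain test is a standard one-way ANOVA decomposition on the
omega values of the "common pairs" (pairs with exactly two qualifying
matches in every strain), with the upper F tail for the p-value and the
pooled within-group standard deviation reported. If every observation
is identical, F is defined as 0.

# The simulator

`simulate_cohort()` evolves each gene family along an explicit species
tree under a GY94-style codon model: substitution rate proportional to
$\pi_{\text{target}} \cdot \kappa^{\text{transition}} \cdot
\omega^{\text{nonsynonymous}}$, stop codons inaccessible, generator
normalized so branch lengths are expected substitutions per codon site.
Sites evolve independently by exact event-by-event (Gillespie)
simulation driven by R's RNG, so a master seed reproduces cohorts
byte-for-byte.

Age classes are generated *structurally*, by event order, not by target
topology: pre-speciation families duplicate on the root branch before
the focal lineage splits from the closer relative species X (truth
Type-A), post-speciation families duplicate inside the focal lineage
after the split (truth Type-B). A more distant species Y provides the
second ortholog that post-speciation pairs need, and makes the
shared-best-ortholog tie-break a genuinely exercised code path. Three
focal-species strains diverge recently and lose each duplicate copy
independently with a configurable probability.

Key defaults, chosen once as the study conditions the package targets:
77% of duplications pre-speciation; family omega lognormal with mean
0.13 and spread 0.033 (the purifying regime the selection analysis
expects, with a cross-pair standard deviation matching the reported
scale); $\kappa = 2$ (a typical bacterial transition bias); 300 codons
per gene; speciation from X at 0.3 and from Y at 0.5 substitutions per
codon site, pre-speciation duplications at 0.6 (internal quartet branch
0.6) and post-speciation ones at 0.15; strain divergence 0.02; per-copy
loss probability 0.3; replicon proportions CI:CII:plasmid =
0.65:0.25:0.10. Ancestral codons are drawn from equilibrium frequencies
(uniform by default; a GC knob mimics high-GC genomes without claiming
any organism's exact composition).

What the simulator does **not** emulate: insertions/deletions (the
aligner is exercised on substitution-only truth, so tests validate the
alignment machinery's correctness, not its accuracy on gappy real
proteins), rate heterogeneity across sites, recombination, gene
conversion between paralogs, and compositional heterogeneity between
genes. Passing recovery tests therefore demonstrates the pipeline's
algorithmic correctness under the stated model, not performance on any
particular real genome.

# Numerical and design notes

* Rounding of report percentages is half-up at the printed number of
  decimals, applied as the last operation, so census fixtures reproduce
  printed tables exactly.
* Degenerate quartets (e.g. four identical sequences) tie all three
  topologies; the deterministic preference order reports a Type-A
  topology with the `tie` flag set.
* All-gap alignment columns are skipped with a warning; a gap leaf
  contributes a flat conditional likelihood.
* The chi-square goodness-of-fit drops categories with zero expected
  proportion and zero observed count from the degrees of freedom, and
  refuses (errors) when a zero-expectation category is observed.
* COG general groups follow the standard 25-letter mapping into
  information storage and processing / cellular processes and
  signaling / metabolism / poorly characterized; unannotated genes form
  group 0. Multi-category genes count once per category, so tally
  totals can exceed gene counts — conserved through binning and
  clustering.
* Positional clusters use fixed non-overlapping 100-kb windows tiled
  from coordinate 0 with a minimum of 3 same-group duplicated genes;
  both knobs are configuration values since no finer rule is
  established for this kind of scan.
* Replicon lengths travel in a small `replicons.tsv` alongside the gene
  table (inferred from gene extents when absent); CI is identified as
  the longest chromosome.
* Test and validation problem sizes — e.g. 200 simulated quartets for
  topology recovery, 200 replicates per omega grid point, 120-family
  cohorts for the Type-A fraction, 50-family cohorts for the
  determinism check, and 150-/80-family cohorts in the reproduction
  script — were chosen so the whole validation suite runs on a
  laptop-class single core in well under half an hour while keeping
  binomial sampling error comfortably inside the stated tolerances.

# Known limitations

* The Karlin–Altschul conversion applies local-alignment statistics to
  global scores; it is used as a configurable ranking device
  (deterministic, monotone in score), not as a calibrated significance
  claim.
* The progressive aligner is a quartet-scale tool; it makes no claim to
  MUSCLE-level accuracy on large or indel-rich families.
* MYN here means the kappa- and frequency-corrected approximate
  counting method described above; exact numerical agreement with any
  external implementation is not a goal — estimator calibration is
  demonstrated by simulation recovery instead.
* Alignment-based homology cannot separate analogy from homology for
  highly diverged pairs, and families with more than two copies are
  censused but deliberately not dated.
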