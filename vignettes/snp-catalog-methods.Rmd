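---
title: "Methods: building and characterizing a multi-dataset SNP catalog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and characterizing a multi-dataset SNP catalog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VariantCatalog)
```

## The problem

Combining whole-genome variant calls from heterogeneous sources —
individual short-read sequencing at variable depth, pooled DNA
sequencing, and long-read sequencing — yields call sets that disagree
for both biological and technical reasons. The strategy implemented
here treats cross-dataset concordance as the confidence criterion: a
biallelic SNP enters the final catalog only where every dataset that
*can* observe its chromosome class actually called it. The catalog is
then characterized with the statistics that matter for downstream
genotyping-array design: per-group call rate and allele frequency,
marker density and spacing along the genome, per-window candidate
budgets, and population-structure summaries.

The package's own simulator generates all inputs with known truth, so
every stage is testable without access to any real cohort.

## Data model and coordinate conventions

All coordinates are 1-based and inclusive, the VCF convention; windows
are `[start, end]` inclusive. A variant's identity is the full key
`(chrom, pos, ref, alt)`: intersection is allele-aware, and the same
position with different alternative alleles yields distinct keys. This
assumes all call sets share one reference assembly, so no liftover or
strand reconciliation is needed.

Per-genotype fields distinguish *absent* from *zero*: a caller that
did not emit AD yields `NA` allele depths, which removes the sample
from frequency sums rather than diluting them with fake zeros.
Haploid calls (male X, Y, MT) are carried as homozygous diploid
genotypes, matching common caller output and keeping a single genotype
encoding.

Multiallelic sites are classified and excluded, not split: the catalog
is biallelic by construction, multiallelics are a sub-percent minority
in this kind of data, and splitting semantics for AD re-allocation are
not well defined. MNPs (equal-length multi-base substitutions) are
normalized into per-base SNPs that inherit the parent record's
genotype entries verbatim — perfect linkage within the few affected
bases is assumed.

## Per-dataset quality control

Each call set gets the filter chain suited to its calling regime
(`defaultFilterConfig`):

| dataset | chain | rationale |
|---|---|---|
| S1 (individuals + pools) | mask `DP >= 5` (pools exempt), then site missingness <= 0.1 over non-pool samples | depth is low and variable (3–40x); pools carry no genotypes and their duplicate-heavy libraries are depth-filtered upstream |
| S2 (high-depth females) | MNP decomposition, mask `GQ >= 30` and `DP >= 10`, site missingness <= 0.1 | uniformly high depth (28–56x) supports strict genotype-quality cuts |
| L (long reads) | mask `GQ > 20` and `DP > 5` (strict), biallelic SNPs, alt allele present in >= 2 samples | higher per-base error; the 2-of-8 carrier rule suppresses singleton artifacts |

Two deliberate reading choices are exposed as configuration rather
than hidden:

* **Inclusive vs strict comparisons.** "Minimum X" thresholds are
  implemented as `>= X` (the convention of the standard filtering
  tool), while the long-read chain's "more than" thresholds are
  strict `>`. The `strict` flag flips either.
* **Missingness dialect.** The prose reading of a "maximum missing
  fraction of 0.1" (keep sites with <= 10% missing genotypes) is the
  default (`PROSE`). The widely used command-line tool's flag of the
  same name actually takes a *minimum called fraction*, so `VCFTOOLS`
  reproduces that inverted semantics for users replicating tool-based
  pipelines. The two differ enormously (call rate >= 0.9 vs >= 0.1);
  the default follows the strict prose reading, which also matches the
  downstream "CR > 0.9" selection.

A genotype whose targeted field is absent is masked (conservative) and
counted in the mask log; silently passing it through would inflate
call rates. Masking never changes the site count, and site filters
never alter genotypes, so the two effects compose cleanly.

The minimum-carrier rule counts *alt-carrying* samples, the stricter
reading of "presence in at least 2 individuals"; `carrierMode =
"called"` gives the lenient alternative.

## Merge rules

Inclusion rules are a table from chromosome class to the set of
datasets that must all contain the key: autosomes and X require
`{S1, S2, L}`; Y requires `S1` (the only dataset with informative
males); MT requires `{S1, S2}` (long reads fail on the short MT
sequence). Because the rules are data, other designs — e.g. a
short-read-only autosomal catalog — are a one-line configuration
change. After merging, each sample's genotypes come from its own
dataset; samples whose dataset lacks a key get all-absent entries, and
no cross-dataset genotype reconciliation is attempted since every
sample belongs to exactly one dataset.

## Group statistics: two denominators by design

Call rate uses genotype presence over a group's *individuals*; pools
are excluded because they carry no GT. The alternative allele
frequency deliberately does **not** use genotypes: it is the ratio of
summed alt read depth to summed total depth over all group members
*including* pools. This makes low-coverage samples and pools —
useless for genotype-level statistics — still informative about
frequency. Consequences handled explicitly:

* `AAF` with zero summed depth is **undefined** (`NA`), never 0; such
  sites fail polymorphism selection because zero reads carry no
  frequency information.
* Masked genotypes keep their AD/DP in the frequency sums by default
  (the read counts are in the VCF regardless of the call);
  `aafRespectsMasking = TRUE` excludes them.
* Samples structurally blind to a chromosome (the female-only dataset
  on Y, the long-read dataset on MT) leave the call-rate denominator
  at such sites instead of counting as missing
  (`excludeByRule`).

Selection defaults (`SelectionThresholds`): call rate strictly
`> 0.9` (the "greater than 90%" wording; the boundary value 0.9
fails), AAF within the inclusive band `[0.02, 0.98]`, and sample
exclusion above 0.5 missingness before structure analyses. Carry-over
into another group is the fraction of selected keys whose other-group
AAF stays inside the band, with undefined AAF counting only in the
denominator. Under the Balding–Nichols model the expected carry-over
is non-increasing in FST, which the tests verify empirically.

## Density, spacing, windows

Per-chromosome density divides the marker count by the assembly length
from the layout (covered length is not modeled). Two spacing notions
are reported: the empirical mean gap between successive markers, and
the density-implied gap `10^6 / density` rounded to the nearest bp.
Headline spacing numbers conventionally use the implied form — it is
the exact reciprocal of the printed density.

Windows tile each chromosome without gap or overlap; the terminal
window is truncated at the chromosome end and its density statistics
use its **actual** width, avoiding edge-inflated rates. For
"count ± SD over nominal windows" summaries, `genomeMeanDensity(...,
perMbp = FALSE)` reproduces the raw-count convention. Window counting
and assignment are interval queries over `GRanges`; positions on the
inclusive window boundary belong to the earlier window. Extreme-window
ranking breaks ties by (chromosome order, start), and the
bottom ranking ignores empty windows.

## Array budgeting

The per-window availability report is exactly what the budget argument
needs: markers per 100-kbp window, whose mean is the mean per-Mbp
density divided by 10. On top of that, the package adds a natural
selection step: a composite score `w1*CR + w2*(1 − |2·AAF − 1|)`
(defaults 0.5/0.5; informativeness peaks at AAF 0.5) and a greedy
per-window pick of the highest-scoring markers subject to a minimum
spacing, ties broken totally by (position, ref, alt) so selection is
deterministic. Greedy selection can be marginally suboptimal in total
score; the tests compare it against exhaustive search on small windows
and assert feasibility rather than optimality, which is adequate at
realistic quotas (3–30 per window against hundreds of candidates).

## Population structure

Dosage matrices use mean imputation for missing entries (the common
default of genotype-PCA toolkits) and drop variants with no called
sample or zero variance. PCA centers and variance-standardizes
variants, then uses SVD; variance explained is the squared singular
value over the total, and each component's largest-magnitude loading
is made positive for a reproducible sign. Clustering uses average
linkage on the allele-sharing distance `1 − mean(1 − |d_i − d_j|/2)`
(equivalently manhattan distance over dosages scaled by `2p`), chosen
because pairwise-identity distances are the convention of the toolkit
family this mirrors; the exact metric behind any given published
dendrogram is rarely stated, so the default is declared, not inferred.

## The simulator: what it emulates, and what it does not

Group divergence follows the Balding–Nichols model: ancestral
frequencies uniform on [0.05, 0.95]; group frequency
`~ Beta(p(1−f)/f, (1−p)(1−f)/f)` with `f` the group's FST. Defaults
`FST = 0.05 / 0.10 / 0.35` for MED/RIV/SWA encode a cohesive reference
breed, a related river group and a strongly diverged swamp group —
the minimal standard model for the observed pattern of
group-differential polymorphism. Default sample composition mirrors
the study design: S1 = 22 males of all three groups (depths spread
evenly over 3–40x, since only the range is known) plus two MED pools
of 18 and 3 animals at 30x; S2 = 24 MED females at 28–56x; L = 8 MED
males at 25–63x.

Per site and individual: genotype from Hardy–Weinberg at the group
frequency (haploid on male X, Y, MT; females have no Y); depth
`~ Poisson(mean depth)`; alt reads `~ Binomial(DP, q)` with
`q = (d/2)(1−e) + (1−d/2)e` for dosage `d` and base error `e`;
emitted genotype flips to a random other genotype with the genotype
error rate; `DP = 0` yields a missing call. GQ is a monotone function
of depth (`3·DP` plus Gaussian noise, clamped to [0, 99]) rather than
a calibrated likelihood — only the threshold behavior at GQ 20/30
matters downstream, and `3·DP` places those thresholds at the
intended depth regimes. Pools draw `2N` haplotypes binomially and
emit AD/DP only. Each dataset independently drops 5% of truth sites
(nontrivial intersections); 2% of S2 records are re-encoded as 2-bp
MNPs whose decomposition restores the original SNP, exercising
normalization without changing site content.

Not modeled: read-level artifacts (duplicates, mapping quality,
strand bias), indels and structural variants, linkage disequilibrium
between sites, relatedness within groups, and reference bias. Passing
tests therefore demonstrate the correctness of the *pipeline logic*
and estimator behavior under a clean generative model, not robustness
to every failure mode of real sequencing data.

## Determinism and numerical choices

Every stochastic function takes a seed and restores the caller's RNG
state; the pipeline fans a single top-level seed out to fixed
per-stage offsets so stages are individually re-runnable. Identical
configuration and seed give byte-identical outputs, including written
VCFs. Histogram bins are closed on the left with the last bin closed
on both sides, so a call rate of exactly 1 lands in the top bin.
Degenerate inputs error loudly rather than silently: empty eligible
sample sets, zero-member groups, keys outside every window, rules
missing for a chromosome class, duplicate keys within a dataset, and
samples appearing in two datasets.

## Problem sizes

The test suite and the acceptance script run on a miniature genome
(five autosomes of 3–8 Mbp plus X, Y, MT) with 150–5,000 simulated
variants and the default 55-sample design; parameter-recovery checks
use 2,000 variants at 20 samples and 30x, and structure-recovery
checks use 5,000 variants across three 20-sample groups at FST 0.2,
five seeds. These sizes give the estimators enough data for tight
property checks (regression slopes within 5% of unity, k-means label
agreement of at least 95%) while keeping a full run in seconds. The
real-scale layout (24 autosomes + X + Y + MT, millions of sites) is
expressible through the same tables; nothing in the code depends on
the miniature scale.

## Known limitations

* Complex-allele normalization (the interplay of haplotype-resolving
  tools on nested or overlapping alleles) is out of scope; only plain
  MNP decomposition is implemented.
* The catalog-level headline numbers of any real cohort are
  data-bound: the simulator reproduces the *structure* of such
  results (e.g. carry-over ordering across groups), not their exact
  values.
* BCF/binary input is not supported; plain or gzipped VCF only.
* The chip-selection score is a transparent default, not an assay
  design tool: no probe sequences, conversion scores or
  cross-hybridization checks.
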