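---
title: "Detecting selection signatures with Fst and XP-EHH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection signatures with Fst and XP-EHH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selsig)
```

## The problem

Strong artificial selection — for example for the fine undercoat fiber
(cashmere) produced by the secondary hair follicles of some goat breeds —
leaves two complementary footprints in a genotyped panel:

* **allele-frequency differentiation**: the selected variant, and linked
  variants, drift to frequencies very different from an unselected
  reference breed, which per-SNP Fst detects; and
* **extended haplotype homozygosity**: the swept haplotype is long and
  shared among carriers, which EHH-based statistics detect from phased
  data.

`selsig` implements both scans, the empirical top-5% candidate rule, ±50 kb
gene annotation and the downstream set operations as one tested pipeline,
together with a simulator that plants sweeps so every stage can be
validated end to end.

## Models and estimators

### Per-SNP Fst

The two-population estimator works on allele-frequency mean squares. With
allele sample sizes $m_i = 2 \times$ (genotyped diploids) and frequencies
$p_i$:

$$\bar p = \frac{\sum_i m_i p_i}{\sum_i m_i}, \qquad
\mathrm{MSP} = \sum_i m_i (p_i - \bar p)^2, \qquad
\mathrm{MSG} = \frac{\sum_i m_i p_i (1 - p_i)}{\sum_i (m_i - 1)},$$

$$n_c = \sum_i m_i - \frac{\sum_i m_i^2}{\sum_i m_i}, \qquad
F_{st} = \frac{\mathrm{MSP} - \mathrm{MSG}}
              {\mathrm{MSP} + (n_c - 1)\,\mathrm{MSG}}.$$

MSP is the *among*-population and MSG the *within*-population mean square
— the assignment under which the estimator behaves correctly at the
boundaries: a fixed difference gives exactly 1 (MSG = 0), equal
frequencies give $-1/(n_c - 1)$, and the estimator never exceeds 1.
Negative values are reported as computed; truncation would not change
which SNPs enter the empirical top 5%.

```{r fst-edges}
fst_per_snp(20, 1, 20, 0)$fst      # fixed difference
fst_per_snp(20, 0.5, 20, 0.5)$fst  # equal frequencies: -1/19
```

Two aggregations of per-SNP values exist and they are *not*
interchangeable. The per-SNP ratio estimate is noisy and its arithmetic
mean is biased downward (a ratio-estimator effect): on simulated panels
with true differentiation 0.4 it averages only about 0.26. The
genome-wide (multi-locus) estimator used by `pairwise_fst_matrix()` is
the ratio of sums, $\sum(\mathrm{MSP}-\mathrm{MSG}) / \sum(\mathrm{MSP} +
(n_c-1)\mathrm{MSG})$, which recovers the simulated differentiation to
within a few thousandths; it is the quantity the parameter-recovery tests
check, and the one fed to the neighbor-joining tree.

### EHH and XP-EHH

From a core SNP, haplotypes are partitioned by their full allele vector
over the closed marker interval $[\mathrm{core}..x]$; with class sizes
$n_i$ and core-allele counts $n_a$, $n_A$,

$$\mathrm{EHH}(x) = \frac{\sum_i \binom{n_i}{2}}
                         {\binom{n_a}{2} + \binom{n_A}{2}}.$$

Because the core allele is part of the interval, the partition never
mixes core alleles, so $\mathrm{EHH}(\mathrm{core}) = 1$ and the curve is
non-increasing outward (classes only refine). This pooled denominator
treats both core alleles jointly; the classical single-allele definition
is available via `ehh_curve(..., mode = "per_allele")` for comparison.

XP-EHH compares integrated EHH between an object and a reference
population over a *shared* domain $D$:

$$\mathrm{XP\text{-}EHH} =
  \frac{\int_D \mathrm{EHH}_{obj}(x)\,dx}
       {\int_D \mathrm{EHH}_{ref}(x)\,dx}.$$

$D$ is extended marker by marker, per direction, until both curves drop
below `epsilon` (default 0.05, "sufficiently small"); the first
below-threshold marker closes the domain so the trapezoid has a defined
endpoint. Integration is trapezoidal over physical bp. The plain ratio is
the default output; `ln_ratio` and a genome-standardized `ln_z` are
emitted alongside, since published per-SNP values may follow any of the
three conventions. Swapping the populations negates `ln_ratio` exactly.
Haplotypes with a missing allele are dropped from the partition from that
marker outward, with the denominator fixed at the core.

### Quality control

Four chip-style SNP filters, applied jointly and idempotently: exact
Hardy–Weinberg test $p \ge 10^{-6}$, call rate $> 0.90$, minor allele
frequency $> 0.01$, and autosomal location. The HWE test is the exact
conditional test (sum of all heterozygote-count probabilities not
exceeding the observed one, no mid-p), computed on the pooled sample by
default — the common chip-QC practice — with `hwe_by_pop = TRUE` to test
within each population and fail on the worst. A zero bound disables its
rule, so all-zero thresholds form the identity filter even on monomorphic
columns.

### Candidates, genes, and set operations

Thresholds are nearest-rank empirical quantiles: sort non-missing values
in decreasing order and take rank $\lceil 0.05\,n\rceil$, so the
threshold is attained and ties can only add candidates. Thresholds are
computed per statistic and per population pair. A gene is a candidate
when its span intersects a ±50 kb window around any candidate SNP on the
same chromosome; per pair the Fst and XP-EHH gene lists are
*intersected* ("merged": genes supported by both approaches), and merged
lists are intersected across pairs to give the shared-overlap set. A
per-SNP nearest-gene column (minimal gap within the window, ties to the
smaller start) reproduces the usual one-gene-per-SNP report table.

### Enrichment

Over-representation of a candidate set against a user-supplied
pathway→gene map: upper-tail hypergeometric p per pathway, with
Benjamini–Hochberg q-values and significance at $q < 0.05$. The
background defaults to all annotated genes. A plain hypergeometric tail
(rather than any web service's modified score) keeps the computation
reproducible from the two supplied files alone.

## The simulator

`simulate_panel()` draws a star-split multi-population panel under the
Balding–Nichols model: ancestral frequency $p \sim U(0.05, 0.95)$ per
SNP, population frequency $p_k \sim \mathrm{Beta}(p(1-F)/F,\,
(1-p)(1-F)/F)$ — so the differentiation parameter $F$ *is* the expected
Fst — and independent Bernoulli alleles per haplotype. Defaults mirror a
50K-chip breed study: three populations of 17, 20 and 16 diploid samples.

`plant_sweep()` adds the selection signal: one donor haplotype is chosen
in the target population and each of a `carrier_fraction` (default 0.8)
of that population's haplotypes copies the donor allele at each variant
with probability $e^{-|pos - core|/L}$ (decay length $L$, default 2 Mb).
This distance-decaying copying directly produces the long shared
haplotype XP-EHH targets, with a closed-form decay profile, and provably
never touches other populations.

What the simulator deliberately omits: background linkage
disequilibrium (sites are independent given frequencies), recombination
maps, mutation-rate heterogeneity, demography beyond the star split, and
sex chromosomes. Consequently passing tests demonstrate the estimators
and the pipeline logic, not robustness to background LD — on real chip
data neighboring SNPs are correlated, EHH decays more slowly everywhere,
and empirical thresholds sit higher. The simulation is a clean null plus
a clean signal, not a portrait of a real genome.

## Numerical and design choices

* **Coordinates** are 1-based inclusive throughout; BED input is shifted
  on read (`start+1`), GFF3 passes through. Interval lengths are
  preserved exactly.
* **Missingness**: a missing haplotype allele is `NA`; a genotype is
  missing when either haplotype is. `./.` reads as fully missing;
  half-calls keep the known allele.
* **Ordering**: variants sort by (chromosome in input order, position),
  duplicate positions are an error; samples keep VCF header order — all
  outputs are byte-stable for a fixed seed.
* **epsilon = 0.05** for the EHH stop: small enough that the discarded
  tail contributes little to either integral, large enough that domains
  stay short on unstructured panels. On LD-free panels EHH falls below it
  within a handful of markers away from sweeps.
* **NJ branch lengths**: negative lengths (possible on non-additive
  inputs) are clamped to zero with the deficit moved to the sibling edge,
  preserving sibling path lengths; additive matrices are unaffected and
  reconstruct exactly.
* **PCA scaling** follows the allele-frequency standardization
  ($2\hat p$ centring, $\sqrt{2\hat p(1-\hat p)}$ scaling, monomorphic
  SNPs dropped, mean imputation of missing dosages); component signs are
  fixed by making the largest-magnitude loading positive.
* **Seeds**: every stochastic function takes one integer seed;
  replicate $k$ of a study derives its seed as base $+ k$. The planted
  sweeps inside `simulate_panel()` use offsets of the panel seed.

## Problem sizes used in validation

The test suite validates each estimator against an independent oracle
(allele-level ANOVA for Fst, exhaustive haplotype-partition counting for
EHH, full enumeration for the exact HWE test and the hypergeometric
tail), then runs simulation studies at desk scale: parameter recovery on
2×20-sample, 5,000-SNP panels for $F \in \{0.05, 0.1, 0.2, 0.4\}$ with 10
seeds each, and sweep-detection power on 50 replicates of a 17-vs-16
sample, 5,000-SNP / 50 Mb panel with one planted sweep
(carrier fraction 0.8, decay 2 Mb). Under those conditions the planted
core is an XP-EHH top-5% candidate, and the gene covering it enters the
merged (Fst ∩ XP-EHH) set, in at least 45 of 50 replicates.

## Known limitations

* The scan statistics assume phased input; phasing itself is out of
  scope and unphased genotypes are only accepted (with a warning and
  arbitrary phase) when explicitly requested.
* Per-SNP XP-EHH ratios on marker-sparse regions depend on marker
  density through the integration domain; compare values only within a
  panel, via the empirical quantile rule, not across panels.
* Fst here is the two-population estimator; multi-population scans are
  limited to the pairwise matrix used for the tree.
* The enrichment background is whatever gene universe the caller
  supplies; q-values are only as meaningful as that background.
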