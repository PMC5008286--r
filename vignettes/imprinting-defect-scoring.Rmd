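---
title: "Quantifying loss of imprinting at 14q32: methods and design notes"
author: "imprintscore authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying loss of imprinting at 14q32: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintscore)
```

## The scientific problem

The human 14q32 locus (mouse 12qF) carries the DLK1-DIO3 imprinted gene
cluster, regulated by three differentially methylated regions: two
intergenic DMRs between *DLK1* and *MEG3* (DMR-1, DMR-2) and the *MEG3*
promoter DMR (DMR-3). In normal tissue each DMR is methylated on exactly
one parental allele, so bulk bisulfite measurements sit near 50%. Both
gain and loss of methylation disturb the monoallelic program and
downregulate the cluster's genes and miRNAs, so a useful defect statistic
must be sign-agnostic.

The **14q-index** is the mean absolute deviation of the three DMRs from
the expected imprinted level:

$$\mathrm{index} = \frac{|m_1 - 50| + |m_2 - 50| + |m_3 - 50|}{3}$$

with $m_i$ the percent methylation of DMR-$i$. A sample is called
defect-positive (14q-I(+)) when its index strictly exceeds 8.5, the
default threshold stored in `ScoringConfig`-like arguments throughout the
package. In osteosarcoma cohorts this quantity separates early-onset
(< 30 years) tumors, where the locus is hypomethylated far beyond the
genome-wide (LINE-1) trend, from late-onset tumors whose modest DMR
demethylation tracks global demethylation.

```{r}
fourteenQIndex(31, 35, 45)   # deviations 19, 15, 5 -> index 13
classifySample(c(7, 8.5, 13))
```

## Model and assumptions, module by module

### Scoring

`dmrDeviation()` and `fourteenQIndex()` implement the formula above.
Choices worth knowing:

* **Strict threshold.** An index of exactly 8.5 is *negative*; the
  comparator is exposed (`strict = FALSE`) for sensitivity analyses.
* **Missing DMRs** are averaged over rather than refused, with a
  `complete` flag, because single-DMR designs (the mouse IG-DMR assay)
  use the same machinery.
* **Per-tissue expected levels.** Bone uses 50%. Buccal epithelium drifts
  upward with age (means near 53% at DMR-1 and 64% at DMR-2 in unrelated
  normals), so `scoreSamples(expectedLevel = c("DMR-1" = 53, ...))`
  accepts per-DMR overrides. The default stays 50.
* `referenceRange()` offers two interval modes. The default `mean_ci`
  (t interval for the mean) reproduces the narrow published normal bands —
  a 51–55% band around a 53% mean is far too tight to be an SD-based
  reference interval at plausible n. `reference_interval` (mean ± z·sd)
  is provided for per-individual coverage. Zero-variance input degenerates
  to [mean, mean] with a warning rather than an error.

### Bisulfite clone calling

`callMethylation()` applies the canonical rule — at a CpG cytosine, C
means methylated (5mC resists deamination), T means unmethylated, anything
else is missing and never imputed. Cytosines outside CpG context are
unmethylated in somatic DNA, so the fraction of them reading T estimates
per-clone conversion efficiency; clones under 0.95 (the usual QC
convention; the protocol itself publishes no threshold) are flagged and
excluded from summaries by default, never silently.

Comparison is gapless and length-checked: clones are Sanger-verified
amplicons of fixed length, so embedding an aligner would add failure modes
without adding information. Sequences needing alignment belong upstream.
Coordinates are 1-based everywhere, following R convention.

`summarizeCloneMatrix()` averages per-clone means (the standard
TA-cloning summary), and `detectImprintingPattern()` encodes the
diagnostic dichotomy of an imprinted region — one densely methylated and
one essentially unmethylated allele with ~50% overall methylation. The
cutoffs (dense ≥ 0.7, sparse ≤ 0.3, each class ≥ 20% of clones, overall
within 40–60%; hypermethylated ≥ 80%, hypomethylated ≤ 20%) mirror the
visual dichotomy of published clone diagrams and are all exposed as
arguments.

### Cohort statistics

Pearson correlation, Welch and pooled t tests, and one-way ANOVA are
implemented from their textbook formulas (p-values from `pt`/`pf`), with
`stats::cor`, `stats::t.test` and `stats::aov` serving as independent
oracles in the test suite. Welch is the default two-group test — cohort
variances differ between tumor groups — with the pooled Student t
available and the report naming which ran. No multiple-testing correction
is applied by default because the analyses are a handful of planned
contrasts; percent-positive summaries round to the nearest integer for
display (one decimal optionally) while retaining full precision.

`demethylationExtent()` defines demethylation as normal-group mean minus
the observed value and compares per-sample locus deltas (14q32 DMRs
averaged within sample) against LINE-1 deltas by unpaired Welch t.
Whether the published comparison used per-sample or per-group summaries
is not stated; per-sample is chosen because it uses all information and
is documented here.

### Expression and ChIP normalization

`relativeExpression()` is classic ΔΔCt with efficiency fixed at perfect
doubling (2.0), matching simple-control qPCR designs. The calibrator
baseline is the arithmetic mean of calibrator ΔCt per gene, so the
geometric mean of calibrator fold changes is exactly 1 — the geometric
convention is the field default for ratio-scale fold changes. `chipEnrichment()` exposes the three common normalization
chains (fold over IgG, percent input, H3-corrected) as explicit modes
rather than guessing a single one, since published ChIP figures rarely
pin down the full chain; the modes satisfy the exact identity
h3_normalized = percent_input(mark) / percent_input(H3).

### Survival

`kmEstimate()` and `logrankTest()` are first-principles implementations
(product-limit curve; Mantel–Haenszel statistic with hypergeometric
variance), with the survival package used only as a cross-check oracle in
tests. Ties follow the standard convention that events precede censorings
at the same time. A median is "not reached" (NA) when the curve never
crosses 0.5. The log-rank test is restricted to two strata — the
published comparisons are two or three curves, and pairwise tests cover
the three-curve case — and `stratifyByIndex()` offers call-based,
threshold and tertile stratification because the exact published strata
definition is not stated.

## The synthetic-data generator

No per-sample methylation tables are publicly deposited for this locus —
the cohort values live in figures — so the package ships a generator,
`simulateCohort()` and friends, whose *defaults are the study
conditions*: they encode the effect structure the analysis assumes, and
the test suite checks that every downstream stage recovers those
parameters from generated data.

* **Cohort.** Normal imprinted DMRs: Gaussian around 50%, clamped to
  [0, 100]. The baseline SD of 8.8 is a calibration, not a published
  value: since $E|N(0,\sigma)| = \sigma\sqrt{2/\pi}$, it makes the
  expected 14q-index of normal samples ≈ 7, consistent with the reported
  normal mean index. Early-onset tumors shift the three 14q32 DMRs by
  −19 points, late-onset by −6; LINE-1 (baseline 70%, SD 3) drops 5
  points in both tumor groups. With these settings the expected
  early-onset mean index is ≈ 19 and the late-onset mean ≈ 8.6,
  bracketing the published 18.6 and 8.5. MEST and PEG3 stay at baseline.
  No within-group variances are published; every SD is a surfaced config
  field, never a hidden constant.
* **H19 coupling.** The H19 defect extent is generated from the sample's
  realized 14q32 defect extent (a shared latent severity) plus noise
  scaled as $\sigma_X\sqrt{1/r^2 - 1}$ so the population correlation with
  the index equals the configured 0.78; the defect's *sign* is random,
  producing both gain and loss of methylation at H19 as observed. Direct
  value copying would force one sign and a degenerate joint distribution.
* **Triads.** Child buccal methylation is a correlation-weighted
  combination of the matching parent's standardized value
  (father at DMR-1, target r = 0.5; mother at DMR-2, target r = 0.63)
  and independent noise, exact in population before clamping. Family
  means (58%/70%) sit above the unrelated-normal buccal means (53%/64%),
  reflecting the hypermethylation observed in patients and parents.
* **Clones.** Two alleles with per-CpG methylation Bernoulli(0.9) /
  Bernoulli(0.1) by default. Clones are split equally between alleles
  (`alleleAssignment = "balanced"`), emulating the clone-*selection* step
  of TA cloning in which sequenced clones are picked to represent both
  alleles; iid Bernoulli(0.5) assignment ("random") is available, but
  under it the overall methylation of a 10-clone sample falls outside the
  40–60% imprinted band about a third of the time from allele-sampling
  noise alone, which is a property of unselected cloning, not of the
  detector. Incomplete conversion leaves unmethylated cytosines reading
  C with probability 1 − efficiency, identically at CpG and QC positions,
  so conversion QC can detect it. Sequences are emitted on the converted
  top strand only.
* **Outcomes.** Imprinted-gene expression decays as
  $\exp(-\gamma\,\mathrm{index}/10)$ with lognormal noise, emitted as a
  Ct table with a flat housekeeping gene so the ΔΔCt machinery applies
  unchanged. Survival is exponential with hazard
  $h_0 \exp(\beta(\mathrm{index} - 8.5)/10)$, $h_0 = \log 2 / 60$ per
  month (median 60 months at the threshold index), under independent
  uniform censoring on (0, 120] months — roughly 45% event rates, typical
  of a followed sarcoma cohort.
* **Determinism.** One global seed; each component (cohort, clones,
  triads, outcomes) draws from a substream derived deterministically from
  it, so regenerating any single table never perturbs the others.

What the generator does *not* emulate: assay-specific error (pyrosequencing
bias, PCR bias toward unmethylated templates), age as a continuous
covariate, batch structure, or read-level signal. Passing tests therefore
demonstrate that the statistical machinery is correct and calibrated
under the assumed effect structure — not that real cohorts satisfy that
structure.

## Numerical choices and degenerate inputs

* Percentages are 0–100 everywhere, never 0–1.
* Methylation values are clamped (censored) at the [0, 100] bounds;
  at the default means and SDs the clamping probability is negligible,
  so means are effectively preserved.
* Zero-variance reference values give a degenerate range with a warning;
  zero-variance correlation input is an error, not NA.
* Ambiguous bases (N) at CpG sites are missing, never imputed; an
  all-missing clone is excluded from summaries with its id reported.
* Tertile stratification uses type-7 quantiles, giving equal thirds on
  distinct values.

## Problem sizes

The shipped checks run at the sizes the contracts name: cohorts of 1000
samples per group for parameter and correlation recovery, 10,000 clones
for the allele-mixture expectation, 100 10-clone replicates for pattern
detection, 1000 null replicates (n = 200) for log-rank type-I error and
50 replicates at n = 2000 for power. On one core the full test suite
runs in well under a minute and the acceptance script in under a minute.

## Known limitations

* The 8.5 threshold is adopted verbatim; whether it arose as a CI bound
  or a quantile of normals is not derivable from the published account,
  so `referenceRange()` is provided to re-derive thresholds on user data.
* Published late-onset positivity (5 of 9) is not reverse-engineered:
  per-sample cohort values are unavailable, and the generator makes no
  attempt to force that fraction.
* Cox models and hazard-ratio intervals are out of scope (the source
  cohorts are too small for them); the survival module stops at KM and
  the two-sample log-rank.
* k-sample log-rank, bisulfite read mapping, and RNA-seq quantification
  are deliberately upstream or out of scope.
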