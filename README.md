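# imprintscore

Quantifying loss of imprinting at the human 14q32 (DLK1–DIO3) locus.

## The problem

The 14q32 imprinted cluster is controlled by three differentially
methylated regions (DMRs): two intergenic DMRs between *DLK1* and *MEG3*
and the *MEG3* promoter DMR. Each is methylated on exactly one parental
allele, so bulk methylation in normal tissue sits near 50%; both
hyper- and hypomethylation disturb the monoallelic program and silence
the cluster's genes and miRNAs. In osteosarcoma, defects at these DMRs
are frequent, onset-dependent, partly heritable, and prognostic — which
makes a simple, sign-agnostic defect statistic useful to anyone analysing
methylation at this locus (or any imprinted DMR).

That statistic is the **14q-index**, the mean absolute deviation of the
three DMRs from the imprinted level:

    index = (|m_DMR-1 − 50| + |m_DMR-2 − 50| + |m_DMR-3 − 50|) / 3

A sample with index strictly above 8.5 is called defect-positive,
14q-I(+).

The package is for epigenomics researchers who need this analysis as
tested, reusable code rather than spreadsheet arithmetic: it covers
bisulfite clone methylation calling with conversion QC and two-allele
pattern detection, reference-range defect classification, cohort
statistics (locus vs LINE-1 demethylation, cross-locus and parent–child
correlations, group tests), ΔΔCt expression and ChIP-qPCR normalization,
Kaplan–Meier/log-rank survival stratified by index, and a synthetic
study generator so every stage is testable without patient data.

## Worked example

Simulate a study-scale cohort, score it, and compare locus-specific
against genome-wide (LINE-1) demethylation:

```r
library(imprintscore)

cfg   <- SimulationConfig(nPerGroup = 30, seed = 42)
meth  <- simulateCohort(cfg)          # long table: sample, locus, dmr, %
scores <- scoreSamples(meth)          # deviations, 14q-index, call

head(scores[, c("sample_id", "fourteen_q_index", "call")], 3)
#>         sample_id fourteen_q_index     call
#> 1 early_onset_001         15.28266 positive
#> 2 early_onset_002         23.78770 positive
#> 3 early_onset_003         29.18223 positive

classificationSummary(scores$call, scores$group)
#>         group n_total n_positive percent_positive percent_positive_exact
#> 1 early_onset      30         30              100              100.00000
#> 2  late_onset      30         16               53               53.33333
#> 3      normal      30          5               17               16.66667

demethylationExtent(meth, groups = "early_onset")$groupMeans
#>         group locus      delta
#> 1 early_onset 14q32 19.5305819
#> 2 early_onset   H19  0.1682199
#> 3 early_onset LINE1  4.8523851
#> 4 early_onset  MEST -2.7736880
#> 5 early_onset  PEG3  1.0434275
```

The early-onset group loses ~19.5 percentage points of methylation at the
14q32 DMRs but only ~4.9 at LINE-1, the genome-wide surrogate — the
locus-specific signature, flagged by the accompanying Welch test
(t = 11.5, p = 3.7e-15). The index formula itself:

```r
fourteenQIndex(31, 35, 45)   # deviations 19, 15, 5
#> [1] 13
```

`runPipeline()` chains read → score → compare → survive on files and
writes scores, classification, demethylation, KM tables and a provenance
manifest; `inst/cli/imprintscore.R` wraps it for the shell
(`simulate`, `callmeth`, `score`, `run` subcommands).

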