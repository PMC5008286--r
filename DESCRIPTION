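Package: imprintscore
Title: Quantifying Loss of Imprinting at the 14q32 (DLK1-DIO3) Locus
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying imprinting defects at differentially
    methylated regions (DMRs), built around the 14q-index: the mean absolute
    deviation of 14q32 DMR methylation from the 50% level expected under
    monoallelic methylation. Provides bisulfite clone methylation calling with
    conversion QC and two-allele pattern detection, reference-range based
    defect classification, cohort statistics (locus versus LINE-1
    demethylation, cross-locus and parent-child correlations, group tests),
    qPCR delta-delta-Ct relative expression and ChIP-qPCR enrichment
    normalization, Kaplan-Meier survival stratified by index, and a synthetic
    cohort generator emulating the statistical structure of osteosarcoma
    methylation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Survival, Software
RoxygenNote: 7.3.3
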