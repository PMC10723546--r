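Package: renalwgs
Title: Somatic Whole-Genome Analysis Toolkit for Renal Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("GEL", "Renal Analysis", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable implementations of the bespoke computational stages of a
    whole-genome-sequencing study of clear cell renal cell carcinoma: somatic
    call curation (germline-proximal indel filtering, multi-caller structural
    variant consensus, mutational burden), negative-binomial recurrence testing
    of non-coding elements with trinucleotide-context background, driver
    co-occurrence analysis, rearrangement hotspot detection by covariate-
    adjusted piecewise constant fitting with fragile-site exclusion, molecular
    and chronological timing of copy-number gains and whole-genome duplication,
    genome-instability metrics, and genetic immune-evasion classification.
    Includes a synthetic tumour-cohort generator with full ground truth so the
    entire pipeline is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
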