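Package: parpicompare
Title: Comparing Predictive Biomarkers of PARP-Inhibitor Response from
    Genomic Scars and Gene-Set Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing candidate predictive biomarkers of
    PARP-inhibitor (PARPi) response in colorectal cancer. Computes genomic
    scar scores (large-scale state transitions, telomeric allelic imbalance,
    loss of heterozygosity, their HRD aggregate, fraction genome altered and
    an arm-level aneuploidy score) from copy-number segment (SEG) files;
    runs a from-scratch gene set enrichment analysis (signal-to-noise
    ranking, weighted running-sum enrichment score, phenotype or gene-set
    permutation null, NES and FDR q); compares biomarkers through a
    Fisher-z differential enrichment-score test and a gene-set
    enrichment-fraction (GSEF) Wilcoxon signed-rank comparison; and
    simulates seeded synthetic cohorts (segments, expression, gene sets)
    with planted ground truth so that the whole pipeline is testable
    end-to-end without external data. Reads and writes SEG, GCT, CLS and
    GMT formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
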