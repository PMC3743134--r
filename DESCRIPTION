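Package: pausekit
Title: RNA Polymerase II Pausing Analysis for Staged Embryo ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A staged ChIP-seq analysis pipeline for quantifying RNA
    polymerase II promoter-proximal pausing across the Drosophila
    midblastula transition (MBT). Provides artifact-filtered per-base
    coverage from aligned reads, input-normalized region enrichments and
    the pausing (stalling) index, multi-criteria identification and
    classification of pre-MBT and MBT gene groups, IUPAC core-promoter
    element scanning with exact-test and resampling enrichment
    statistics, anchored metapeak and TSS group-average profiles, and
    gene-structure, conservation and expression-pattern group statistics.
    Includes a synthetic-data generator that emulates the statistical
    structure of the study inputs so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
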