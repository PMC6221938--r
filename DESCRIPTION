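Package: liquidbiopsy
Title: Tumor-Informed Liquid Biopsy Analysis: Variant Selection, ddPCR
    Quantification and Fixed-Bin Copy-Number Profiling
Version: 0.1.0
Authors@R: person("Plasma", "Pipelines", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for tumor-informed circulating tumor DNA (ctDNA) analysis
    in plasma cell-free DNA. Implements the somatic variant
    filter-and-prioritize cascade that reduces a patient's exome variant
    list to a single droplet-digital-PCR (ddPCR) trackable target;
    Poisson-corrected ddPCR quantification (mean molecules per droplet,
    variant allele fraction, copies per mL plasma, positivity calling and
    per-sample detection limit); a fixed 50 kb-bin copy-number pipeline
    (genome binning, read counting, tumor/normal logR, profile correlation
    and chromosomal-instability scoring); a per-patient report pipeline; and
    synthetic-data generators with known ground truth so every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    optparse,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
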