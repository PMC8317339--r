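Package: errprofiler
Title: Background Substitution Error Profiling for UMI-Based Targeted Deep Sequencing
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes background substitution errors in targeted deep
    sequencing of cell-free DNA (cfDNA) and matched cellular genomic DNA.
    Streams per-base observations from aligned reads restricted to a capture
    panel, groups reads into UMI families and collapses them to consensus
    calls (digital error suppression), applies quality / depth / paired
    allele-frequency filters to isolate background errors, and estimates
    error rates across the 12 directional (6 strand-collapsed) substitution
    classes, per genomic position, and in 5-bp bins relative to the DNA
    fragment breakpoint. Includes group comparison statistics
    (cfDNA versus gDNA), trinucleotide-context spectra with non-negative
    signature refitting, and a synthetic read- and count-level data
    generator with a ledger of planted truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    GenomicAlignments,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
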