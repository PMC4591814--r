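Package: tlsbypass
Title: Quantification of Translesion DNA Synthesis Primer-Extension Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying translesion DNA synthesis (TLS)
    primer-extension assays read out on denaturing polyacrylamide gels.
    Implements the band-intensity statistics used to characterize lesion
    bypass by DNA polymerases (per-position termination, insertion,
    extension and bypass probabilities; bypass efficiency of a damaged
    template relative to its undamaged control; percent primer extension
    for nucleotide-selectivity assays), a generative model of processive
    primer extension with Poisson-distributed polymerase re-engagement
    for producing synthetic gel lanes, parameter recovery with bootstrap
    confidence intervals, and readers and writers for lane tables,
    substrate descriptions and simulation configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
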