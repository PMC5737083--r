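Package: sirmut
Title: Short Inverted Repeats and Localized Somatic Mutability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects short inverted repeats (SIRs) in genomic sequence,
    quantifies domain-dependent somatic mutability (hairpin loop/spacer versus
    stem/arm versus flanking control sequence), calls highly mutated SIRs and
    SIR hotspots with an exact binomial test and Benjamini-Hochberg correction,
    and classifies tumor samples (mismatch-repair deficient, APOBEC-driven)
    from hotspot mutation counts. Ships a synthetic genome and mutation-catalog
    generator with ground-truth manifests so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
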