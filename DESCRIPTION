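Package: stackvip
Title: DNA Base-Stack Ionization Potentials and Single Base Substitution Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links the vertical ionization potential (vIP) of DNA nucleobase
    stack motifs to the normalized frequency and pathogenicity of single base
    substitutions (SBSs) in gene regions. Provides vIP tables for bases and
    base-stack motifs, strand-aware extraction of the sequence context around
    substitution sites, region-specific motif counting and normalized SBS
    frequencies, transition/transversion ratios, inverse-polynomial non-linear
    correlation, Fisher z significance tests, a pathogenic-minus-benign
    frequency contrast, 5'-3' flank asymmetry statistics, and a synthetic-data
    generator that plants a vIP-coupled mutation process so the whole pipeline
    can be exercised and calibrated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stringi,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
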