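Package: scarkit
Title: Species-Specific SCAR Marker Design and DNA-Barcode Authentication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for DNA-barcode-based authentication of biological
    material, built around nrDNA-ITS reference panels. From an aligned
    multi-species barcode panel it discovers species-diagnostic substitution
    and indel sites, designs species-specific SCAR (sequence characterized
    amplified region) primer pairs under duplex-marker constraints, validates
    them by in-silico PCR against all panel templates, summarises intra- and
    inter-specific sequence variability under p and Kimura two-parameter
    distances, builds neighbor-joining trees with bootstrap support, analyses
    real-time PCR standard curves (slope, R-squared, amplification efficiency,
    limit of detection), and authenticates unknown samples by a virtual SCAR
    assay combined with nearest-reference classification. A synthetic panel
    generator with recorded ground truth supports fully offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
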