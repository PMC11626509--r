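Package: chimeraframe
Title: Reading-Frame and Domain-Retention Annotation of Fusion Transcript Breakpoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for harmonizing literature-derived fusion transcript
    breakpoints onto named mRNA reference sequences and annotating each
    junction for reading-frame preservation, 3'-UTR fusion geometry,
    premature stop codons, predicted chimeric protein sequence, and
    protein-domain retention. Includes cohort summary statistics with
    explicit denominators, plot-ready breakpoint distributions, a
    deterministic synthetic-cohort simulator with ground-truth labels for
    end-to-end validation, and small quantitation helpers for common
    normalization schemes (delta-Ct relative expression, two-anchor percent
    normalization, Sidak adjustment, ellipsoid tumor volume, and
    area-scaled stain quantitation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Biostrings,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    patchwork
Config/testthat/edition: 3
RoxygenNote: 7.3.3
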