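#' chimeraframe: fusion-transcript breakpoint annotation
#'
#' Harmonizes literature-derived fusion breakpoints onto mRNA reference
#' coordinates and classifies each junction for reading-frame preservation,
#' UTR-fusion geometry, premature stops, and protein-domain retention, with
#' cohort summaries, a ground-truth simulator, and assay quantitation
#' helpers.
#'
#' @keywords internal
"_PACKAGE"

utils::globalVariables(c("five_prime_last_base", "three_prime_first_base",
                         "category", "nt_start", "nt_end", "x", "y", "id",
                         "partner", "gene"))
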