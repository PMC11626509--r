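#' Classify a fusion breakpoint pair
#'
#' Determines the category of a chimeric transcript from the two junction
#' coordinates. The junction is encoded as (last retained base of the 5'
#' partner, first retained base of the 3' partner), 1-based on the
#' respective mRNA references, with ambiguous junction bases already
#' assigned (see [assignAmbiguousBases()]).
#'
#' Decision order:
#' \enumerate{
#'   \item `bp5 < cdsStart(ref5)`: `five_prime_noncoding` — no 5' coding
#'     sequence is retained.
#'   \item `bp5 >= cdsEnd(ref5)`: `five_prime_readthrough` — the 5'
#'     partner's own stop codon is retained, so no fusion protein extends
#'     beyond it.
#'   \item 3' breakpoint in the 3' UTR of the 3' partner: `utr_fusion`
#'     (the hallmark of 5'-partner::UTR fusions, which typically truncate
#'     the 5' protein at a stop shortly after the junction).
#'   \item 3' breakpoint in the 5' UTR of the 3' partner:
#'     `three_prime_upstream_of_cds`; the reading frame outcome is only
#'     defined by full-chimera translation ([predictFusionProtein()]).
#'   \item both breakpoints in CDS: in-frame iff the junction phases
#'     match, i.e. `n5_cds mod 3 == (p3_cds - 1) mod 3` where
#'     `n5_cds = bp5 - cdsStart(ref5) + 1` is the retained 5' CDS length
#'     and `p3_cds = bp3 - cdsStart(ref3) + 1` the CDS entry position.
#' }
#'
#' @param ref5,ref3 [TranscriptReference-class] objects for the 5' and 3'
#'   partners.
#' @param bp5 Last retained base of the 5' partner (transcript coordinate).
#' @param bp3 First retained base of the 3' partner.
#' @return A [FusionAnnotation-class] with category and phases; domain
#'   status and protein slots are filled by [domainStatusGenomic()],
#'   [domainStatusProtein()] and [predictFusionProtein()] (or use
#'   [annotateDatabase()] for the full pipeline).
#' @export
classifyFusion <- function(ref5, bp5, ref3, bp3) {
  stopifnot(is(ref5, "TranscriptReference"), is(ref3, "TranscriptReference"))
  bp5 <- as.integer(bp5); bp3 <- as.integer(bp3)
  if (is.na(bp5) || bp5 < 1L || bp5 > length(ref5))
    stop(sprintf("5' coordinate %s outside [1, %d] of %s", bp5, length(ref5),
                 accession(ref5)))
  if (is.na(bp3) || bp3 < 1L || bp3 > length(ref3))
    stop(sprintf("3' coordinate %s outside [1, %d] of %s", bp3, length(ref3),
                 accession(ref3)))
  ann <- function(category, n5 = NA_integer_, ph5 = NA_integer_,
                  p3 = NA_integer_, ph3 = NA_integer_)
    new("FusionAnnotation", category = category, n5Cds = n5, phase5 = ph5,
        p3Cds = p3, phase3 = ph3)
  if (bp5 < cdsStart(ref5)) return(ann("five_prime_noncoding"))
  if (bp5 >= cdsEnd(ref5)) return(ann("five_prime_readthrough"))
  loc3 <- locateNt(ref3, bp3)
  if (loc3$region == "three_prime_utr") {
    n5 <- bp5 - cdsStart(ref5) + 1L
    return(ann("utr_fusion", n5 = n5, ph5 = n5 %% 3L))
  }
  if (loc3$region == "five_prime_utr") {
    n5 <- bp5 - cdsStart(ref5) + 1L
    return(ann("three_prime_upstream_of_cds", n5 = n5, ph5 = n5 %% 3L))
  }
  n5 <- bp5 - cdsStart(ref5) + 1L
  p3 <- loc3$cds_pos
  ph5 <- n5 %% 3L
  ph3 <- (p3 - 1L) %% 3L
  ann(if (ph5 == ph3) "in_frame_coding" else "out_of_frame_coding",
      n5 = n5, ph5 = ph5, p3 = p3, ph3 = ph3)
}

#' Predict the chimeric protein of a fusion transcript
#'
#' Builds the chimeric mRNA `ref5[1..bp5] ++ ref3[bp3..end]`, translates
#' from the 5' partner's CDS start, and reports the protein sequence up to
#' the first in-frame stop codon together with the stop's origin:
#' `native_3prime` when the terminating stop is the 3' partner's own stop
#' codon read in its native frame, `premature` for any other stop
#' (including the 5' partner's retained stop and stops encountered in
#' fused UTR sequence), or `none_found` when translation runs off the end
#' of the chimera. `junctionToStopNt` is the distance from the junction
#' (last 5'-retained base) to the first base of the stop codon — the
#' quantity behind "stop codons shortly after the breakpoint" in
#' UTR-fusion biology.
#'
#' A junction-spanning hybrid codon (when `n5_cds mod 3 != 0`) is assigned
#' to the junction residue, `junctionResidueIndex = floor(n5_cds/3) + 1`.
#'
#' @inheritParams classifyFusion
#' @return A [ProteinPrediction-class].
#' @export
predictFusionProtein <- function(ref5, bp5, ref3, bp3) {
  stopifnot(is(ref5, "TranscriptReference"), is(ref3, "TranscriptReference"))
  bp5 <- as.integer(bp5); bp3 <- as.integer(bp3)
  if (bp5 < 1L || bp5 > length(ref5) || bp3 < 1L || bp3 > length(ref3))
    stop("breakpoint coordinate out of bounds")
  if (bp5 < cdsStart(ref5))
    stop("no 5' coding sequence retained (five_prime_noncoding); no protein is predicted")
  chimera <- paste0(substr(as.character(refSequence(ref5)), 1L, bp5),
                    substr(as.character(refSequence(ref3)), bp3,
                           length(ref3)))
  tr <- translateFrom(chimera, cdsStart(ref5))
  n5 <- bp5 - cdsStart(ref5) + 1L
  jri <- min(n5 %/% 3L + 1L, nchar(tr$protein) + 1L)
  if (!tr$stop_found) {
    return(new("ProteinPrediction", sequence = tr$protein,
               junctionResidueIndex = jri, stopOrigin = "none_found",
               junctionToStopNt = NA_integer_))
  }
  # chimeric position of the first base of the 3' partner's own stop codon
  native_stop3 <- bp5 + (cdsEnd(ref3) - 2L - bp3 + 1L)
  origin <- if (bp3 <= cdsEnd(ref3) - 2L && tr$stop_nt == native_stop3)
    "native_3prime" else "premature"
  new("ProteinPrediction", sequence = tr$protein,
      junctionResidueIndex = jri, stopOrigin = origin,
      junctionToStopNt = tr$stop_nt - bp5)
}
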