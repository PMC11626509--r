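#' Convert a protein residue range to a transcript nucleotide interval
#'
#' Maps 1-based inclusive protein residues onto the 1-based inclusive
#' transcript coordinates of their codons:
#' `nt_start = cdsStart + 3*(residueStart - 1)` and
#' `nt_end = cdsStart + 3*residueEnd - 1`. Domain annotations are stored in
#' residue space, while breakpoints are nucleotide-denominated; this is the
#' bridge between the two.
#'
#' @param ref A [TranscriptReference-class].
#' @param residueStart,residueEnd 1-based inclusive residue range within the
#'   protein (the stop codon is not a residue).
#' @return Integer vector `c(nt_start, nt_end)`, length `3*(residueEnd -
#'   residueStart + 1)`.
#' @examples
#' ref <- makeToyReference("TOY", utr5Len = 9, nCodons = 10, utr3Len = 5,
#'                         seed = 1)
#' residueToNt(ref, 1, 1)  # first codon: c(10, 12)
#' @export
residueToNt <- function(ref, residueStart, residueEnd = residueStart) {
  stopifnot(is(ref, "TranscriptReference"))
  nres <- proteinLength(ref)
  if (residueStart < 1L || residueEnd < residueStart || residueEnd > nres)
    stop(sprintf("residue range %d..%d outside protein [1, %d] of %s",
                 residueStart, residueEnd, nres, accession(ref)))
  c(nt_start = cdsStart(ref) + 3L * (as.integer(residueStart) - 1L),
    nt_end = cdsStart(ref) + 3L * as.integer(residueEnd) - 1L)
}

#' Locate a transcript coordinate relative to the CDS
#'
#' Classifies a 1-based transcript position as 5' UTR, CDS (with CDS
#' position and reading-frame phase), or 3' UTR. Phase is
#' `(nt - cdsStart) mod 3`, so the first base of the start codon has
#' phase 0. UTR membership of the 3'-partner breakpoint is the hinge of
#' the UTR-fusion call.
#'
#' @param ref A [TranscriptReference-class].
#' @param nt 1-based transcript coordinate.
#' @return A list with `region` ("five_prime_utr", "cds", or
#'   "three_prime_utr") and, for CDS positions, integer `cds_pos` and
#'   `phase`; both NA otherwise.
#' @export
locateNt <- function(ref, nt) {
  stopifnot(is(ref, "TranscriptReference"))
  nt <- as.integer(nt)
  if (is.na(nt) || nt < 1L || nt > length(ref))
    stop(sprintf("coordinate %s outside sequence [1, %d] of %s",
                 nt, length(ref), accession(ref)))
  if (nt < cdsStart(ref))
    list(region = "five_prime_utr", cds_pos = NA_integer_, phase = NA_integer_)
  else if (nt > cdsEnd(ref))
    list(region = "three_prime_utr", cds_pos = NA_integer_, phase = NA_integer_)
  else
    list(region = "cds",
         cds_pos = nt - cdsStart(ref) + 1L,
         phase = (nt - cdsStart(ref)) %% 3L)
}

#' Translate a nucleotide string up to the first stop codon
#'
#' Standard genetic code. Codons containing N translate to `"X"` and never
#' count as stop codons; a trailing partial codon is ignored. Translation
#' stops at, and excludes, the first stop codon.
#'
#' @param seq Character or [Biostrings::DNAString] nucleotide sequence
#'   (mRNA sense).
#' @param start 1-based offset of the first codon.
#' @return List with `protein` (character), `stop_found` (logical), and
#'   `stop_nt` (1-based position in `seq` of the first base of the stop
#'   codon; NA when no stop was reached).
#' @examples
#' translateFrom("ATGGAATAA", 1)  # list(protein = "ME", stop_found = TRUE, ...)
#' @export
translateFrom <- function(seq, start = 1L) {
  seq <- as.character(seq)
  start <- as.integer(start)
  stopifnot(start >= 1L)
  n <- nchar(seq)
  if (start > n)
    return(list(protein = "", stop_found = FALSE, stop_nt = NA_integer_))
  ncod <- (n - start + 1L) %/% 3L
  if (ncod == 0L)
    return(list(protein = "", stop_found = FALSE, stop_nt = NA_integer_))
  starts <- start + 3L * (seq_len(ncod) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"  # any codon containing N (or other ambiguity)
  stop_idx <- which(aa == "*")
  if (length(stop_idx)) {
    k <- stop_idx[1L]
    list(protein = paste(aa[seq_len(k - 1L)], collapse = ""),
         stop_found = TRUE, stop_nt = starts[k])
  } else {
    list(protein = paste(aa, collapse = ""), stop_found = FALSE,
         stop_nt = NA_integer_)
  }
}
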