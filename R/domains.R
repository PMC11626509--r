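#' Domain retention status from breakpoint position alone
#'
#' Compares a breakpoint to a domain's nucleotide interval
#' `(d_s, d_e) = residueToNt(ref, domain)` on the same reference:
#' \itemize{
#'   \item 5' side (breakpoint = last retained base): `retained` iff
#'     `bp >= d_e`; `disrupted` iff `d_s <= bp < d_e`; `lost` iff `bp < d_s`.
#'   \item 3' side (breakpoint = first retained base): `retained` iff
#'     `bp <= d_s`; `disrupted` iff `d_s < bp <= d_e`; `lost` iff `bp > d_e`.
#' }
#' A 5' breakpoint exactly at the domain's last nucleotide counts as
#' retained: the last retained base then covers the domain's final codon,
#' so the full domain is present (this is the "breakpoint after the 3' end
#' of the domain" convention for domain-retaining fusions).
#'
#' @param ref The [TranscriptReference-class] carrying the domain.
#' @param domainName Name of a domain annotated on `ref`, or a one-row
#'   data.frame/list with `residueStart`, `residueEnd`.
#' @param bp Breakpoint transcript coordinate on `ref`.
#' @param side `"five_prime"` or `"three_prime"`: which partner `ref` is.
#' @return `"retained"`, `"disrupted"`, or `"lost"`.
#' @export
domainStatusGenomic <- function(ref, domainName, bp,
                                side = c("five_prime", "three_prime")) {
  side <- match.arg(side)
  dom <- resolve_domain(ref, domainName)
  nt <- residueToNt(ref, dom$residueStart, dom$residueEnd)
  bp <- as.integer(bp)
  if (bp < 1L || bp > length(ref))
    stop(sprintf("breakpoint %d outside reference %s", bp, accession(ref)))
  d_s <- nt[["nt_start"]]; d_e <- nt[["nt_end"]]
  if (side == "five_prime") {
    if (bp >= d_e) "retained" else if (bp >= d_s) "disrupted" else "lost"
  } else {
    if (bp <= d_s) "retained" else if (bp <= d_e) "disrupted" else "lost"
  }
}

#' Domain retention status from the predicted protein
#'
#' Scores a domain by which of its residues are present \emph{with their
#' native identities} in the predicted chimeric protein: all residues
#' present -> `retained`; some -> `disrupted`; none -> `lost`. Unlike
#' [domainStatusGenomic()], this sees premature stop codons — a UTR fusion
#' whose stop falls inside a 5'-partner domain demotes that domain even
#' though the breakpoint itself lies beyond it. A residue translated as
#' `"X"` (ambiguous bases in the codon) is conservatively counted as not
#' native, so an X inside the range demotes retained to disrupted.
#'
#' A residue counts as natively present when its codon is derived entirely
#' from the partner's own sequence, it falls on the chimeric reading-frame
#' grid at its native frame, its position precedes any premature stop, and
#' the translated amino acid equals the native one.
#'
#' @param prediction A [ProteinPrediction-class] for this breakpoint pair
#'   (from [predictFusionProtein()]).
#' @param ref The [TranscriptReference-class] carrying the domain.
#' @param domainName As in [domainStatusGenomic()].
#' @param bp Breakpoint coordinate on `ref` (same convention as `side`).
#' @param side `"five_prime"` or `"three_prime"`.
#' @param cdsStart5,bp5 For `side = "three_prime"`: the 5' partner's CDS
#'   start and breakpoint, needed to place 3' residues on the chimeric
#'   grid. Ignored for the 5' side.
#' @return `"retained"`, `"disrupted"`, or `"lost"`.
#' @export
domainStatusProtein <- function(prediction, ref, domainName, bp,
                                side = c("five_prime", "three_prime"),
                                cdsStart5 = NULL, bp5 = NULL) {
  side <- match.arg(side)
  stopifnot(is(prediction, "ProteinPrediction"))
  dom <- resolve_domain(ref, domainName)
  native <- translateFrom(substr(as.character(refSequence(ref)),
                                 cdsStart(ref), cdsEnd(ref)), 1L)$protein
  pred <- prediction@sequence
  plen <- nchar(pred)
  residues <- seq(dom$residueStart, dom$residueEnd)
  bp <- as.integer(bp)
  if (side == "five_prime") {
    present <- vapply(residues, function(r) {
      codon_end <- cdsStart(ref) + 3L * r - 1L
      codon_end <= bp && r <= plen &&
        substr(pred, r, r) == substr(native, r, r)
    }, logical(1))
  } else {
    if (is.null(cdsStart5) || is.null(bp5))
      stop("three_prime side needs cdsStart5 and bp5 to place residues on the chimeric grid")
    cdsStart5 <- as.integer(cdsStart5); bp5 <- as.integer(bp5)
    present <- vapply(residues, function(r) {
      codon_start <- cdsStart(ref) + 3L * (r - 1L)
      if (codon_start < bp) return(FALSE)        # codon (partially) lost
      q <- bp5 + (codon_start - bp + 1L)         # chimeric position
      if ((q - cdsStart5) %% 3L != 0L) return(FALSE)  # off the chimeric grid
      idx <- (q - cdsStart5) %/% 3L + 1L
      idx <= plen && substr(pred, idx, idx) == substr(native, r, r)
    }, logical(1))
  }
  if (all(present)) "retained" else if (any(present)) "disrupted" else "lost"
}

resolve_domain <- function(ref, domainName) {
  if (is.character(domainName)) {
    d <- domains(ref)
    hit <- which(d$name == domainName)
    if (length(hit) != 1L)
      stop(sprintf("domain '%s' not annotated (exactly once) on %s",
                   domainName, accession(ref)))
    as.list(d[hit, ])
  } else {
    dom <- as.list(domainName)
    stopifnot(!is.null(dom$residueStart), !is.null(dom$residueEnd))
    dom
  }
}
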