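#' @import methods
#' @importFrom Biostrings DNAString GENETIC_CODE
NULL

setClassUnion("DataFrameOrNULL", c("data.frame", "NULL"))

#' TranscriptReference: an mRNA reference with CDS and domain annotation
#'
#' Represents a single transcript reference sequence in mRNA sense (5'->3'),
#' the coordinate system that all breakpoint arithmetic maps onto. The CDS
#' span is 1-based inclusive and includes the stop codon; protein-domain
#' annotations are stored in protein-residue space and converted to
#' nucleotide intervals on demand with [residueToNt()].
#'
#' @slot accession Character, e.g. "NM_015125.5".
#' @slot geneSymbol Character gene symbol.
#' @slot sequence A [Biostrings::DNAString] over {A,C,G,T,N}.
#' @slot cdsStart Integer, transcript coordinate of the first base of the
#'   start codon.
#' @slot cdsEnd Integer, transcript coordinate of the last base of the stop
#'   codon; `(cdsEnd - cdsStart + 1)` must be a multiple of 3.
#' @slot domains data.frame with columns `name`, `residueStart`,
#'   `residueEnd`, `source`; residue ranges are 1-based inclusive and must
#'   lie within the translated protein.
#' @slot exons Optional data.frame with columns `start`, `end`: disjoint,
#'   sorted 1-based intervals tiling the transcript. NULL when unknown.
#' @slot internalStop Logical flag set when the CDS translation contains an
#'   internal stop codon (tolerated with a warning only when the offending
#'   codon contains N).
#'
#' @seealso [readTranscriptReference()], [makeToyReference()], [locateNt()]
#' @export
setClass("TranscriptReference",
  representation(
    accession = "character",
    geneSymbol = "character",
    sequence = "DNAString",
    cdsStart = "integer",
    cdsEnd = "integer",
    domains = "data.frame",
    exons = "DataFrameOrNULL",
    internalStop = "logical"
  ),
  prototype(
    domains = data.frame(name = character(), residueStart = integer(),
                         residueEnd = integer(), source = character(),
                         stringsAsFactors = FALSE),
    exons = NULL,
    internalStop = FALSE
  )
)

setValidity("TranscriptReference", function(object) {
  msg <- character()
  len <- length(object@sequence)
  if (length(object@accession) != 1L || !nzchar(object@accession))
    msg <- c(msg, "accession must be a single non-empty string")
  cs <- object@cdsStart; ce <- object@cdsEnd
  if (!(1L <= cs && cs < ce && ce <= len))
    msg <- c(msg, sprintf("CDS span %d..%d invalid for sequence of length %d",
                          cs, ce, len))
  else {
    if ((ce - cs + 1L) %% 3L != 0L)
      msg <- c(msg, sprintf("CDS length %d not divisible by 3", ce - cs + 1L))
    nres <- (ce - cs + 1L) %/% 3L - 1L
    d <- object@domains
    if (nrow(d)) {
      bad <- d$residueStart < 1L | d$residueStart > d$residueEnd |
        d$residueEnd > nres
      if (any(bad))
        msg <- c(msg, sprintf("domain(s) %s outside protein [1, %d]",
                              paste(d$name[bad], collapse = ", "), nres))
    }
  }
  ex <- object@exons
  if (!is.null(ex) && nrow(ex)) {
    ex <- ex[order(ex$start), , drop = FALSE]
    ok <- ex$start[1] == 1L && ex$end[nrow(ex)] == len &&
      all(ex$start <= ex$end) &&
      (nrow(ex) == 1L || all(ex$start[-1] == ex$end[-nrow(ex)] + 1L))
    if (!ok) msg <- c(msg, "exons must be disjoint, sorted, and tile [1, length]")
  }
  bad_letters <- setdiff(strsplit(as.character(object@sequence), "")[[1]],
                         c("A", "C", "G", "T", "N"))
  if (length(bad_letters))
    msg <- c(msg, sprintf("sequence contains letters outside {A,C,G,T,N}: %s",
                          paste(unique(bad_letters), collapse = "")))
  if (length(msg)) msg else TRUE
})

#' HarmonizedDatabase: a harmonized collection of breakpoint records
#'
#' One row of `records` per literature-derived fusion junction, in the
#' harmonized schema: partner genes, evidence source, resolution, 1-based
#' transcript coordinates (`five_prime_last_base` = last retained base of the
#' 5' partner; `three_prime_first_base` = first retained base of the 3'
#' partner), ambiguous junction bases, and accessions. Rows rejected during
#' parsing are retained in `rejects` with a reason, never silently dropped.
#'
#' @slot records data.frame of accepted [breakpoint records][readBreakpointTable].
#' @slot rejects data.frame of rejected rows with a `reject_reason` column.
#' @slot provenance Character vector of free-text provenance notes
#'   (source file, harmonization and filtering steps).
#' @export
setClass("HarmonizedDatabase",
  representation(records = "data.frame", rejects = "data.frame",
                 provenance = "character"),
  prototype(rejects = data.frame(), provenance = character())
)

setValidity("HarmonizedDatabase", function(object) {
  rec <- object@records
  need <- c("case_id", "publication_id", "five_prime_gene", "three_prime_gene",
            "evidence_source", "resolution", "five_prime_last_base",
            "three_prime_first_base", "ambiguous_junction_bases",
            "five_prime_accession", "three_prime_accession", "notes")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    return(sprintf("records missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(rec$case_id))
    return("case_id values must be unique")
  if (nrow(rec)) {
    if (!all(rec$resolution %in% c("nucleotide", "exon")))
      return("resolution must be 'nucleotide' or 'exon'")
    if (!all(rec$evidence_source %in% c("RNA", "DNA", "unknown")))
      return("evidence_source must be RNA, DNA or unknown")
    nuc <- rec$resolution == "nucleotide"
    if (any(nuc & is.na(rec$five_prime_last_base) &
              is.na(rec$three_prime_first_base)))
      return("nucleotide-level records need at least one coordinate")
    amb <- rec$ambiguous_junction_bases
    amb[is.na(amb)] <- ""
    if (any(grepl("[^ACGTN]", amb)))
      return("ambiguous_junction_bases alphabet must be within {A,C,G,T,N}")
  }
  TRUE
})

#' ProteinPrediction: the predicted chimeric protein of a fusion
#'
#' @slot sequence Character amino-acid string, up to and excluding the first
#'   in-frame stop codon.
#' @slot junctionResidueIndex 1-based residue index at/after which
#'   junction-derived or 3'-derived sequence begins; a junction-spanning
#'   hybrid codon is assigned to this residue.
#' @slot stopOrigin One of `"native_3prime"` (the terminating stop is the 3'
#'   partner's own stop codon read in its native frame), `"premature"`, or
#'   `"none_found"` (translation ran off the end of the chimera).
#' @slot junctionToStopNt Nucleotide distance from the junction (last 5'
#'   retained base) to the first base of the first in-frame stop; NA when no
#'   stop was found.
#' @export
setClass("ProteinPrediction",
  representation(sequence = "character",
                 junctionResidueIndex = "integer",
                 stopOrigin = "character",
                 junctionToStopNt = "integer")
)

setValidity("ProteinPrediction", function(object) {
  if (!object@stopOrigin %in% c("native_3prime", "premature", "none_found"))
    return("stopOrigin must be native_3prime, premature or none_found")
  if (object@junctionResidueIndex > nchar(object@sequence) + 1L)
    return("junctionResidueIndex exceeds protein length + 1")
  TRUE
})

#' FusionAnnotation: the classification of one breakpoint pair
#'
#' @slot category One of `in_frame_coding`, `out_of_frame_coding`,
#'   `utr_fusion`, `five_prime_noncoding`, `five_prime_readthrough`,
#'   `three_prime_upstream_of_cds`.
#' @slot n5Cds Count of 5'-partner CDS nucleotides retained (NA outside the
#'   both-in-CDS geometry).
#' @slot phase5,phase3 Junction phases in {0,1,2}; NA when undefined.
#' @slot p3Cds 1-based CDS position of the first retained 3' base; NA when
#'   the 3' breakpoint is not in the CDS.
#' @slot domainStatusGenomic Named character vector, domain ->
#'   {retained, disrupted, lost}, from breakpoint position alone.
#' @slot domainStatusProtein Same codomain, computed from the predicted
#'   protein (sees premature stops that the genomic call cannot).
#' @slot protein A [ProteinPrediction-class] (may be an empty placeholder
#'   until [predictFusionProtein()] is run).
#' @export
setClass("FusionAnnotation",
  representation(category = "character",
                 n5Cds = "integer", phase5 = "integer",
                 p3Cds = "integer", phase3 = "integer",
                 domainStatusGenomic = "character",
                 domainStatusProtein = "character",
                 protein = "ProteinPrediction"),
  prototype(domainStatusGenomic = character(),
            domainStatusProtein = character(),
            protein = new("ProteinPrediction", sequence = "",
                          junctionResidueIndex = 1L,
                          stopOrigin = "none_found",
                          junctionToStopNt = NA_integer_))
)

.fusion_categories <- c("in_frame_coding", "out_of_frame_coding", "utr_fusion",
                        "five_prime_noncoding", "five_prime_readthrough",
                        "three_prime_upstream_of_cds")

setValidity("FusionAnnotation", function(object) {
  msg <- character()
  if (!object@category %in% .fusion_categories)
    msg <- c(msg, sprintf("unknown category '%s'", object@category))
  if (identical(object@category, "in_frame_coding") &&
      !isTRUE(object@phase5 == object@phase3))
    msg <- c(msg, "in_frame_coding requires phase5 == phase3")
  if (identical(object@category, "out_of_frame_coding") &&
      !isTRUE(object@phase5 != object@phase3))
    msg <- c(msg, "out_of_frame_coding requires phase5 != phase3")
  for (m in list(object@domainStatusGenomic, object@domainStatusProtein))
    if (length(m) && !all(m %in% c("retained", "disrupted", "lost")))
      msg <- c(msg, "domain status values must be retained/disrupted/lost")
  if (length(msg)) msg else TRUE
})

#' CohortSummary: cohort partition counts with explicit denominators
#'
#' Every fraction carries its numerator and denominator explicitly; display
#' rounding (round-half-up to integer percent) never alters the stored
#' values.
#'
#' @slot counts Named integer vector of partition counts.
#' @slot byPartner Named integer vector, 3' partner gene -> record count.
#' @slot domainRetained Named integer vector, domain -> retained count among
#'   the stated denominator (in-frame records of the analysis set).
#' @slot fractions data.frame with columns `name`, `numerator`,
#'   `denominator`, `value`, `display_pct`.
#' @slot filterProvenance Character description of the filters defining the
#'   analysis set, plus caveat notes.
#' @export
setClass("CohortSummary",
  representation(counts = "integer", byPartner = "integer",
                 domainRetained = "integer", fractions = "data.frame",
                 filterProvenance = "character")
)

setValidity("CohortSummary", function(object) {
  fr <- object@fractions
  if (nrow(fr)) {
    ok <- ifelse(fr$denominator == 0, fr$value == 0,
                 abs(fr$value - fr$numerator / fr$denominator) < 1e-12)
    if (!all(ok)) return("stored numerator/denominator must reproduce value")
  }
  cn <- object@counts
  need <- c("n_total_nucleotide", "n_total_exon", "n_analysis_set",
            "n_utr_fusion", "n_non_utr", "n_in_frame", "n_out_of_frame",
            "n_other_categories")
  miss <- setdiff(need, names(cn))
  if (length(miss))
    return(sprintf("counts missing: %s", paste(miss, collapse = ", ")))
  if (cn["n_analysis_set"] !=
      cn["n_utr_fusion"] + cn["n_non_utr"] + cn["n_other_categories"])
    return("analysis set must partition into UTR + non-UTR + other")
  if (cn["n_non_utr"] != cn["n_in_frame"] + cn["n_out_of_frame"])
    return("non-UTR records must partition into in-frame + out-of-frame")
  TRUE
})
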