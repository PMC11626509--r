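#' @rdname TranscriptReference-class
#' @aliases accession,TranscriptReference-method
#' @export
setMethod("accession", "TranscriptReference", function(x) x@accession)

#' @rdname TranscriptReference-class
#' @export
setMethod("geneSymbol", "TranscriptReference", function(x) x@geneSymbol)

#' @rdname TranscriptReference-class
#' @export
setMethod("refSequence", "TranscriptReference", function(x) x@sequence)

#' @rdname TranscriptReference-class
#' @export
setMethod("cdsStart", "TranscriptReference", function(x) x@cdsStart)

#' @rdname TranscriptReference-class
#' @export
setMethod("cdsEnd", "TranscriptReference", function(x) x@cdsEnd)

#' @rdname TranscriptReference-class
#' @export
setMethod("domains", "TranscriptReference", function(x) x@domains)

#' @rdname TranscriptReference-class
#' @export
setMethod("proteinLength", "TranscriptReference",
          function(x) (x@cdsEnd - x@cdsStart + 1L) %/% 3L - 1L)

#' @rdname TranscriptReference-class
#' @export
setMethod("length", "TranscriptReference", function(x) length(x@sequence))

#' @export
setMethod("show", "TranscriptReference", function(object) {
  cat(sprintf("TranscriptReference %s (%s)\n", object@accession,
              object@geneSymbol))
  cat(sprintf("  %d nt; CDS %d..%d (%d aa)\n", length(object@sequence),
              object@cdsStart, object@cdsEnd, proteinLength(object)))
  d <- object@domains
  if (nrow(d))
    cat(sprintf("  domains: %s\n",
                paste(sprintf("%s[%d-%d]", d$name, d$residueStart,
                              d$residueEnd), collapse = ", ")))
  if (object@internalStop)
    cat("  warning: internal stop codon in CDS translation\n")
})

#' @rdname HarmonizedDatabase-class
#' @export
setMethod("records", "HarmonizedDatabase", function(x) x@records)

#' @rdname HarmonizedDatabase-class
#' @export
setMethod("rejects", "HarmonizedDatabase", function(x) x@rejects)

#' @rdname HarmonizedDatabase-class
#' @export
setMethod("provenance", "HarmonizedDatabase", function(x) x@provenance)

#' @rdname HarmonizedDatabase-class
#' @export
setMethod("length", "HarmonizedDatabase", function(x) nrow(x@records))

#' @export
setMethod("show", "HarmonizedDatabase", function(object) {
  rec <- object@records
  cat(sprintf("HarmonizedDatabase: %d record(s), %d reject(s)\n",
              nrow(rec), nrow(object@rejects)))
  if (nrow(rec)) {
    tab <- table(rec$three_prime_gene)
    cat(sprintf("  partners: %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
    cat(sprintf("  resolution: %d nucleotide / %d exon\n",
                sum(rec$resolution == "nucleotide"),
                sum(rec$resolution == "exon")))
  }
  for (p in utils::head(object@provenance, 3)) cat("  # ", p, "\n", sep = "")
})

#' @rdname FusionAnnotation-class
#' @export
setMethod("fusionCategory", "FusionAnnotation", function(x) x@category)

#' @rdname FusionAnnotation-class
#' @export
setMethod("junctionPhases", "FusionAnnotation",
          function(x) c(phase5 = x@phase5, phase3 = x@phase3))

#' @rdname FusionAnnotation-class
#' @param view `"genomic"` (breakpoint position only) or `"protein"`
#'   (from the predicted protein).
#' @param ... unused.
#' @export
setMethod("domainStatus", "FusionAnnotation",
          function(x, view = c("genomic", "protein"), ...) {
  view <- match.arg(view)
  if (view == "genomic") x@domainStatusGenomic else x@domainStatusProtein
})

#' @export
setMethod("show", "FusionAnnotation", function(object) {
  cat(sprintf("FusionAnnotation: %s\n", object@category))
  cat(sprintf("  n5Cds=%s phase5=%s p3Cds=%s phase3=%s\n",
              object@n5Cds, object@phase5, object@p3Cds, object@phase3))
  g <- object@domainStatusGenomic
  if (length(g))
    cat(sprintf("  domains (genomic): %s\n",
                paste(sprintf("%s=%s", names(g), g), collapse = ", ")))
  if (nzchar(object@protein@sequence))
    cat(sprintf("  protein: %d aa, stop %s\n",
                nchar(object@protein@sequence), object@protein@stopOrigin))
})

#' @rdname ProteinPrediction-class
#' @export
setMethod("predictedSequence", "ProteinPrediction", function(x) x@sequence)

#' @rdname ProteinPrediction-class
#' @export
setMethod("stopOrigin", "ProteinPrediction", function(x) x@stopOrigin)

#' @export
setMethod("show", "ProteinPrediction", function(object) {
  s <- object@sequence
  cat(sprintf("ProteinPrediction: %d aa, junction at residue %d\n",
              nchar(s), object@junctionResidueIndex))
  cat(sprintf("  stop: %s (junction-to-stop %s nt)\n", object@stopOrigin,
              ifelse(is.na(object@junctionToStopNt), "NA",
                     object@junctionToStopNt)))
})

#' @rdname CohortSummary-class
#' @export
setMethod("summaryCounts", "CohortSummary", function(x) x@counts)

#' @rdname CohortSummary-class
#' @export
setMethod("summaryFractions", "CohortSummary", function(x) x@fractions)

#' @export
setMethod("show", "CohortSummary", function(object) {
  cn <- object@counts
  cat("CohortSummary\n")
  cat(sprintf("  nucleotide-level: %d, exon-level: %d\n",
              cn["n_total_nucleotide"], cn["n_total_exon"]))
  cat(sprintf("  analysis set: %d (UTR %d / in-frame %d / out-of-frame %d / other %d)\n",
              cn["n_analysis_set"], cn["n_utr_fusion"], cn["n_in_frame"],
              cn["n_out_of_frame"], cn["n_other_categories"]))
  fr <- object@fractions
  for (i in seq_len(nrow(fr)))
    cat(sprintf("  %s: %d of %d (%d%%)\n", fr$name[i], fr$numerator[i],
                fr$denominator[i], fr$display_pct[i]))
})
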