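#' @rdname TranscriptReference-class
#' @param object,x A TranscriptReference.
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))

#' @rdname TranscriptReference-class
#' @export
setGeneric("geneSymbol", function(x) standardGeneric("geneSymbol"))

#' @rdname TranscriptReference-class
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))

#' @rdname TranscriptReference-class
#' @export
setGeneric("cdsStart", function(x) standardGeneric("cdsStart"))

#' @rdname TranscriptReference-class
#' @export
setGeneric("cdsEnd", function(x) standardGeneric("cdsEnd"))

#' @rdname TranscriptReference-class
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname TranscriptReference-class
#' @export
setGeneric("proteinLength", function(x) standardGeneric("proteinLength"))

#' @rdname HarmonizedDatabase-class
#' @param x A HarmonizedDatabase.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname HarmonizedDatabase-class
#' @export
setGeneric("rejects", function(x) standardGeneric("rejects"))

#' @rdname HarmonizedDatabase-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname FusionAnnotation-class
#' @param x A FusionAnnotation or ProteinPrediction.
#' @export
setGeneric("fusionCategory", function(x) standardGeneric("fusionCategory"))

#' @rdname FusionAnnotation-class
#' @export
setGeneric("junctionPhases", function(x) standardGeneric("junctionPhases"))

#' @rdname FusionAnnotation-class
#' @export
setGeneric("domainStatus", function(x, ...) standardGeneric("domainStatus"))

#' @rdname ProteinPrediction-class
#' @param x A ProteinPrediction.
#' @export
setGeneric("predictedSequence", function(x) standardGeneric("predictedSequence"))

#' @rdname ProteinPrediction-class
#' @export
setGeneric("stopOrigin", function(x) standardGeneric("stopOrigin"))

#' @rdname CohortSummary-class
#' @param x A CohortSummary.
#' @export
setGeneric("summaryCounts", function(x) standardGeneric("summaryCounts"))

#' @rdname CohortSummary-class
#' @export
setGeneric("summaryFractions", function(x) standardGeneric("summaryFractions"))
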