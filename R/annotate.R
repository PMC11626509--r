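#' Fully annotate one breakpoint pair
#'
#' Runs [classifyFusion()], [predictFusionProtein()] and the per-domain
#' retention calls for every domain annotated on either partner, returning
#' a complete [FusionAnnotation-class]. Domain map names are prefixed with
#' the side, e.g. `"5p_C1"`, `"3p_HOX1"`.
#'
#' @inheritParams classifyFusion
#' @return A [FusionAnnotation-class] with domain maps and protein filled
#'   (protein left empty for `five_prime_noncoding`, where no translation
#'   start is retained).
#' @export
annotateBreakpoint <- function(ref5, bp5, ref3, bp3) {
  ann <- classifyFusion(ref5, bp5, ref3, bp3)
  has_protein <- ann@category != "five_prime_noncoding"
  if (has_protein)
    ann@protein <- predictFusionProtein(ref5, bp5, ref3, bp3)
  d5 <- domains(ref5); d3 <- domains(ref3)
  gen <- prot <- character()
  for (i in seq_len(nrow(d5))) {
    nm <- paste0("5p_", d5$name[i])
    gen[nm] <- domainStatusGenomic(ref5, d5$name[i], bp5, "five_prime")
    prot[nm] <- if (has_protein)
      domainStatusProtein(ann@protein, ref5, d5$name[i], bp5, "five_prime")
    else "lost"
  }
  for (i in seq_len(nrow(d3))) {
    nm <- paste0("3p_", d3$name[i])
    gen[nm] <- domainStatusGenomic(ref3, d3$name[i], bp3, "three_prime")
    prot[nm] <- if (has_protein)
      domainStatusProtein(ann@protein, ref3, d3$name[i], bp3, "three_prime",
                          cdsStart5 = cdsStart(ref5), bp5 = bp5)
    else "lost"
  }
  ann@domainStatusGenomic <- gen
  ann@domainStatusProtein <- prot
  validObject(ann)
  ann
}

#' Annotate every record of a harmonized database
#'
#' Deterministic, order-preserving annotation of all records.
#' Nucleotide-level records with both coordinates are fully annotated;
#' exon-level records receive the sentinel status `"not_annotatable"`
#' (nucleotide resolution is required for frame arithmetic); records whose
#' accessions cannot be resolved, or with missing coordinates, become
#' per-record failure entries rather than aborting the run.
#'
#' @param db A [HarmonizedDatabase-class] (run [assignAmbiguousBases()]
#'   first — junction phase depends on the ambiguity assignment).
#' @param refs Named list of [TranscriptReference-class] objects keyed by
#'   accession.
#' @return A data.frame with one row per record: identification columns
#'   (`case_id`, genes, evidence, resolution, coordinates), `status`
#'   (`"ok"`, `"not_annotatable"`, or `"failed"` with `failure_reason`),
#'   the classification (`category`, `n5_cds`, `phase5`, `p3_cds`,
#'   `phase3`), protein fields (`junction_residue_index`, `stop_origin`,
#'   `junction_to_stop_nt`, `protein_length`, `protein_sequence`), and one
#'   `genomic_*` / `protein_*` column per domain seen in the cohort.
#' @export
annotateDatabase <- function(db, refs) {
  stopifnot(is(db, "HarmonizedDatabase"), is.list(refs))
  rec <- records(db)
  rows <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    base <- data.frame(case_id = r$case_id,
                       five_prime_gene = r$five_prime_gene,
                       three_prime_gene = r$three_prime_gene,
                       evidence_source = r$evidence_source,
                       resolution = r$resolution,
                       five_prime_last_base = r$five_prime_last_base,
                       three_prime_first_base = r$three_prime_first_base,
                       status = "ok", failure_reason = "",
                       category = NA_character_, n5_cds = NA_integer_,
                       phase5 = NA_integer_, p3_cds = NA_integer_,
                       phase3 = NA_integer_,
                       junction_residue_index = NA_integer_,
                       stop_origin = NA_character_,
                       junction_to_stop_nt = NA_integer_,
                       protein_length = NA_integer_,
                       protein_sequence = NA_character_,
                       stringsAsFactors = FALSE)
    if (r$resolution == "exon") {
      base$status <- "not_annotatable"
      base$failure_reason <- "exon-level record: nucleotide resolution required"
      rows[[i]] <- base
      next
    }
    ref5 <- refs[[r$five_prime_accession]]
    ref3 <- refs[[r$three_prime_accession]]
    if (is.null(ref5) || is.null(ref3)) {
      base$status <- "failed"
      base$failure_reason <- sprintf("missing reference: %s",
                                     if (is.null(ref5)) r$five_prime_accession
                                     else r$three_prime_accession)
      rows[[i]] <- base
      next
    }
    if (is.na(r$five_prime_last_base) || is.na(r$three_prime_first_base)) {
      base$status <- "failed"
      base$failure_reason <- "missing breakpoint coordinate"
      rows[[i]] <- base
      next
    }
    ann <- tryCatch(annotateBreakpoint(ref5, r$five_prime_last_base,
                                       ref3, r$three_prime_first_base),
                    error = function(e) e)
    if (inherits(ann, "error")) {
      base$status <- "failed"
      base$failure_reason <- conditionMessage(ann)
      rows[[i]] <- base
      next
    }
    base$category <- ann@category
    base$n5_cds <- ann@n5Cds
    base$phase5 <- ann@phase5
    base$p3_cds <- ann@p3Cds
    base$phase3 <- ann@phase3
    if (ann@category != "five_prime_noncoding") {
      p <- ann@protein
      base$junction_residue_index <- p@junctionResidueIndex
      base$stop_origin <- p@stopOrigin
      base$junction_to_stop_nt <- p@junctionToStopNt
      base$protein_length <- nchar(p@sequence)
      base$protein_sequence <- p@sequence
    }
    for (nm in names(ann@domainStatusGenomic))
      base[[paste0("genomic_", nm)]] <- ann@domainStatusGenomic[[nm]]
    for (nm in names(ann@domainStatusProtein))
      base[[paste0("protein_", nm)]] <- ann@domainStatusProtein[[nm]]
    rows[[i]] <- base
  }
  if (!length(rows)) return(empty_annotation_frame())
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(x) {
    for (col in setdiff(all_cols, names(x))) x[[col]] <- NA_character_
    x[all_cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_annotation_frame <- function() {
  data.frame(case_id = character(), five_prime_gene = character(),
             three_prime_gene = character(), evidence_source = character(),
             resolution = character(), five_prime_last_base = integer(),
             three_prime_first_base = integer(), status = character(),
             failure_reason = character(), category = character(),
             n5_cds = integer(), phase5 = integer(), p3_cds = integer(),
             phase3 = integer(), junction_residue_index = integer(),
             stop_origin = character(), junction_to_stop_nt = integer(),
             protein_length = integer(), protein_sequence = character(),
             stringsAsFactors = FALSE)
}

#' Export annotations
#'
#' `writeAnnotationsTsv()` writes the flat annotation table (one column per
#' domain status); `writeAnnotationsJsonl()` writes one JSON object per
#' record (JSON lines).
#'
#' @param annotations Output of [annotateDatabase()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeAnnotationsTsv <- function(annotations, file) {
  utils::write.table(annotations, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname writeAnnotationsTsv
#' @export
writeAnnotationsJsonl <- function(annotations, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(annotations))) {
    row <- as.list(annotations[i, ])
    writeLines(jsonlite::toJSON(row[!is.na(row)], auto_unbox = TRUE), con)
  }
  invisible(file)
}
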