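.db_columns <- c("case_id", "publication_id", "five_prime_gene",
                 "three_prime_gene", "evidence_source", "resolution",
                 "five_prime_last_base", "three_prime_first_base",
                 "ambiguous_junction_bases", "five_prime_accession",
                 "three_prime_accession", "notes")

.default_partner_whitelist <- c("DUX4", "NUTM1", "LEUTX", "FOXO4")

empty_records <- function() {
  rec <- data.frame(case_id = character(), publication_id = character(),
                    five_prime_gene = character(), three_prime_gene = character(),
                    evidence_source = character(), resolution = character(),
                    five_prime_last_base = integer(),
                    three_prime_first_base = integer(),
                    ambiguous_junction_bases = character(),
                    five_prime_accession = character(),
                    three_prime_accession = character(),
                    notes = character(), stringsAsFactors = FALSE)
  rec$harmonization_note <- character()
  rec$ambiguity_mismatch <- logical()
  rec
}

normalize_records <- function(rec) {
  for (col in setdiff(.db_columns, names(rec))) rec[[col]] <- NA
  rec$five_prime_last_base <- suppressWarnings(as.integer(rec$five_prime_last_base))
  rec$three_prime_first_base <- suppressWarnings(as.integer(rec$three_prime_first_base))
  for (col in setdiff(.db_columns, c("five_prime_last_base",
                                     "three_prime_first_base"))) {
    rec[[col]] <- as.character(rec[[col]])
    rec[[col]][is.na(rec[[col]])] <- ""
  }
  rec$ambiguous_junction_bases <- toupper(rec$ambiguous_junction_bases)
  if (is.null(rec$harmonization_note)) rec$harmonization_note <- ""
  if (is.null(rec$ambiguity_mismatch)) rec$ambiguity_mismatch <- FALSE
  rec$ambiguity_mismatch <- as.logical(rec$ambiguity_mismatch)
  rec[c(.db_columns, "harmonization_note", "ambiguity_mismatch")]
}

#' Build a HarmonizedDatabase from a records data.frame
#'
#' Validating constructor used by the table reader and the simulator.
#'
#' @param records data.frame in the harmonized breakpoint schema (see
#'   [HarmonizedDatabase-class]).
#' @param provenance Character provenance notes.
#' @param rejects Optional data.frame of rejected rows.
#' @return A [HarmonizedDatabase-class].
#' @export
HarmonizedDatabase <- function(records, provenance = character(),
                               rejects = data.frame()) {
  records <- normalize_records(as.data.frame(records, stringsAsFactors = FALSE))
  rownames(records) <- NULL
  obj <- new("HarmonizedDatabase", records = records, rejects = rejects,
             provenance = as.character(provenance))
  validObject(obj)
  obj
}

#' Read a harmonized breakpoint table
#'
#' Parses a delimited breakpoint table (one row per literature case) into a
#' [HarmonizedDatabase-class]. Rows that violate record invariants — unknown
#' partner gene under the whitelist, unparseable or out-of-range
#' coordinates, bad ambiguous-base alphabet — are collected into the reject
#' report with a reason, never silently dropped.
#'
#' @param file Path to a tab- (or `sep`-) separated table with a header row.
#' @param columnMap Named character vector mapping schema fields to column
#'   names in the file, for tables using different headers; e.g.
#'   `c(five_prime_last_base = "CIC_bp")`. Unmapped fields use their schema
#'   names directly.
#' @param partnerWhitelist Character vector of allowed 3'-partner gene
#'   symbols, or NULL to accept any symbol.
#' @param junctionConvention `"last_retained"` (default schema: coordinates
#'   are the last retained 5' base and first retained 3' base) or
#'   `"first_lost"` (5' coordinate is the first lost base; converted on
#'   ingest by subtracting 1).
#' @param sep Field separator.
#' @return A [HarmonizedDatabase-class]; inspect [rejects()] for refused rows.
#' @export
readBreakpointTable <- function(file, columnMap = character(),
                                partnerWhitelist = .default_partner_whitelist,
                                junctionConvention = c("last_retained",
                                                       "first_lost"),
                                sep = "\t") {
  junctionConvention <- match.arg(junctionConvention)
  raw <- utils::read.table(file, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  for (field in names(columnMap)) {
    src <- columnMap[[field]]
    if (!src %in% names(raw))
      stop(sprintf("mapped column '%s' (for %s) not in table", src, field))
    raw[[field]] <- raw[[src]]
  }
  for (col in setdiff(.db_columns, names(raw))) raw[[col]] <- ""
  raw <- raw[.db_columns]

  reason <- rep("", nrow(raw))
  flag <- function(idx, why) {
    reason[idx & reason == ""] <<- why
  }
  amb <- toupper(ifelse(is.na(raw$ambiguous_junction_bases), "",
                        raw$ambiguous_junction_bases))
  bp5 <- suppressWarnings(as.integer(raw$five_prime_last_base))
  bp3 <- suppressWarnings(as.integer(raw$three_prime_first_base))
  has5 <- nzchar(trimws(ifelse(is.na(raw$five_prime_last_base), "",
                               raw$five_prime_last_base)))
  has3 <- nzchar(trimws(ifelse(is.na(raw$three_prime_first_base), "",
                               raw$three_prime_first_base)))
  flag(!raw$resolution %in% c("nucleotide", "exon"), "unknown resolution")
  flag(!raw$evidence_source %in% c("RNA", "DNA", "unknown"),
       "unknown evidence source")
  if (!is.null(partnerWhitelist))
    flag(!raw$three_prime_gene %in% partnerWhitelist, "unknown partner")
  flag(has5 & is.na(bp5), "unparseable 5' coordinate")
  flag(has3 & is.na(bp3), "unparseable 3' coordinate")
  flag(raw$resolution == "nucleotide" & is.na(bp5) & is.na(bp3),
       "nucleotide resolution without coordinates")
  flag(grepl("[^ACGTN]", amb), "bad ambiguous-base alphabet")

  accepted <- raw[reason == "", , drop = FALSE]
  accepted$five_prime_last_base <- bp5[reason == ""]
  accepted$three_prime_first_base <- bp3[reason == ""]
  accepted$ambiguous_junction_bases <- amb[reason == ""]
  if (junctionConvention == "first_lost") {
    conv <- !is.na(accepted$five_prime_last_base)
    accepted$five_prime_last_base[conv] <-
      accepted$five_prime_last_base[conv] - 1L
  }
  rejected <- raw[reason != "", , drop = FALSE]
  if (nrow(rejected)) rejected$reject_reason <- reason[reason != ""]
  rownames(rejected) <- NULL
  HarmonizedDatabase(accepted,
                     provenance = c(sprintf("parsed from %s (%d accepted, %d rejected)",
                                            file, nrow(accepted), nrow(rejected)),
                                    sprintf("junction convention: %s",
                                            junctionConvention)),
                     rejects = rejected)
}

#' Resolve ambiguous junction bases onto the 5' partner
#'
#' Bases at a fusion junction that cannot be definitively attributed to
#' either partner are assigned to the 5' partner: for each
#' nucleotide-resolution record carrying `k > 0` ambiguous bases,
#' `five_prime_last_base` is increased by `k`, the ambiguous string is
#' cleared, and a harmonization note is appended. The 3' coordinate is
#' unchanged. When the 5' reference is supplied, the ambiguous bases are
#' checked against the reference sequence at the extended positions; a
#' mismatch sets the `ambiguity_mismatch` flag (the junction sequence then
#' does not look 5'-derived at those positions).
#'
#' The operation is idempotent: a second application is the identity.
#'
#' @param db A [HarmonizedDatabase-class].
#' @param refs Optional named list of [TranscriptReference-class] objects,
#'   keyed by accession, for the sequence check.
#' @return The database with junctions normalized.
#' @export
assignAmbiguousBases <- function(db, refs = NULL) {
  stopifnot(is(db, "HarmonizedDatabase"))
  rec <- db@records
  todo <- which(rec$resolution == "nucleotide" &
                  nzchar(rec$ambiguous_junction_bases) &
                  !is.na(rec$five_prime_last_base))
  for (i in todo) {
    bases <- rec$ambiguous_junction_bases[i]
    k <- nchar(bases)
    bp5 <- rec$five_prime_last_base[i]
    ref <- refs[[rec$five_prime_accession[i]]]
    if (!is.null(ref)) {
      if (bp5 + k > length(ref))
        stop(sprintf("%s: assigning %d ambiguous base(s) extends past end of %s (%d nt)",
                     rec$case_id[i], k, accession(ref), length(ref)))
      ref_bases <- substr(as.character(refSequence(ref)), bp5 + 1L, bp5 + k)
      if (!identical(ref_bases, bases))
        rec$ambiguity_mismatch[i] <- TRUE
    }
    rec$five_prime_last_base[i] <- bp5 + k
    rec$ambiguous_junction_bases[i] <- ""
    note <- sprintf("assigned %d ambiguous base(s) '%s' to 5' partner", k, bases)
    rec$harmonization_note[i] <- if (nzchar(rec$harmonization_note[i]))
      paste(rec$harmonization_note[i], note, sep = "; ") else note
  }
  new("HarmonizedDatabase", records = rec, rejects = db@rejects,
      provenance = c(db@provenance,
                     sprintf("ambiguous junction bases assigned to 5' partner (%d record(s))",
                             length(todo))))
}

#' Filter a harmonized database
#'
#' Order-preserving subset on partner genes, evidence source, resolution,
#' and coordinate completeness. The filter is recorded in the database
#' provenance so cohort denominators stay reproducible.
#'
#' @param db A [HarmonizedDatabase-class].
#' @param partnerGenes Character vector of 3'-partner genes to keep (NULL =
#'   all).
#' @param evidenceSource Evidence sources to keep (NULL = all).
#' @param resolution Resolutions to keep (NULL = all).
#' @param bothCoordinatesRequired Keep only records with both
#'   `five_prime_last_base` and `three_prime_first_base` non-missing.
#' @return The filtered [HarmonizedDatabase-class].
#' @export
filterRecords <- function(db, partnerGenes = NULL, evidenceSource = NULL,
                          resolution = NULL, bothCoordinatesRequired = FALSE) {
  stopifnot(is(db, "HarmonizedDatabase"))
  rec <- db@records
  keep <- rep(TRUE, nrow(rec))
  desc <- character()
  if (!is.null(partnerGenes)) {
    keep <- keep & rec$three_prime_gene %in% partnerGenes
    desc <- c(desc, sprintf("partner in {%s}", paste(partnerGenes, collapse = ",")))
  }
  if (!is.null(evidenceSource)) {
    keep <- keep & rec$evidence_source %in% evidenceSource
    desc <- c(desc, sprintf("evidence in {%s}", paste(evidenceSource, collapse = ",")))
  }
  if (!is.null(resolution)) {
    keep <- keep & rec$resolution %in% resolution
    desc <- c(desc, sprintf("resolution in {%s}", paste(resolution, collapse = ",")))
  }
  if (isTRUE(bothCoordinatesRequired)) {
    keep <- keep & !is.na(rec$five_prime_last_base) &
      !is.na(rec$three_prime_first_base)
    desc <- c(desc, "both coordinates present")
  }
  if (!length(desc)) desc <- "no criteria (identity)"
  new("HarmonizedDatabase", records = rec[keep, , drop = FALSE],
      rejects = db@rejects,
      provenance = c(db@provenance,
                     sprintf("filtered: %s (%d of %d kept)",
                             paste(desc, collapse = " & "), sum(keep), nrow(rec))))
}

#' Combine harmonized databases
#'
#' Row-binds the records of several databases (case_ids must stay unique)
#' and concatenates provenance.
#'
#' @param ... [HarmonizedDatabase-class] objects.
#' @return A single [HarmonizedDatabase-class].
#' @export
combineDatabases <- function(...) {
  dbs <- list(...)
  stopifnot(length(dbs) >= 1L, all(vapply(dbs, is, TRUE, "HarmonizedDatabase")))
  rec <- do.call(rbind, lapply(dbs, function(d) d@records))
  rownames(rec) <- NULL
  rej <- do.call(rbind, lapply(dbs, function(d)
    if (nrow(d@rejects)) d@rejects else NULL))
  HarmonizedDatabase(rec,
                     provenance = c(unlist(lapply(dbs, function(d) d@provenance)),
                                    sprintf("combined %d databases", length(dbs))),
                     rejects = if (is.null(rej)) data.frame() else rej)
}

#' Write a harmonized breakpoint table
#'
#' Serializes the records to TSV in the same schema [readBreakpointTable()]
#' reads, so that parse -> serialize -> parse is the identity on accepted
#' records. Output is deterministic (fixed column order, no row names).
#'
#' @param db A [HarmonizedDatabase-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeBreakpointTable <- function(db, file) {
  stopifnot(is(db, "HarmonizedDatabase"))
  out <- db@records[.db_columns]
  out$five_prime_last_base <- ifelse(is.na(out$five_prime_last_base), "",
                                     as.character(out$five_prime_last_base))
  out$three_prime_first_base <- ifelse(is.na(out$three_prime_first_base), "",
                                       as.character(out$three_prime_first_base))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(file)
}

#' Write a plain-text reject report
#'
#' @param db A [HarmonizedDatabase-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeRejectReport <- function(db, file) {
  stopifnot(is(db, "HarmonizedDatabase"))
  rej <- db@rejects
  lines <- c(sprintf("# reject report: %d row(s)", nrow(rej)))
  if (nrow(rej))
    lines <- c(lines, sprintf("%s\t%s", rej$case_id, rej$reject_reason))
  writeLines(lines, file)
  invisible(file)
}
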