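#' Construct a TranscriptReference
#'
#' Low-level constructor used by the readers and the toy-reference
#' generator. Validates the CDS span, checks the CDS translation for
#' internal stop codons (warns and sets the `internalStop` flag rather than
#' failing, since published reference records occasionally carry them), and
#' validates domain residue ranges against the protein length.
#'
#' @param accession Accession string, e.g. "NM_015125.5".
#' @param geneSymbol Gene symbol.
#' @param sequence Character or DNAString, mRNA sense.
#' @param cdsStart,cdsEnd 1-based inclusive CDS span; includes the stop
#'   codon.
#' @param domains data.frame with columns `name`, `residueStart`,
#'   `residueEnd` and optionally `source`.
#' @param exons Optional data.frame with columns `start`, `end`.
#' @return A validated [TranscriptReference-class].
#' @export
TranscriptReference <- function(accession, geneSymbol, sequence,
                                cdsStart, cdsEnd,
                                domains = NULL, exons = NULL) {
  seq <- Biostrings::DNAString(toupper(as.character(sequence)))
  cdsStart <- as.integer(cdsStart); cdsEnd <- as.integer(cdsEnd)
  if (is.na(cdsStart) || is.na(cdsEnd) || cdsStart < 1L ||
      cdsStart >= cdsEnd || cdsEnd > length(seq))
    stop(sprintf("%s: CDS span %s..%s invalid for %d nt sequence",
                 accession, cdsStart, cdsEnd, length(seq)))
  if ((cdsEnd - cdsStart + 1L) %% 3L != 0L)
    stop(sprintf("%s: CDS length %d not divisible by 3",
                 accession, cdsEnd - cdsStart + 1L))
  if (is.null(domains))
    domains <- data.frame(name = character(), residueStart = integer(),
                          residueEnd = integer(), source = character(),
                          stringsAsFactors = FALSE)
  else {
    domains <- as.data.frame(domains, stringsAsFactors = FALSE)
    if (is.null(domains$source)) domains$source <- ""
    domains$residueStart <- as.integer(domains$residueStart)
    domains$residueEnd <- as.integer(domains$residueEnd)
  }
  cds_seq <- substr(as.character(seq), cdsStart, cdsEnd)
  tr <- translateFrom(cds_seq, 1L)
  internal_stop <- tr$stop_found && tr$stop_nt != nchar(cds_seq) - 2L
  if (internal_stop)
    warning(sprintf("%s: internal stop codon at CDS position %d",
                    accession, tr$stop_nt), call. = FALSE)
  obj <- new("TranscriptReference", accession = as.character(accession),
             geneSymbol = as.character(geneSymbol), sequence = seq,
             cdsStart = cdsStart, cdsEnd = cdsEnd, domains = domains,
             exons = exons, internalStop = internal_stop)
  validObject(obj)
  obj
}

#' Read a transcript reference from GenBank or FASTA + sidecar
#'
#' Two source layouts are supported:
#' \itemize{
#'   \item a single-record GenBank flat file whose FEATURES table carries
#'     exactly one simple `CDS` feature (`CDS a..b`); the ORIGIN block
#'     supplies the sequence and VERSION/LOCUS the accession;
#'   \item a FASTA file plus a tab-separated sidecar annotation giving the
#'     accession, gene symbol, CDS span and optional domain rows.
#' }
#' Domain rows from the sidecar (or `domains` argument) are merged in.
#' The sidecar format is line-oriented TSV:
#' \preformatted{
#' accession   NM_000000.1
#' gene        TOY
#' cds_start   10
#' cds_end     309
#' domain      C1  1464  1519  optional-source-note
#' }
#'
#' @param file Path to the GenBank or FASTA file.
#' @param format `"genbank"` or `"fasta"`; guessed from the first character
#'   of the file when `"auto"` (GenBank files start with "LOCUS").
#' @param sidecar Path to the sidecar annotation (required for FASTA).
#' @param domains Optional data.frame of extra domain annotations to merge.
#' @return A [TranscriptReference-class].
#' @export
readTranscriptReference <- function(file, format = c("auto", "genbank", "fasta"),
                                    sidecar = NULL, domains = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(file, n = 1L)
    format <- if (startsWith(first, "LOCUS")) "genbank" else "fasta"
  }
  if (format == "genbank") {
    parsed <- parse_genbank_record(file)
  } else {
    if (is.null(sidecar))
      stop("FASTA input requires a sidecar annotation file")
    ss <- Biostrings::readDNAStringSet(file)
    if (length(ss) != 1L)
      stop(sprintf("expected exactly one FASTA record in %s, found %d",
                   file, length(ss)))
    sc <- parse_sidecar(sidecar)
    parsed <- list(accession = sc$accession %||% sub("\\s.*", "", names(ss)),
                   gene = sc$gene %||% "", sequence = as.character(ss[[1]]),
                   cds_start = sc$cds_start, cds_end = sc$cds_end,
                   domains = sc$domains)
  }
  if (is.null(parsed$cds_start) || is.null(parsed$cds_end))
    stop(sprintf("no CDS span resolvable for %s", parsed$accession))
  dom <- parsed$domains
  if (!is.null(domains)) {
    domains <- as.data.frame(domains, stringsAsFactors = FALSE)
    if (is.null(domains$source)) domains$source <- ""
    dom <- if (is.null(dom) || !nrow(dom)) domains else rbind(dom, domains)
  }
  TranscriptReference(parsed$accession, parsed$gene, parsed$sequence,
                      parsed$cds_start, parsed$cds_end, domains = dom)
}

# Minimal single-record GenBank flat-file parser: LOCUS/VERSION header,
# one simple CDS feature (a..b), ORIGIN sequence block.
parse_genbank_record <- function(file) {
  lines <- readLines(file, warn = FALSE)
  acc <- NA_character_
  v <- grep("^VERSION", lines, value = TRUE)
  if (length(v)) acc <- strsplit(trimws(sub("^VERSION", "", v[1])), "\\s+")[[1]][1]
  if (is.na(acc)) {
    l <- grep("^LOCUS", lines, value = TRUE)
    if (length(l)) acc <- strsplit(trimws(sub("^LOCUS", "", l[1])), "\\s+")[[1]][1]
  }
  if (is.na(acc)) stop(sprintf("no LOCUS/VERSION accession in %s", file))
  gene <- ""
  g <- grep("/gene=", lines, value = TRUE)
  if (length(g)) gene <- sub('.*?/gene="?([^"]*)"?.*', "\\1", g[1], perl = TRUE)
  cds_lines <- grep("^\\s{5}CDS\\s", lines)
  if (length(cds_lines) == 0L)
    stop(sprintf("%s: missing CDS feature", acc))
  if (length(cds_lines) > 1L)
    stop(sprintf("%s: ambiguous CDS (found %d CDS features)", acc,
                 length(cds_lines)))
  loc <- trimws(sub("^\\s{5}CDS\\s+", "", lines[cds_lines]))
  m <- regmatches(loc, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc))[[1]]
  if (length(m) != 3L)
    stop(sprintf("%s: unsupported CDS location '%s' (need a..b)", acc, loc))
  origin <- grep("^ORIGIN", lines)
  if (length(origin) != 1L) stop(sprintf("%s: missing ORIGIN block", acc))
  seq_lines <- lines[(origin + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  list(accession = acc, gene = gene, sequence = seq,
       cds_start = as.integer(m[2]), cds_end = as.integer(m[3]),
       domains = NULL)
}

parse_sidecar <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(lines, "\t")
  out <- list(domains = NULL)
  dom <- list()
  for (f in fields) {
    key <- trimws(f[[1]])
    if (key == "domain") {
      if (length(f) < 4L) stop("sidecar domain row needs name, start, end")
      dom[[length(dom) + 1L]] <- data.frame(
        name = trimws(f[[2]]), residueStart = as.integer(f[[3]]),
        residueEnd = as.integer(f[[4]]),
        source = if (length(f) >= 5L) trimws(f[[5]]) else "",
        stringsAsFactors = FALSE)
    } else if (key %in% c("cds_start", "cds_end")) {
      out[[key]] <- as.integer(trimws(f[[2]]))
    } else if (key %in% c("accession", "gene")) {
      out[[key]] <- trimws(f[[2]])
    }
  }
  if (length(dom)) out$domains <- do.call(rbind, dom)
  out
}
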