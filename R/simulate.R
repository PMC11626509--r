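#' Generate a toy transcript reference
#'
#' Builds a synthetic mRNA with valid anatomy: a random 5' UTR, a CDS that
#' starts with ATG, continues with codons drawn uniformly from the 61 sense
#' codons (so no internal stops arise by construction), and ends with TAA,
#' followed by a random 3' UTR. Deterministic under `seed`.
#'
#' @param geneSymbol Gene symbol for the toy reference.
#' @param utr5Len,utr3Len UTR lengths in nucleotides (may be 0).
#' @param nCodons Number of CDS codons including start and stop
#'   (`nCodons >= 3`); the encoded protein has `nCodons - 1` residues.
#' @param domains Optional data.frame of domain annotations (`name`,
#'   `residueStart`, `residueEnd`); must fit within the protein.
#' @param seed Integer seed.
#' @param accession Accession string; defaults to `"SYN_<geneSymbol>.1"`.
#' @return A [TranscriptReference-class].
#' @export
makeToyReference <- function(geneSymbol, utr5Len, nCodons, utr3Len,
                             domains = NULL, seed = 1L, accession = NULL) {
  stopifnot(nCodons >= 3L, utr5Len >= 0L, utr3Len >= 0L)
  accession <- accession %||% sprintf("SYN_%s.1", geneSymbol)
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  seq <- with_local_seed(seed, {
    bases <- c("A", "C", "G", "T")
    paste0(paste(sample(bases, utr5Len, replace = TRUE), collapse = ""),
           "ATG",
           paste(sample(sense, nCodons - 2L, replace = TRUE), collapse = ""),
           "TAA",
           paste(sample(bases, utr3Len, replace = TRUE), collapse = ""))
  })
  TranscriptReference(accession, geneSymbol, seq,
                      cdsStart = utr5Len + 1L,
                      cdsEnd = utr5Len + 3L * nCodons,
                      domains = domains)
}

#' Default toy reference set
#'
#' Toy references shaped like the five transcripts of the CIC-fusion
#' cohort: a CIC-like 5' partner (1608-residue protein, HMG box at
#' I200-K268 and C1 domain at R1464-M1519) and partner-shaped DUX4 /
#' NUTM1 / LEUTX / FOXO4 references with realistic protein lengths. The
#' DUX4 homeodomain/transactivation coordinates are illustrative defaults
#' (the literature anchors them only approximately), supplied here as
#' configuration, not asserted as ground truth.
#'
#' @param seed Integer seed for the random sequence content.
#' @return Named list of [TranscriptReference-class] objects keyed by gene
#'   symbol.
#' @export
makeDefaultReferences <- function(seed = 1L) {
  list(
    CIC = makeToyReference("CIC", utr5Len = 100L, nCodons = 1609L,
                           utr3Len = 300L, seed = seed,
                           domains = data.frame(
                             name = c("HMG", "C1"),
                             residueStart = c(200L, 1464L),
                             residueEnd = c(268L, 1519L),
                             source = c("HMG box I200-K268",
                                        "C1 domain R1464-M1519"))),
    DUX4 = makeToyReference("DUX4", utr5Len = 50L, nCodons = 425L,
                            utr3Len = 400L, seed = seed + 1L,
                            domains = data.frame(
                              name = c("HOX1", "HOX2", "TAD"),
                              residueStart = c(19L, 94L, 371L),
                              residueEnd = c(81L, 153L, 424L),
                              source = "illustrative default")),
    NUTM1 = makeToyReference("NUTM1", utr5Len = 100L, nCodons = 1133L,
                             utr3Len = 200L, seed = seed + 2L),
    LEUTX = makeToyReference("LEUTX", utr5Len = 50L, nCodons = 168L,
                             utr3Len = 150L, seed = seed + 3L),
    FOXO4 = makeToyReference("FOXO4", utr5Len = 80L, nCodons = 506L,
                             utr3Len = 200L, seed = seed + 4L))
}

#' Map references by accession
#'
#' [annotateDatabase()] resolves references by accession; this re-keys a
#' gene-keyed reference list.
#'
#' @param refs List of [TranscriptReference-class] objects.
#' @return The same list, named by accession.
#' @export
referenceMap <- function(refs) {
  stats::setNames(refs, vapply(refs, accession, character(1)))
}

#' Simulation configuration
#'
#' Bundles and validates the knobs of [simulateCohort()]. The defaults are
#' the composition of the published CIC::DUX4 analysis cohort: 74 RNA-level
#' records with both coordinates, of which 32 are UTR fusions, 37 of the
#' remaining 42 coding fusions in-frame, and 32 of the 37 in-frame fusions
#' retaining the C1 domain. Class counts follow deterministic
#' largest-remainder apportionment of the proportions, so the realized
#' composition is exact, not multinomially sampled.
#'
#' @param seed Integer seed; one generator instance governs all randomness.
#' @param nRecords Number of nucleotide-level records.
#' @param partnerMix Named proportions of 3' partner genes (sums to 1).
#' @param fracUtrFusion Proportion of records that are UTR fusions.
#' @param fracInFrameGivenCoding Proportion of coding (non-UTR) records
#'   that are in-frame.
#' @param domainRetentionTarget Named proportion (single 5'-partner domain)
#'   retained among in-frame records, e.g. `c(C1 = 32/37)`.
#' @param ambiguousBaseLengthDist Named probabilities of ambiguous-junction
#'   lengths, names are lengths (e.g. `c("0" = .7, "1" = .15, ...)`).
#' @param evidenceSource Evidence source stamped on the records.
#' @param fracOneSided Proportion of records emitted without a 3'
#'   coordinate (excluded by both-coordinate filters).
#' @param nExonRecords Additional exon-level records (no coordinates).
#' @param fivePrimeGene 5' partner gene (must be in the reference set).
#' @param caseIdPrefix Prefix for generated case_ids (keep distinct when
#'   combining cohorts).
#' @return A list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(seed = 1L,
                             nRecords = 74L,
                             partnerMix = c(DUX4 = 1),
                             fracUtrFusion = 32 / 74,
                             fracInFrameGivenCoding = 37 / 42,
                             domainRetentionTarget = c(C1 = 32 / 37),
                             ambiguousBaseLengthDist = c("0" = 0.70,
                                                         "1" = 0.15,
                                                         "2" = 0.10,
                                                         "3" = 0.05),
                             evidenceSource = "RNA",
                             fracOneSided = 0,
                             nExonRecords = 0L,
                             fivePrimeGene = "CIC",
                             caseIdPrefix = "SIM") {
  cfg <- list(seed = as.integer(seed), nRecords = as.integer(nRecords),
              partnerMix = partnerMix, fracUtrFusion = fracUtrFusion,
              fracInFrameGivenCoding = fracInFrameGivenCoding,
              domainRetentionTarget = domainRetentionTarget,
              ambiguousBaseLengthDist = ambiguousBaseLengthDist,
              evidenceSource = evidenceSource,
              fracOneSided = fracOneSided,
              nExonRecords = as.integer(nExonRecords),
              fivePrimeGene = fivePrimeGene,
              caseIdPrefix = as.character(caseIdPrefix))
  props <- c(cfg$fracUtrFusion, cfg$fracInFrameGivenCoding, cfg$fracOneSided,
             cfg$domainRetentionTarget)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (abs(sum(cfg$partnerMix) - 1) > 1e-9) stop("partnerMix must sum to 1")
  if (abs(sum(cfg$ambiguousBaseLengthDist) - 1) > 1e-9)
    stop("ambiguousBaseLengthDist must sum to 1")
  if (length(cfg$domainRetentionTarget) > 1L)
    stop("a single focal-domain retention target is supported")
  if (!cfg$evidenceSource %in% c("RNA", "DNA", "unknown"))
    stop("unknown evidenceSource")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a breakpoint cohort with known truth labels
#'
#' For each record the target label is drawn first and the coordinates are
#' then constructed to realize it exactly: in-frame fusions sample a 5'
#' breakpoint in the CDS and choose a 3' CDS entry with matching phase;
#' out-of-frame fusions force a phase mismatch; UTR fusions place the 3'
#' breakpoint beyond the 3' partner's stop codon (and, when a focal domain
#' is configured, the 5' breakpoint inside that domain, matching the
#' anatomy of published 5'-partner::UTR fusions); domain-retaining records
#' place the 5' breakpoint at or after the domain's last nucleotide.
#' Ambiguous junction bases are emitted verbatim from the 5' reference at
#' the extension positions, so [assignAmbiguousBases()] restores the true
#' junction exactly.
#'
#' Class counts follow largest-remainder apportionment (exact composition);
#' record order is a deterministic permutation under the seed.
#'
#' @param config A [simulationConfig()].
#' @param refs Named list of [TranscriptReference-class] objects keyed by
#'   gene symbol, covering `fivePrimeGene` and every partner in
#'   `partnerMix` (see [makeDefaultReferences()]).
#' @return List with `db` (a [HarmonizedDatabase-class] emitting the same
#'   TSV schema [readBreakpointTable()] reads) and `truth` (a data.frame of
#'   per-case true category, junction phases, and genomic domain statuses —
#'   the test oracle's reference).
#' @export
simulateCohort <- function(config, refs = makeDefaultReferences(config$seed)) {
  stopifnot(inherits(config, "SimulationConfig"))
  ref5 <- refs[[config$fivePrimeGene]]
  if (is.null(ref5))
    stop(sprintf("no reference for 5' gene %s", config$fivePrimeGene))
  partners <- names(config$partnerMix)
  missing_ref <- setdiff(partners, names(refs))
  if (length(missing_ref))
    stop(sprintf("no reference for partner(s): %s",
                 paste(missing_ref, collapse = ", ")))
  with_local_seed(config$seed, {
    n_partner <- apportion(config$nRecords, config$partnerMix)
    rows <- list(); truths <- list()
    idx <- 0L
    for (pi in seq_along(partners)) {
      gene3 <- partners[pi]
      ref3 <- refs[[gene3]]
      n <- n_partner[pi]
      if (n == 0L) next
      n_utr <- apportion(n, c(config$fracUtrFusion, 1 - config$fracUtrFusion))[1]
      n_coding <- n - n_utr
      n_if <- apportion(n_coding, c(config$fracInFrameGivenCoding,
                                    1 - config$fracInFrameGivenCoding))[1]
      n_oof <- n_coding - n_if
      ret_target <- config$domainRetentionTarget
      n_ret <- if (length(ret_target) && n_if > 0)
        apportion(n_if, c(ret_target[[1]], 1 - ret_target[[1]]))[1] else NA_integer_
      cats <- c(rep("utr_fusion", n_utr), rep("in_frame_coding", n_if),
                rep("out_of_frame_coding", n_oof))
      retain <- c(rep(NA, n_utr),
                  if (is.na(n_ret)) rep(NA, n_if)
                  else c(rep(TRUE, n_ret), rep(FALSE, n_if - n_ret)),
                  rep(NA, n_oof))
      for (j in seq_along(cats)) {
        idx <- idx + 1L
        sim <- simulate_one(ref5, ref3, cats[j], retain[j],
                            names(ret_target), config)
        sim$row$case_id <- sprintf("%s-%04d", config$caseIdPrefix, idx)
        sim$truth$case_id <- sim$row$case_id
        rows[[idx]] <- sim$row
        truths[[idx]] <- sim$truth
      }
    }
    if (config$nExonRecords > 0L) {
      n_ex <- apportion(config$nExonRecords, config$partnerMix)
      for (pi in seq_along(partners)) {
        for (j in seq_len(n_ex[pi])) {
          idx <- idx + 1L
          rows[[idx]] <- data.frame(
            case_id = sprintf("%s-%04d", config$caseIdPrefix, idx),
            publication_id = "synthetic",
            five_prime_gene = geneSymbol(ref5),
            three_prime_gene = partners[pi],
            evidence_source = config$evidenceSource, resolution = "exon",
            five_prime_last_base = NA_integer_,
            three_prime_first_base = NA_integer_,
            ambiguous_junction_bases = "",
            five_prime_accession = accession(ref5),
            three_prime_accession = accession(refs[[partners[pi]]]),
            notes = "exon-level literature report (synthetic)",
            stringsAsFactors = FALSE)
          truths[[idx]] <- data.frame(case_id = sprintf("%s-%04d",
                                                        config$caseIdPrefix, idx),
                                      category = "not_annotatable",
                                      phase5 = NA_integer_,
                                      phase3 = NA_integer_,
                                      stringsAsFactors = FALSE)
        }
      }
    }
    ord <- sample.int(idx)
    rec <- do.call(rbind, fill_columns(rows))[ord, , drop = FALSE]
    truth <- do.call(rbind, fill_columns(truths))[ord, , drop = FALSE]
    rownames(rec) <- rownames(truth) <- NULL
    db <- HarmonizedDatabase(
      rec, provenance = sprintf(
        "simulated cohort: n=%d nucleotide + %d exon-level, seed=%d",
        config$nRecords, config$nExonRecords, config$seed))
    list(db = db, truth = truth)
  })
}

# Construct one record realizing `category` (and focal-domain retention).
simulate_one <- function(ref5, ref3, category, retain_domain, domain_name,
                         config) {
  seq5 <- as.character(refSequence(ref5))
  cs5 <- cdsStart(ref5); ce5 <- cdsEnd(ref5)
  cs3 <- cdsStart(ref3); ce3 <- cdsEnd(ref3)
  dom_nt <- if (length(domain_name))
    residueToNt(ref5, domains(ref5)$residueStart[domains(ref5)$name == domain_name],
                domains(ref5)$residueEnd[domains(ref5)$name == domain_name])
  else NULL
  sample_range <- function(lo, hi, what) {
    if (lo > hi) stop(sprintf("unrealizable constraint: empty %s range [%d, %d]",
                              what, lo, hi))
    if (lo == hi) lo else sample(lo:hi, 1L)
  }
  # 5' breakpoint: respect the retention constraint when one is requested
  bp5 <- if (isTRUE(retain_domain)) {
    sample_range(dom_nt[["nt_end"]], ce5 - 3L, "domain-retaining bp5")
  } else if (isFALSE(retain_domain)) {
    sample_range(cs5, dom_nt[["nt_end"]] - 1L, "domain-non-retaining bp5")
  } else if (category == "utr_fusion" && !is.null(dom_nt)) {
    sample_range(dom_nt[["nt_start"]], dom_nt[["nt_end"]] - 1L,
                 "UTR-fusion bp5 (within focal domain)")
  } else {
    sample_range(cs5, ce5 - 3L, "bp5 in CDS")
  }
  phase5 <- (bp5 - cs5 + 1L) %% 3L
  bp3 <- if (category == "utr_fusion") {
    sample_range(ce3 + 1L, length(ref3), "bp3 in 3' UTR")
  } else {
    off_max <- ce3 - cs3 - 3L   # keep bp3 <= cds_end - 3
    want <- if (category == "in_frame_coding") phase5
            else (phase5 + sample(1:2, 1L)) %% 3L
    offs <- seq.int(want, off_max, by = 3L)
    cs3 + offs[sample.int(length(offs), 1L)]
  }
  phase3 <- if (bp3 <= ce3) (bp3 - cs3) %% 3L else NA_integer_
  # ambiguous junction bases, taken verbatim from the 5' reference
  k <- as.integer(sample(names(config$ambiguousBaseLengthDist), 1L,
                         prob = config$ambiguousBaseLengthDist))
  k <- min(k, bp5 - 1L)
  amb <- if (k > 0L) substr(seq5, bp5 - k + 1L, bp5) else ""
  one_sided <- config$fracOneSided > 0 &&
    stats::runif(1L) < config$fracOneSided
  row <- data.frame(
    case_id = "", publication_id = "synthetic",
    five_prime_gene = geneSymbol(ref5), three_prime_gene = geneSymbol(ref3),
    evidence_source = config$evidenceSource, resolution = "nucleotide",
    five_prime_last_base = bp5 - k,
    three_prime_first_base = if (one_sided) NA_integer_ else bp3,
    ambiguous_junction_bases = amb,
    five_prime_accession = accession(ref5),
    three_prime_accession = accession(ref3),
    notes = "", stringsAsFactors = FALSE)
  truth <- data.frame(case_id = "",
                      category = if (one_sided) "not_annotatable" else category,
                      phase5 = if (one_sided) NA_integer_ else phase5,
                      phase3 = if (one_sided) NA_integer_ else phase3,
                      stringsAsFactors = FALSE)
  if (!one_sided) {
    d5 <- domains(ref5)
    for (i in seq_len(nrow(d5))) {
      nt <- residueToNt(ref5, d5$residueStart[i], d5$residueEnd[i])
      truth[[paste0("genomic_5p_", d5$name[i])]] <-
        if (bp5 >= nt[["nt_end"]]) "retained"
        else if (bp5 >= nt[["nt_start"]]) "disrupted" else "lost"
    }
    d3 <- domains(ref3)
    for (i in seq_len(nrow(d3))) {
      nt <- residueToNt(ref3, d3$residueStart[i], d3$residueEnd[i])
      truth[[paste0("genomic_3p_", d3$name[i])]] <-
        if (bp3 <= nt[["nt_start"]]) "retained"
        else if (bp3 <= nt[["nt_end"]]) "disrupted" else "lost"
    }
  }
  list(row = row, truth = truth)
}

# rbind data.frames with differing columns (missing filled with NA)
fill_columns <- function(dfs) {
  dfs <- dfs[!vapply(dfs, is.null, logical(1))]
  cols <- unique(unlist(lapply(dfs, names)))
  lapply(dfs, function(x) {
    for (col in setdiff(cols, names(x))) x[[col]] <- NA
    x[cols]
  })
}

#' Write simulation truth labels as JSON
#'
#' @param truth The `truth` data.frame from [simulateCohort()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeTruthLabels <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file)
}
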