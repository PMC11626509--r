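make_table <- function(rows, file = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  file
}

base_row <- function(case_id, gene3 = "DUX4", evidence = "RNA",
                     resolution = "nucleotide", bp5 = 100, bp3 = 50,
                     amb = "") {
  data.frame(case_id = case_id, publication_id = "pub1",
             five_prime_gene = "CIC", three_prime_gene = gene3,
             evidence_source = evidence, resolution = resolution,
             five_prime_last_base = bp5, three_prime_first_base = bp3,
             ambiguous_junction_bases = amb,
             five_prime_accession = "SYN_CIC.1",
             three_prime_accession = "SYN_DUX4.1", notes = "",
             stringsAsFactors = FALSE)
}

test_that("well-formed tables parse fully; bad rows land in the reject report", {
  f <- make_table(rbind(base_row("a"), base_row("b"), base_row("c")))
  db <- readBreakpointTable(f)
  expect_s4_class(db, "HarmonizedDatabase")
  expect_identical(length(db), 3L)
  expect_identical(nrow(rejects(db)), 0L)

  mixed <- rbind(base_row("good"),
                 base_row("badgene", gene3 = "ATXN1"),
                 base_row("badcoord", bp5 = "xyz"),
                 base_row("exonlevel", resolution = "exon", bp5 = NA, bp3 = NA))
  db2 <- readBreakpointTable(make_table(mixed))
  expect_identical(records(db2)$case_id, c("good", "exonlevel"))
  expect_identical(records(db2)$resolution[2], "exon")
  rej <- rejects(db2)
  expect_identical(rej$reject_reason[rej$case_id == "badgene"],
                   "unknown partner")
  expect_identical(rej$reject_reason[rej$case_id == "badcoord"],
                   "unparseable 5' coordinate")
  # whitelist can be widened
  db3 <- readBreakpointTable(make_table(mixed),
                             partnerWhitelist = c("DUX4", "ATXN1"))
  expect_true("badgene" %in% records(db3)$case_id)
})

test_that("column mapping and first-lost junction convention convert on ingest", {
  row <- base_row("m1")
  names(row)[names(row) == "five_prime_last_base"] <- "CIC_bp"
  f <- make_table(row)
  db <- readBreakpointTable(f, columnMap = c(five_prime_last_base = "CIC_bp"),
                            junctionConvention = "first_lost")
  expect_identical(records(db)$five_prime_last_base, 99L)   # 100 - 1
  expect_identical(records(db)$three_prime_first_base, 50L)
  expect_error(readBreakpointTable(f, columnMap = c(notes = "nope")),
               "not in table")
})

test_that("parse -> serialize -> parse is the identity on accepted records", {
  refs <- tiny_refs()
  sim <- simulateCohort(simulationConfig(seed = 5, nRecords = 12,
                                         partnerMix = c(THREE = 1),
                                         domainRetentionTarget = c(DOM = 0.5),
                                         fivePrimeGene = "FIVE",
                                         nExonRecords = 2),
                        refs)
  f <- tempfile(fileext = ".tsv")
  writeBreakpointTable(sim$db, f)
  db2 <- readBreakpointTable(f, partnerWhitelist = NULL)
  expect_identical(records(db2)[names(records(sim$db))], records(sim$db))
})

test_that("ambiguous bases are assigned to the 5' partner and the rule is idempotent", {
  refs <- tiny_refs()
  ref5 <- refs$FIVE
  db <- HarmonizedDatabase(rbind(
    within(base_row("plain"), ambiguous_junction_bases <- ""),
    base_row("twobase", bp5 = 100, amb = "AT")))
  out <- assignAmbiguousBases(db)
  rec <- records(out)
  expect_identical(rec$five_prime_last_base, c(100L, 102L))
  expect_identical(rec$ambiguous_junction_bases, c("", ""))
  expect_match(rec$harmonization_note[2], "assigned 2 ambiguous")
  # idempotent
  expect_identical(records(assignAmbiguousBases(out)), rec)

  # with a reference: matching bases don't flag, corrupted ones do
  s5 <- as.character(refSequence(ref5))
  good <- HarmonizedDatabase(base_row("ok", bp5 = 60,
                                      amb = substr(s5, 61, 62)))
  flagged <- records(assignAmbiguousBases(good, list(SYN_CIC.1 = NULL,
                                                     SYN_FIVE.1 = ref5)))
  # record uses accession SYN_CIC.1 which has no reference -> unchecked
  expect_false(flagged$ambiguity_mismatch[1])
  rec_ok <- base_row("ok2", bp5 = 60, amb = substr(s5, 61, 62))
  rec_ok$five_prime_accession <- accession(ref5)
  checked <- records(assignAmbiguousBases(HarmonizedDatabase(rec_ok),
                                          referenceMap(refs)))
  expect_false(checked$ambiguity_mismatch[1])
  rec_bad <- rec_ok
  rec_bad$case_id <- "corrupt"
  rec_bad$ambiguous_junction_bases <- chartr("ACGT", "TGCA",
                                             rec_bad$ambiguous_junction_bases)
  corrupted <- records(assignAmbiguousBases(HarmonizedDatabase(rec_bad),
                                            referenceMap(refs)))
  expect_true(corrupted$ambiguity_mismatch[1])

  # extension beyond the reference is an error
  rec_end <- base_row("end", bp5 = length(ref5), amb = "A")
  rec_end$five_prime_accession <- accession(ref5)
  expect_error(assignAmbiguousBases(HarmonizedDatabase(rec_end),
                                    referenceMap(refs)),
               "extends past end")
})

test_that("filterRecords subsets in order and composes across criteria", {
  rows <- rbind(base_row("rna_both"),
                base_row("rna_one", bp3 = NA),
                base_row("dna_both", evidence = "DNA"))
  db <- HarmonizedDatabase(rows)
  expect_identical(records(filterRecords(db)), records(db))
  sub <- filterRecords(db, evidenceSource = "RNA",
                       bothCoordinatesRequired = TRUE)
  expect_identical(records(sub)$case_id, "rna_both")
  expect_match(tail(provenance(sub), 1), "1 of 3 kept")
  # composition: joint filter == chained filters
  joint <- filterRecords(db, evidenceSource = "RNA",
                         bothCoordinatesRequired = TRUE)
  chained <- filterRecords(filterRecords(db, evidenceSource = "RNA"),
                           bothCoordinatesRequired = TRUE)
  expect_identical(records(joint), records(chained))
})

test_that("databases with duplicate case ids are refused", {
  expect_error(HarmonizedDatabase(rbind(base_row("dup"), base_row("dup"))),
               "unique")
  expect_error(combineDatabases(HarmonizedDatabase(base_row("x")),
                                HarmonizedDatabase(base_row("x"))),
               "unique")
})
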