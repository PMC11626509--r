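test_that("makeToyReference builds valid anatomy deterministically", {
  r <- makeToyReference("MIN", utr5Len = 0, nCodons = 3, utr3Len = 0, seed = 2)
  expect_identical(length(r), 9L)
  expect_identical(cdsStart(r), 1L)
  expect_identical(cdsEnd(r), 9L)
  expect_identical(substr(as.character(refSequence(r)), 1, 3), "ATG")
  expect_identical(substr(as.character(refSequence(r)), 7, 9), "TAA")
  # determinism
  a <- makeToyReference("G", 10, 40, 10, seed = 123)
  b <- makeToyReference("G", 10, 40, 10, seed = 123)
  expect_identical(as.character(refSequence(a)), as.character(refSequence(b)))
  # translation oracle: nCodons - 1 residues, terminal stop only
  tr <- translateFrom(substr(as.character(refSequence(a)), cdsStart(a),
                             cdsEnd(a)), 1)
  expect_true(tr$stop_found)
  expect_identical(nchar(tr$protein), 39L)
  expect_error(makeToyReference("G", 0, 10, 0,
                                domains = data.frame(name = "D",
                                                     residueStart = 1,
                                                     residueEnd = 50)),
               "outside protein")
})

test_that("degenerate mixes are realized exactly", {
  refs <- tiny_refs()
  sim <- simulateCohort(simulationConfig(seed = 4, nRecords = 10,
                                         partnerMix = c(THREE = 1),
                                         fracUtrFusion = 1,
                                         domainRetentionTarget = c(DOM = 1),
                                         fivePrimeGene = "FIVE"),
                        refs)
  expect_identical(nrow(records(sim$db)), 10L)
  expect_identical(unique(sim$truth$category), "utr_fusion")
})

test_that("identical config and seed give byte-identical emitted tables", {
  refs <- tiny_refs()
  cfg <- simulationConfig(seed = 17, nRecords = 30, partnerMix = c(THREE = 1),
                          domainRetentionTarget = c(DOM = 0.5),
                          fivePrimeGene = "FIVE", nExonRecords = 3)
  f1 <- tempfile(); f2 <- tempfile()
  writeBreakpointTable(simulateCohort(cfg, refs)$db, f1)
  writeBreakpointTable(simulateCohort(cfg, refs)$db, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed changes the table
  cfg2 <- simulationConfig(seed = 18, nRecords = 30, partnerMix = c(THREE = 1),
                           domainRetentionTarget = c(DOM = 0.5),
                           fivePrimeGene = "FIVE", nExonRecords = 3)
  f3 <- tempfile()
  writeBreakpointTable(simulateCohort(cfg2, refs)$db, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("annotation recovers the generated truth labels exactly", {
  refs <- tiny_refs()
  sim <- simulateCohort(simulationConfig(seed = 8, nRecords = 45,
                                         partnerMix = c(THREE = 1),
                                         fracUtrFusion = 0.3,
                                         fracInFrameGivenCoding = 0.8,
                                         domainRetentionTarget = c(DOM = 0.7),
                                         fivePrimeGene = "FIVE",
                                         fracOneSided = 0.1,
                                         nExonRecords = 4),
                        refs)
  expect_truth_recovered(sim, refs)
})

test_that("emitting ambiguous bases then harmonizing equals emitting the resolved junction", {
  refs <- tiny_refs()
  amb_cfg <- simulationConfig(seed = 12, nRecords = 25,
                              partnerMix = c(THREE = 1),
                              domainRetentionTarget = c(DOM = 0.5),
                              ambiguousBaseLengthDist = c("2" = 0.5, "3" = 0.5),
                              fivePrimeGene = "FIVE")
  amb <- simulateCohort(amb_cfg, refs)
  expect_true(any(nzchar(records(amb$db)$ambiguous_junction_bases)))
  harmonized <- assignAmbiguousBases(amb$db, referenceMap(refs))
  # generated bases are verbatim from the 5' reference: never flagged
  expect_false(any(records(harmonized)$ambiguity_mismatch))
  ann_amb <- annotateDatabase(harmonized, referenceMap(refs))
  # truth labels refer to the resolved junction, so exact recovery means the
  # ambiguity round trip is lossless
  expect_truth_recovered(amb, refs)
  # emitting the pre-resolved junction directly gives the same annotation
  pre <- records(amb$db)
  k <- nchar(pre$ambiguous_junction_bases)
  pre$five_prime_last_base <- pre$five_prime_last_base + k
  pre$ambiguous_junction_bases <- ""
  ann_pre <- annotateDatabase(HarmonizedDatabase(pre), referenceMap(refs))
  cols <- c("case_id", "category", "phase5", "phase3", "protein_sequence")
  expect_identical(ann_amb[cols], ann_pre[cols])
})

test_that("unrealizable label constraints fail loudly", {
  refs <- list(FIVE = tiny_refs()$FIVE,
               NOUTR = makeToyReference("NOUTR", 10, 30, 0, seed = 3))
  cfg <- simulationConfig(seed = 1, nRecords = 5, partnerMix = c(NOUTR = 1),
                          fracUtrFusion = 1, domainRetentionTarget = NULL,
                          fivePrimeGene = "FIVE")
  expect_error(simulateCohort(cfg, refs), "bp3 in 3' UTR")
  expect_error(simulateCohort(simulationConfig(seed = 1, partnerMix = c(XX = 1),
                                               fivePrimeGene = "FIVE"),
                              refs), "no reference for partner")
})

test_that("truth labels serialize to JSON", {
  refs <- tiny_refs()
  sim <- simulateCohort(simulationConfig(seed = 2, nRecords = 5,
                                         partnerMix = c(THREE = 1),
                                         domainRetentionTarget = c(DOM = 0.5),
                                         fivePrimeGene = "FIVE"), refs)
  f <- tempfile(fileext = ".json")
  writeTruthLabels(sim$truth, f)
  back <- jsonlite::read_json(f)
  expect_identical(length(back), 5L)
})
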