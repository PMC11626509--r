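test_that("classifyFusion resolves the coding/UTR/noncoding geometries", {
  refs <- tiny_refs()
  r5 <- refs$FIVE; r3 <- refs$THREE
  # 300 retained CDS nt (phase 0) joined to CDS position 4 (phase 0)
  ann <- classifyFusion(r5, cdsStart(r5) + 299L, r3, cdsStart(r3) + 3L)
  expect_identical(fusionCategory(ann), "in_frame_coding")
  expect_identical(ann@n5Cds, 300L)
  expect_identical(unname(junctionPhases(ann)), c(0L, 0L))
  # shifting the 3' entry by one base breaks the frame
  oof <- classifyFusion(r5, cdsStart(r5) + 299L, r3, cdsStart(r3) + 4L)
  expect_identical(fusionCategory(oof), "out_of_frame_coding")
  expect_identical(oof@phase3, 1L)
  # 3' breakpoint past the stop codon: UTR fusion regardless of 5' phase
  expect_identical(fusionCategory(classifyFusion(r5, cdsStart(r5) + 299L,
                                                 r3, cdsEnd(r3) + 50L)),
                   "utr_fusion")
  # 5' breakpoint before/after its CDS
  expect_identical(fusionCategory(classifyFusion(r5, cdsStart(r5) - 1L,
                                                 r3, cdsStart(r3))),
                   "five_prime_noncoding")
  expect_identical(fusionCategory(classifyFusion(r5, cdsEnd(r5),
                                                 r3, cdsStart(r3))),
                   "five_prime_readthrough")
  expect_identical(fusionCategory(classifyFusion(r5, cdsStart(r5) + 299L,
                                                 r3, cdsStart(r3) - 2L)),
                   "three_prime_upstream_of_cds")
  expect_error(classifyFusion(r5, 0L, r3, 1L), "outside")
  expect_error(classifyFusion(r5, 1L, r3, length(r3) + 1L), "outside")
})

test_that("sliding the 5' breakpoint cycles the phase and the frame call with period 3", {
  refs <- tiny_refs()
  r5 <- refs$FIVE; r3 <- refs$THREE
  bp3 <- cdsStart(r3) + 6L  # phase 0 entry
  cats <- vapply(0:8, function(d)
    fusionCategory(classifyFusion(r5, cdsStart(r5) + 59L + d, r3, bp3)),
    character(1))
  phases <- vapply(0:8, function(d)
    classifyFusion(r5, cdsStart(r5) + 59L + d, r3, bp3)@phase5, integer(1))
  expect_identical(phases, rep(c(0L, 1L, 2L), 3))
  expect_identical(cats, rep(c("in_frame_coding", "out_of_frame_coding",
                               "out_of_frame_coding"), 3))
})

test_that("classifyFusion matches the full-chimera translation oracle on random pairs", {
  refs <- tiny_refs()
  r5 <- refs$FIVE; r3 <- refs$THREE
  set.seed(202)
  for (i in 1:200) {
    bp5 <- sample.int(length(r5), 1)
    bp3 <- sample.int(length(r3), 1)
    expect_identical(fusionCategory(classifyFusion(r5, bp5, r3, bp3)),
                     oracle_classify(r5, bp5, r3, bp3),
                     info = sprintf("bp5=%d bp3=%d", bp5, bp3))
  }
})

test_that("in-frame fusion proteins are the spliced native translations", {
  refs <- tiny_refs()
  r5 <- refs$FIVE; r3 <- refs$THREE
  n5_codons <- 20L
  bp5 <- cdsStart(r5) + 3L * n5_codons - 1L      # phase 0 junction
  p3_res <- 10L
  bp3 <- cdsStart(r3) + 3L * (p3_res - 1L)        # enters at codon 10
  pred <- predictFusionProtein(r5, bp5, r3, bp3)
  prot5 <- translateFrom(substr(as.character(refSequence(r5)),
                                cdsStart(r5), cdsEnd(r5)), 1)$protein
  prot3 <- translateFrom(substr(as.character(refSequence(r3)),
                                cdsStart(r3), cdsEnd(r3)), 1)$protein
  expect_identical(predictedSequence(pred),
                   paste0(substr(prot5, 1, n5_codons),
                          substr(prot3, p3_res, nchar(prot3))))
  expect_identical(stopOrigin(pred), "native_3prime")
  expect_identical(pred@junctionResidueIndex, n5_codons + 1L)
})

test_that("UTR fusions truncate at a premature stop shortly after the junction", {
  # hand-built 3' partner whose UTR carries TAA at in-frame offset 9
  utr <- paste0("CCCCCCCCC", "TAA", "CCC")
  seq3 <- paste0("GG", "ATG", strrep("GCT", 8), "TAA", utr)
  r3 <- TranscriptReference("SYN_UTR3.1", "U3", seq3, 3, 32)
  r5 <- tiny_refs()$FIVE
  bp5 <- cdsStart(r5) + 29L                      # n5 = 30, phase 0
  bp3 <- 33L                                     # first UTR base
  ann <- classifyFusion(r5, bp5, r3, bp3)
  expect_identical(fusionCategory(ann), "utr_fusion")
  pred <- predictFusionProtein(r5, bp5, r3, bp3)
  expect_identical(stopOrigin(pred), "premature")
  expect_lte(pred@junctionToStopNt, 12L)
  expect_identical(pred@junctionToStopNt, 10L)   # direct scan of the chimera
})

test_that("a fully retained 5' CDS dominates: complete protein, premature stop", {
  refs <- tiny_refs()
  r5 <- refs$FIVE; r3 <- refs$THREE
  pred <- predictFusionProtein(r5, cdsEnd(r5), r3, cdsStart(r3))
  prot5 <- translateFrom(substr(as.character(refSequence(r5)),
                                cdsStart(r5), cdsEnd(r5)), 1)$protein
  expect_identical(predictedSequence(pred), prot5)
  expect_identical(stopOrigin(pred), "premature")
  expect_error(predictFusionProtein(r5, cdsStart(r5) - 1L, r3, cdsStart(r3)),
               "noncoding")
})

test_that("genomic domain status transitions exactly at the domain nt boundaries", {
  ref <- tiny_refs()$FIVE
  nt <- residueToNt(ref, 20, 30)
  d_s <- nt[["nt_start"]]; d_e <- nt[["nt_end"]]
  expect_identical(domainStatusGenomic(ref, "DOM", d_e, "five_prime"),
                   "retained")
  expect_identical(domainStatusGenomic(ref, "DOM", d_s, "five_prime"),
                   "disrupted")
  expect_identical(domainStatusGenomic(ref, "DOM", d_s - 1L, "five_prime"),
                   "lost")
  expect_identical(domainStatusGenomic(ref, "DOM", d_s, "three_prime"),
                   "retained")
  expect_identical(domainStatusGenomic(ref, "DOM", d_e + 1L, "three_prime"),
                   "lost")
  # monotone sweep: lost -> disrupted -> retained with changes only at d_s, d_e
  sweep <- vapply((d_s - 2L):(d_e + 2L), function(bp)
    domainStatusGenomic(ref, "DOM", bp, "five_prime"), character(1))
  expect_identical(sweep, c(rep("lost", 2), rep("disrupted", d_e - d_s),
                            rep("retained", 3)))
})

test_that("protein-level domain status sees premature stops that genomic status cannot", {
  r5 <- tiny_refs()$FIVE
  nt <- residueToNt(r5, 20, 30)
  # UTR partner whose fused tail stops translation inside DOM: junction
  # placed mid-domain would be genomically visible, so instead break after
  # residue 22 with an immediate in-frame UTR stop -> residues 23..30 absent
  seq3 <- paste0("AA", "ATG", strrep("GGT", 5), "TAA", "TAACCCCCC")
  r3 <- TranscriptReference("SYN_STOPU.1", "SU", seq3, 3, 23)
  bp5 <- cdsStart(r5) + 3L * 22L - 1L    # 22 full codons retained
  bp3 <- 24L                             # UTR: immediate TAA in frame
  ann <- classifyFusion(r5, bp5, r3, bp3)
  expect_identical(fusionCategory(ann), "utr_fusion")
  pred <- predictFusionProtein(r5, bp5, r3, bp3)
  expect_identical(stopOrigin(pred), "premature")
  expect_identical(domainStatusGenomic(r5, "DOM", bp5, "five_prime"),
                   "disrupted")
  expect_identical(domainStatusProtein(pred, r5, "DOM", bp5, "five_prime"),
                   "disrupted")
  # oracle: residue-set intersection on the constructed protein
  present <- 20:30 <= nchar(predictedSequence(pred))
  expect_true(any(present) && !all(present))

  # consistency: in-frame fusion breaking after the domain keeps both views
  r3b <- tiny_refs()$THREE
  bp5b <- nt[["nt_end"]] + 3L  # phase 0 by construction (d_e has phase 2)
  stopifnot((bp5b - cdsStart(r5) + 1L) %% 3L == 0L)
  bp3b <- cdsStart(r3b) + 3L
  predb <- predictFusionProtein(r5, bp5b, r3b, bp3b)
  expect_identical(stopOrigin(predb), "native_3prime")
  expect_identical(domainStatusGenomic(r5, "DOM", bp5b, "five_prime"),
                   domainStatusProtein(predb, r5, "DOM", bp5b, "five_prime"))
  # readthrough retains every 5' domain in both views
  predc <- predictFusionProtein(r5, cdsEnd(r5), r3b, cdsStart(r3b))
  expect_identical(domainStatusProtein(predc, r5, "DOM", cdsEnd(r5),
                                       "five_prime"),
                   "retained")
})

test_that("3'-side protein domain status follows the chimeric reading frame", {
  refs <- tiny_refs(seed = 31L)
  r5 <- refs$FIVE
  r3 <- makeToyReference("T3D", utr5Len = 9L, nCodons = 50L, utr3Len = 20L,
                         seed = 77L,
                         domains = data.frame(name = "HOX", residueStart = 20L,
                                              residueEnd = 30L, source = ""))
  bp5 <- cdsStart(r5) + 29L               # phase 0
  bp3_in <- cdsStart(r3) + 3L             # phase 0: in frame, HOX upstream-intact
  pred_in <- predictFusionProtein(r5, bp5, r3, bp3_in)
  expect_identical(domainStatusProtein(pred_in, r3, "HOX", bp3_in,
                                       "three_prime",
                                       cdsStart5 = cdsStart(r5), bp5 = bp5),
                   "retained")
  bp3_oof <- cdsStart(r3) + 4L            # phase 1: frame lost downstream
  pred_oof <- predictFusionProtein(r5, bp5, r3, bp3_oof)
  expect_identical(domainStatusProtein(pred_oof, r3, "HOX", bp3_oof,
                                       "three_prime",
                                       cdsStart5 = cdsStart(r5), bp5 = bp5),
                   "lost")
  # junction inside the domain: codons downstream of the junction survive
  bp3_mid <- residueToNt(r3, 25, 25)[["nt_start"]]
  stopifnot((bp3_mid - cdsStart(r3)) %% 3L == 0L)
  pred_mid <- predictFusionProtein(r5, bp5, r3, bp3_mid)
  expect_identical(domainStatusProtein(pred_mid, r3, "HOX", bp3_mid,
                                       "three_prime",
                                       cdsStart5 = cdsStart(r5), bp5 = bp5),
                   "disrupted")
})

test_that("annotateDatabase is total: sentinels and per-record failures, never fatal", {
  refs <- tiny_refs()
  expect_identical(nrow(annotateDatabase(
    HarmonizedDatabase(records(simulateCohort(
      simulationConfig(seed = 1, nRecords = 1, partnerMix = c(THREE = 1),
                       domainRetentionTarget = c(DOM = 1),
                       fivePrimeGene = "FIVE"), refs)$db)[0, ]),
    referenceMap(refs))), 0L)
  sim <- simulateCohort(simulationConfig(seed = 9, nRecords = 50,
                                         partnerMix = c(THREE = 1),
                                         domainRetentionTarget = c(DOM = 0.6),
                                         fivePrimeGene = "FIVE",
                                         nExonRecords = 1),
                        refs)
  db <- assignAmbiguousBases(sim$db, referenceMap(refs))
  ann <- annotateDatabase(db, referenceMap(refs))
  expect_identical(nrow(ann), 51L)
  expect_identical(sum(ann$status == "ok"), 50L)
  expect_identical(ann$status[ann$resolution == "exon"], "not_annotatable")
  # unknown accession degrades to a per-record failure
  bad <- records(db)
  bad$three_prime_accession[1] <- "MISSING.1"
  ann_bad <- annotateDatabase(HarmonizedDatabase(bad), referenceMap(refs))
  expect_identical(sum(ann_bad$status == "failed"), 1L)
  expect_match(ann_bad$failure_reason[ann_bad$status == "failed"],
               "missing reference")
})
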