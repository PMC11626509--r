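# Shared fixtures and independent oracles, built in code.

# Small fast references for unit tests: a 5' partner with one domain and a
# 3' partner with UTRs on both sides.
tiny_refs <- function(seed = 11L) {
  list(
    FIVE = makeToyReference("FIVE", utr5Len = 12L, nCodons = 120L,
                            utr3Len = 30L, seed = seed,
                            domains = data.frame(name = "DOM",
                                                 residueStart = 20L,
                                                 residueEnd = 30L,
                                                 source = "synthetic")),
    THREE = makeToyReference("THREE", utr5Len = 15L, nCodons = 50L,
                             utr3Len = 60L, seed = seed + 1L))
}

# Independent classification oracle: positional rules plus full-chimera
# construction. In the both-in-CDS geometry the frame call asks whether the
# 3' partner's own stop codon, located on the constructed chimera, sits on
# the codon grid read from the 5' CDS start and is a genuine stop triplet.
# No junction-phase arithmetic is used.
oracle_classify <- function(ref5, bp5, ref3, bp3) {
  s5 <- as.character(refSequence(ref5))
  s3 <- as.character(refSequence(ref3))
  cs5 <- cdsStart(ref5); ce5 <- cdsEnd(ref5)
  cs3 <- cdsStart(ref3); ce3 <- cdsEnd(ref3)
  if (bp5 < cs5) return("five_prime_noncoding")
  if (bp5 >= ce5) return("five_prime_readthrough")
  if (bp3 > ce3) return("utr_fusion")
  if (bp3 < cs3) return("three_prime_upstream_of_cds")
  chim <- paste0(substr(s5, 1L, bp5), substr(s3, bp3, nchar(s3)))
  native_stop_start <- bp5 + (ce3 - 2L - bp3 + 1L)
  on_grid <- (native_stop_start - cs5) %% 3L == 0L
  if (bp3 <= ce3 - 2L) {
    # stop codon fully retained: it must sit on the chimeric codon grid and
    # still read as a stop triplet
    codon <- substr(chim, native_stop_start, native_stop_start + 2L)
    if (on_grid && codon %in% c("TAA", "TAG", "TGA"))
      "in_frame_coding" else "out_of_frame_coding"
  } else {
    # breakpoint intrudes into the stop codon; the native 3' frame is still
    # anchored at the (partially lost) stop codon's first base
    if (on_grid) "in_frame_coding" else "out_of_frame_coding"
  }
}

# Annotate a simulated cohort and join with its truth labels.
annotate_with_truth <- function(sim, refs) {
  db <- assignAmbiguousBases(sim$db, referenceMap(refs))
  ann <- annotateDatabase(db, referenceMap(refs))
  keep <- intersect(names(sim$truth), names(ann))
  merge(sim$truth, ann[keep], by = "case_id", suffixes = c(".truth", ".ann"))
}

expect_truth_recovered <- function(sim, refs) {
  m <- annotate_with_truth(sim, refs)
  annotatable <- m$category.truth != "not_annotatable"
  expect_identical(m$category.ann[annotatable], m$category.truth[annotatable])
  expect_identical(m$phase5.ann[annotatable], m$phase5.truth[annotatable])
  expect_identical(m$phase3.ann[annotatable], m$phase3.truth[annotatable])
  for (col in grep("^genomic_", names(sim$truth), value = TRUE)) {
    a <- m[[paste0(col, ".ann")]][annotatable]
    t <- m[[paste0(col, ".truth")]][annotatable]
    expect_identical(a[!is.na(t)], t[!is.na(t)])
  }
  invisible(m)
}

extdata <- function(f) system.file("extdata", f, package = "chimeraframe")
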