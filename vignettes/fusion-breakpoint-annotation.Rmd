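---
title: "Annotating fusion-transcript breakpoints: model, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating fusion-transcript breakpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeraframe)
```

## The coordinate model

Everything in this package is computed on mRNA-sense transcript
coordinates, 1-based and inclusive, matching RefSeq convention. A
`TranscriptReference` carries the CDS span with the stop codon included
(`cdsEnd` is the stop's last base), so the encoded protein has
`(cdsEnd − cdsStart + 1)/3 − 1` residues. Protein domains are stored in
residue space and converted on demand:

* residue *r* occupies nucleotides `cdsStart + 3(r−1)` through
  `cdsStart + 3r − 1`;
* the reading-frame phase of a nucleotide is `(nt − cdsStart) mod 3`, so
  the first base of the start codon has phase 0.

A junction is the pair (last retained base of the 5′ partner, first
retained base of the 3′ partner). This encoding is unambiguous under
RefSeq coordinates and matches how RT-PCR-derived junction sequences are
reported; tables encoded as "first lost base" are converted on ingest
(`junctionConvention = "first_lost"`).

Ambiguous junction bases — bases that could belong to either partner, as
happens with microhomology at the junction — are resolved entirely onto
the 5′ partner *before* any frame computation, because junction phase
depends on the assignment. When the 5′ reference is available the
ambiguous bases are compared to the reference at the extended positions
and a mismatch flags the record. The per-record ambiguity length is data,
not a model parameter; records whose category would change under the
opposite (3′) assignment can be found by re-annotating with the
ambiguous bases left unassigned on a shifted junction.

## Classification

Categories are decided in a fixed order: 5′ breakpoint upstream of the
CDS (`five_prime_noncoding`), 5′ breakpoint at or beyond the 5′ stop
codon (`five_prime_readthrough` — the partner's own stop terminates
translation, so no fusion protein forms beyond it), 3′ breakpoint in the
3′ UTR (`utr_fusion`), 3′ breakpoint upstream of the 3′ CDS
(`three_prime_upstream_of_cds`), otherwise both breakpoints lie in CDS
and the junction is in frame iff the retained 5′ CDS length and the 3′
entry position have equal phase:

\[ n_5 \bmod 3 \;=\; (p_3 - 1) \bmod 3 . \]

Phase arithmetic is exact where both coordinates are coding; for
geometries it does not cover, full-chimera translation is the arbiter.
The test suite drives both routes against each other on >1,000 random
junction pairs: the independent oracle rebuilds the chimeric mRNA,
locates the 3′ partner's own stop codon on it, and asks whether that stop
sits on the codon grid read from the 5′ CDS start. The two
`three_prime_upstream_of_cds` and readthrough geometries have no
counterpart in published cohorts and are flagged as out-of-cohort rather
than refined further.

Two deliberate conventions:

* **UTR fusions are positional, not stop-defined.** Premature stops
  shortly after the junction are characteristic of 5′-partner::UTR
  fusions but not definitional; the category is assigned from UTR
  membership alone and `junctionToStopNt` is reported as a number.
* **A junction entering within the 3′ partner's stop codon** is still
  classified by phase (the stop anchor defines the native frame), though
  it cannot produce the 3′ partner's native stop. These junctions are
  effectively UTR-fusion-like but are vanishingly rare boundary cases.

## Protein prediction and domain retention

The chimera `ref5[1..bp5] ++ ref3[bp3..end]` is translated from the 5′
CDS start with the standard genetic code. Codons containing N translate
to `X` and never count as stops; a trailing partial codon is ignored. The
stop's origin is `native_3prime` only when the terminating codon is the
3′ partner's own stop read in its native frame; the retained 5′ stop of a
readthrough, or any stop in fused UTR sequence, is `premature`. A
junction-spanning hybrid codon (when `n₅ mod 3 ≠ 0`) is assigned to the
junction residue `floor(n₅/3) + 1`, which keeps residue bookkeeping
deterministic.

Domain retention has two views with one trichotomy
(retained/disrupted/lost):

* **Genomic** — from breakpoint position against the domain's nucleotide
  interval. On the 5′ side a breakpoint equal to the domain's *last*
  nucleotide counts as retained: the final codon is then fully covered,
  so "breakpoint after the 3′ end of the domain" means a
  domain-preserving fusion. Transitions occur exactly at the interval
  ends, which the test suite verifies by exhaustive sweep.
* **Protein** — from the predicted protein: a domain residue counts as
  present only when its codon derives entirely from its own partner, sits
  on the chimeric grid in native frame, precedes any premature stop, and
  translates to the native amino acid. This view sees truncations the
  genomic view cannot (a UTR fusion whose premature stop falls inside a
  domain), and an `X` inside a domain range conservatively demotes
  retained to disrupted.

## Cohort statistics

The analysis set is defined as nucleotide-level records of the requested
partner with RNA evidence and both coordinates present. Within it,
records partition into UTR fusions, in-frame ("bona fide"), out-of-frame,
and a reported remainder. Three denominators circulate in one sentence of
a typical cohort description — the analysis set, its non-UTR subset, and
the in-frame subset — so every fraction stores numerator and denominator
explicitly, and display rounding (round half-up to integer percent) never
touches the stored values. Exon-level records are retained in the
database but excluded from all nucleotide arithmetic: published exon
numbering is not consistent across references, so those records carry a
`not_annotatable` sentinel instead of a guessed coordinate. Literature
cohorts carry PCR-primer ascertainment bias; no correction exists for it,
so it is surfaced as a provenance caveat rather than modelled.

## What the simulator emulates — and what it does not

`simulateCohort()` draws each record's label first and then constructs
coordinates realizing it exactly: matched or mismatched phases for
in/out-of-frame records, a 3′ breakpoint beyond the stop codon for UTR
fusions, and 5′ breakpoints placed relative to the focal domain interval
for retention targets. Class counts use largest-remainder apportionment,
not multinomial sampling, so the realized composition is exact and
summary-level tests can assert equality instead of tolerances. Ambiguous
junction bases are emitted verbatim from the 5′ reference at the
extension positions — mirroring how real junction reads share sequence
with both partners — so harmonization must restore the true junction
byte-for-byte, and the mismatch-warning path is tested by deliberate
corruption.

Default parameters are the published CIC::DUX4 analysis-cohort
composition: 74 records, 32/74 UTR fusions, 37/42 in-frame among coding,
32/37 C1-retained among in-frame. The toy references mirror the real
transcripts' scale: a 1608-residue CIC-like 5′ partner with HMG
(I200–K268) and C1 (R1464–M1519) domains, and partner-shaped DUX4 /
NUTM1 / LEUTX / FOXO4 references. DUX4's homeodomain and transactivation
coordinates are supplied as illustrative configuration because the
literature anchors them only approximately — they are deliberately not
hard-coded as ground truth. The ambiguous-base length distribution is not
published anywhere; the default (70% none, 15%/10%/5% for 1/2/3 bases)
encodes the expectation that most junctions are unambiguous with short
microhomology otherwise.

What passing simulator-based tests shows: the arithmetic pipeline —
harmonization, phase calls, UTR detection, domain calls, partitioning —
is exact on inputs in the harmonized schema. What it does not show:
correctness of upstream literature curation (alignment of published
junction sequences to references is out of scope), behaviour on
transcript isoform mismatches, or anything about fusion expression,
degradation, or transactivation — the annotation records geometry and
truncation only, and deliberately draws no functional inference about
UTR-fusion products.

## Numerical and interface choices

* Degenerate inputs error early and by name: CDS not divisible by three,
  domains outside the protein, coordinates outside the sequence,
  ambiguous-base extension past the reference, empty simulation ranges.
  Internal stop codons in a loaded CDS warn and set a flag rather than
  fail, since published records occasionally carry them.
* Scatter rows order by partner, then 5′ coordinate, then case id — a
  total order, so emitted tables are byte-stable and diffable; the same
  is true of the simulator under a fixed seed, which routes all
  randomness through one generator and restores global RNG state.
* Per-record failures during database annotation (missing reference,
  missing coordinate) become failure rows, never exceptions, so one bad
  record cannot abort a cohort.
* The package surface is R functions plus `scripts/acceptance.R`; the
  analysis is library-shaped, so no shell subcommands are shipped.
* Test problem sizes — 1,100 oracle pairs over five geometries, a
  12-configuration recovery grid, and a 134-record end-to-end cohort —
  were chosen as the smallest sizes at which every code path
  (all six categories, all three domain statuses, ambiguity lengths 0–3,
  exon-level sentinels, per-record failures) is exercised with margin.

## Known limitations

Single-transcript coordinates only: no genomic liftover, no splice-graph
or isoform modelling, and no re-alignment of published junction reads.
The frame rule assumes a simple two-segment chimera; insertions of
untemplated bases at the junction would need to be expressed as ambiguous
bases or a modified reference. Domain calls treat residue identity as the
criterion for presence; conservative substitutions introduced by hybrid
codons count as disruption.
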