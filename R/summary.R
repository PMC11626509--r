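#' Summarize an annotated cohort
#'
#' Computes the cohort partition with explicit denominators. The analysis
#' set is defined as: nucleotide-level records of the requested 3' partner,
#' with the requested evidence source, both breakpoint coordinates present,
#' and successful annotation. Within it, records partition into UTR
#' fusions, in-frame coding fusions, out-of-frame coding fusions, and a
#' reported remainder of other categories. "Bona fide" fusions are the
#' in-frame coding records; domain retention is counted among them from the
#' genomic (breakpoint-position) status of each focal 5'-partner domain.
#'
#' Three denominators circulate in these cohorts — the analysis set, the
#' non-UTR records, and the in-frame records — so every fraction stores its
#' numerator and denominator explicitly. Display percentages round half-up
#' to integer percent; rounding never alters the stored fractions.
#'
#' @param annotations Output of [annotateDatabase()].
#' @param partner 3'-partner gene defining the analysis set.
#' @param focalDomains Character vector of 5'-partner domain names whose
#'   retention is counted among in-frame records.
#' @param evidenceSource Evidence source(s) required for the analysis set.
#' @return A [CohortSummary-class].
#' @export
summarizeCohort <- function(annotations, partner,
                            focalDomains = character(),
                            evidenceSource = "RNA") {
  a <- annotations
  nuc <- a$resolution == "nucleotide"
  counts <- c(n_total_nucleotide = sum(nuc),
              n_total_exon = sum(a$resolution == "exon"))
  by_partner <- if (nrow(a)) {
    tab <- table(a$three_prime_gene[nuc])
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(), character())

  sel <- nuc & a$three_prime_gene %in% partner &
    a$evidence_source %in% evidenceSource &
    !is.na(a$five_prime_last_base) & !is.na(a$three_prime_first_base) &
    a$status == "ok"
  sub <- a[sel, , drop = FALSE]
  n_analysis <- nrow(sub)
  n_utr <- sum(sub$category == "utr_fusion")
  n_in <- sum(sub$category == "in_frame_coding")
  n_out <- sum(sub$category == "out_of_frame_coding")
  n_other <- n_analysis - n_utr - n_in - n_out
  counts <- c(counts,
              n_analysis_set = n_analysis, n_utr_fusion = n_utr,
              n_non_utr = n_in + n_out, n_in_frame = n_in,
              n_out_of_frame = n_out, n_other_categories = n_other)

  frac <- function(name, num, den)
    data.frame(name = name, numerator = num, denominator = den,
               value = if (den > 0) num / den else 0,
               display_pct = if (den > 0)
                 as.integer(round_half_up(100 * num / den)) else 0L,
               stringsAsFactors = FALSE)
  fractions <- rbind(
    frac("utr_fusion_of_analysis_set", n_utr, n_analysis),
    frac("in_frame_of_non_utr", n_in, n_in + n_out))
  dom_retained <- stats::setNames(integer(length(focalDomains)), focalDomains)
  inframe <- sub[sub$category == "in_frame_coding", , drop = FALSE]
  for (dm in focalDomains) {
    col <- paste0("genomic_5p_", dm)
    nr <- if (col %in% names(inframe))
      sum(inframe[[col]] == "retained", na.rm = TRUE) else 0L
    dom_retained[dm] <- nr
    fractions <- rbind(fractions,
                       frac(sprintf("%s_retained_of_in_frame", dm), nr, n_in))
  }
  prov <- c(sprintf("analysis set: partner %s, evidence %s, nucleotide resolution, both coordinates, annotated ok",
                    paste(partner, collapse = "/"),
                    paste(evidenceSource, collapse = "/")),
            "caveat: literature breakpoints are subject to PCR-primer ascertainment bias; no correction applied")
  obj <- new("CohortSummary", counts = counts, byPartner = by_partner,
             domainRetained = dom_retained, fractions = fractions,
             filterProvenance = prov)
  validObject(obj)
  obj
}

#' Plot-ready breakpoint scatter data
#'
#' One row per successfully annotated nucleotide-level record, in
#' deterministic order (3' partner gene, then 5' coordinate, then case_id)
#' so that downstream rendering and file diffs are stable. When references
#' are supplied, their domain nucleotide intervals are attached as the
#' `"domain_tracks"` attribute for axis tracks.
#'
#' @param annotations Output of [annotateDatabase()].
#' @param refs Optional named list of [TranscriptReference-class] objects
#'   for domain tracks.
#' @return data.frame with columns `case_id`, `three_prime_gene`,
#'   `five_prime_last_base`, `three_prime_first_base`, `category`.
#' @export
scatterData <- function(annotations, refs = NULL) {
  a <- annotations
  keep <- a$resolution == "nucleotide" & a$status == "ok" &
    !is.na(a$five_prime_last_base) & !is.na(a$three_prime_first_base)
  out <- a[keep, c("case_id", "three_prime_gene", "five_prime_last_base",
                   "three_prime_first_base", "category"), drop = FALSE]
  out <- out[order(out$three_prime_gene, out$five_prime_last_base,
                   out$case_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(refs)) {
    tracks <- do.call(rbind, lapply(refs, function(r) {
      d <- domains(r)
      if (!nrow(d)) return(NULL)
      data.frame(accession = accession(r), gene = geneSymbol(r),
                 domain = d$name,
                 nt_start = vapply(seq_len(nrow(d)), function(i)
                   residueToNt(r, d$residueStart[i], d$residueEnd[i])[["nt_start"]],
                   integer(1)),
                 nt_end = vapply(seq_len(nrow(d)), function(i)
                   residueToNt(r, d$residueStart[i], d$residueEnd[i])[["nt_end"]],
                   integer(1)),
                 stringsAsFactors = FALSE)
    }))
    rownames(tracks) <- NULL
    attr(out, "domain_tracks") <- tracks
  }
  out
}

#' Render cohort plots
#'
#' Writes presentation-only figures: a breakpoint scatterplot (5' vs 3'
#' coordinate, colored by category, with domain tracks when available and
#' marginal histograms to aid with overplotting) and an arc ("circos-style")
#' partner plot linking 5' breakpoint positions to their 3' partners. No
#' statistic is computed here — everything plotted comes from
#' [scatterData()] and [summarizeCohort()].
#'
#' @param scatter Output of [scatterData()].
#' @param summary A [CohortSummary-class] (used for figure captions only).
#' @param outdir Output directory (created if missing).
#' @param width,height Device size in inches.
#' @return Character vector of files written, invisibly.
#' @export
renderPlots <- function(scatter, summary, outdir, width = 7, height = 6) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop(sprintf("cannot create '%s'", outdir))
  }
  if (file.access(outdir, 2) != 0) stop(sprintf("'%s' is not writable", outdir))
  caption <- sprintf("analysis set n = %d",
                     summaryCounts(summary)[["n_analysis_set"]])
  scatter_file <- file.path(outdir, "breakpoint_scatter.png")
  arc_file <- file.path(outdir, "partner_arcs.png")

  p <- ggplot2::ggplot(scatter,
                       ggplot2::aes(x = five_prime_last_base,
                                    y = three_prime_first_base,
                                    colour = category)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "5' partner breakpoint (last retained base, nt)",
                  y = "3' partner breakpoint (first retained base, nt)",
                  caption = caption) +
    ggplot2::theme_minimal()
  tracks <- attr(scatter, "domain_tracks")
  if (!is.null(tracks) && nrow(tracks)) {
    p <- p + ggplot2::geom_rect(
      data = tracks,
      ggplot2::aes(xmin = nt_start, xmax = nt_end),
      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "steelblue",
      inherit.aes = FALSE)
  }
  main <- p
  if (nrow(scatter) && requireNamespace("patchwork", quietly = TRUE)) {
    top <- ggplot2::ggplot(scatter,
                           ggplot2::aes(x = five_prime_last_base)) +
      ggplot2::geom_histogram(bins = 40, fill = "grey40") +
      ggplot2::theme_void()
    right <- ggplot2::ggplot(scatter,
                             ggplot2::aes(y = three_prime_first_base)) +
      ggplot2::geom_histogram(bins = 40, fill = "grey40") +
      ggplot2::theme_void()
    main <- top + patchwork::plot_spacer() + p + right +
      patchwork::plot_layout(ncol = 2, widths = c(4, 1), heights = c(1, 4))
  }
  ggplot2::ggsave(scatter_file, main, width = width, height = height,
                  dpi = 150)

  arc <- arc_plot_data(scatter)
  q <- ggplot2::ggplot() + ggplot2::theme_void() +
    ggplot2::coord_fixed() + ggplot2::labs(caption = caption)
  if (nrow(arc$nodes)) {
    q <- q +
      ggplot2::geom_path(data = arc$links,
                         ggplot2::aes(x = x, y = y,
                                      group = id,
                                      colour = partner),
                         alpha = 0.5) +
      ggplot2::geom_text(data = arc$nodes,
                         ggplot2::aes(x = 1.15 * x, y = 1.15 * y,
                                      label = gene), size = 3)
  }
  ggplot2::ggsave(arc_file, q, width = width, height = height, dpi = 150)
  invisible(c(scatter_file, arc_file))
}

# Lay records out on a circle: one arc sector per gene (the shared 5'
# partner plus each 3' partner), quadratic Bezier chords through the
# center. Pure layout, no statistics.
arc_plot_data <- function(scatter) {
  if (!nrow(scatter))
    return(list(nodes = data.frame(), links = data.frame()))
  genes <- c("5' partner", sort(unique(scatter$three_prime_gene)))
  k <- length(genes)
  centers <- seq(0, 2 * pi, length.out = k + 1L)[seq_len(k)]
  nodes <- data.frame(gene = genes, x = cos(centers), y = sin(centers))
  span <- 2 * pi / k * 0.7
  pos_on <- function(sector, frac) centers[sector] + (frac - 0.5) * span
  bezier <- function(a1, a2, n = 20) {
    p0 <- c(cos(a1), sin(a1)); p2 <- c(cos(a2), sin(a2))
    t <- seq(0, 1, length.out = n)
    data.frame(x = (1 - t)^2 * p0[1] + t^2 * p2[1],
               y = (1 - t)^2 * p0[2] + t^2 * p2[2])
  }
  rel5 <- rank(scatter$five_prime_last_base,
               ties.method = "first") / (nrow(scatter) + 1L)
  links <- do.call(rbind, lapply(seq_len(nrow(scatter)), function(i) {
    sector3 <- match(scatter$three_prime_gene[i], genes)
    rel3 <- scatter$three_prime_first_base[i] /
      max(scatter$three_prime_first_base, na.rm = TRUE)
    b <- bezier(pos_on(1L, rel5[i]), pos_on(sector3, rel3))
    b$id <- scatter$case_id[i]
    b$partner <- scatter$three_prime_gene[i]
    b
  }))
  list(nodes = nodes, links = links)
}

#' Export a cohort summary
#'
#' `writeSummaryTsv()` writes counts and fractions as a flat TSV;
#' `writeSummaryJson()` writes the full summary as JSON.
#'
#' @param summary A [CohortSummary-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeSummaryTsv <- function(summary, file) {
  cn <- summaryCounts(summary)
  rows <- data.frame(name = names(cn), numerator = as.integer(cn),
                     denominator = NA_integer_, value = NA_real_,
                     display_pct = NA_integer_, stringsAsFactors = FALSE)
  utils::write.table(rbind(rows, summaryFractions(summary)), file,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname writeSummaryTsv
#' @export
writeSummaryJson <- function(summary, file) {
  jsonlite::write_json(
    list(counts = as.list(summaryCounts(summary)),
         by_partner = as.list(summary@byPartner),
         domain_retained = as.list(summary@domainRetained),
         fractions = summaryFractions(summary),
         filter_provenance = summary@filterProvenance),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
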