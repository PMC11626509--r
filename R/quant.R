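#' Relative expression by the 2^(delta-Ct) method
#'
#' `2^(ctHousekeeping - ctTarget)`: expression of a target gene relative to
#' a housekeeping gene from qPCR cycle-threshold values. Each extra cycle
#' needed for the target halves the value.
#'
#' @param ctTarget,ctHousekeeping Finite Ct values (may be vectors,
#'   recycled).
#' @return Fold value(s) relative to the housekeeping gene.
#' @export
relativeExpression <- function(ctTarget, ctHousekeeping) {
  if (!all(is.finite(ctTarget)) || !all(is.finite(ctHousekeeping)))
    stop("Ct values must be finite")
  2^(ctHousekeeping - ctTarget)
}

#' Two-anchor percent normalization
#'
#' Linearly rescales values so that the mean of the negative-control (EV)
#' condition maps to 0% and the mean of the positive-anchor (full-length
#' fusion) condition maps to 100%:
#' `100 * (x - mean(ev)) / (mean(anchor) - mean(ev))`.
#'
#' @param x Value(s) to normalize.
#' @param evValues Replicate values of the 0% anchor condition.
#' @param anchorValues Replicate values of the 100% anchor condition.
#' @return Percent value(s).
#' @export
anchorNormalize <- function(x, evValues, anchorValues) {
  m0 <- mean(evValues); m1 <- mean(anchorValues)
  if (!is.finite(m0) || !is.finite(m1)) stop("anchor means must be finite")
  if (m1 == m0) stop("degenerate anchors: the two anchor means are equal")
  100 * (x - m0) / (m1 - m0)
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` comparisons, clipped to [0, 1].
#' Monotone nondecreasing in both `p` and `m`; identity at `m = 1`. `m` is
#' the number of pairwise comparisons actually made (caller-supplied), as
#' in selected-comparison post hoc testing.
#'
#' @param p P value(s) in [0, 1].
#' @param m Number of comparisons, `m >= 1`.
#' @return Adjusted p value(s).
#' @export
sidakAdjust <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = FALSE) || any(is.na(p)))
    stop("p values must lie in [0, 1]")
  if (any(m < 1)) stop("m must be >= 1")
  pmin(pmax(1 - (1 - p)^m, 0), 1)
}

#' Classical one-way ANOVA
#'
#' Between/within mean-square F ratio with `(k - 1, N - k)` degrees of
#' freedom, computed via [stats::oneway.test()] with `var.equal = TRUE`.
#'
#' @param groups List of >= 2 numeric replicate vectors, each of length
#'   >= 2.
#' @return List with `F`, `p_value`, `df_between`, `df_within`.
#' @export
oneWayAnova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 2L))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  within_ss <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
  if (within_ss == 0) {
    if (length(unique(vapply(groups, mean, numeric(1)))) > 1L)
      stop("undefined F: zero within-group variance with unequal means")
    return(list(F = 0, p_value = 1,
                df_between = length(groups) - 1L,
                df_within = length(y) - length(groups)))
  }
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p_value = unname(fit$p.value),
       df_between = unname(fit$parameter[1]),
       df_within = unname(fit$parameter[2]))
}

#' Ellipsoid tumor volume
#'
#' `(pi/6) * length * width * height` from caliper measurements.
#'
#' @param length,width,height Nonnegative dimensions (same unit; volume is
#'   in that unit cubed).
#' @return Volume(s).
#' @export
tumorVolume <- function(length, width, height) {
  if (any(c(length, width, height) < 0)) stop("dimensions must be nonnegative")
  (pi / 6) * length * width * height
}

#' Area-scaled, background-subtracted stain signal
#'
#' Total stain signal per well: the mean signal intensity over the
#' measured area times that area, minus the background mean (measured
#' outside the plate) times the same area.
#'
#' @param meanSignal Mean signal intensity within the well.
#' @param area Measured area (> 0).
#' @param backgroundMean Mean background intensity over the same area.
#' @return Background-subtracted total signal.
#' @export
crystalVioletTotal <- function(meanSignal, area, backgroundMean) {
  if (any(area <= 0)) stop("area must be positive")
  meanSignal * area - backgroundMean * area
}

#' Aggregate technical replicates within experiments
#'
#' Averages technical replicates within each experiment first, then
#' returns the per-experiment means for cross-experiment statistics (the
#' per-experiment mean, not the pooled technical replicate, is the unit of
#' analysis).
#'
#' @param replicates List of numeric vectors, one per independent
#'   experiment, each holding that experiment's technical replicates.
#' @return Numeric vector of per-experiment means.
#' @export
aggregateReplicates <- function(replicates) {
  stopifnot(is.list(replicates), all(lengths(replicates) >= 1L))
  vapply(replicates, mean, numeric(1))
}
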