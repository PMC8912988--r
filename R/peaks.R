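#' @include eem-model.R
NULL

#' Define a peak region
#'
#' @param name peak label.
#' @param excitationNm excitation wavelength (nm).
#' @param emissionLoNm,emissionHiNm closed emission band (nm); give only the
#'   lower bound for a point peak.
#' @return A \code{\linkS4class{PeakDefinition}}.
#' @export
peakDefinition <- function(name, excitationNm, emissionLoNm,
                           emissionHiNm = emissionLoNm) {
  new("PeakDefinition", name = name, excitationNm = as.numeric(excitationNm),
      emissionBand = c(as.numeric(emissionLoNm), as.numeric(emissionHiNm)))
}

setMethod("show", "PeakDefinition", function(object) {
  b <- object@emissionBand
  em <- if (b[1] == b[2]) sprintf("%g", b[1]) else sprintf("%g-%g", b[1], b[2])
  cat(sprintf("Peak %s: ex %g nm / em %s nm\n", object@name,
              object@excitationNm, em))
  invisible(NULL)
})

#' The standard Coble-style peak set
#'
#' Peak T (tryptophan-like, ex 275 / em 340), Peak C (humic-like, ex 340 /
#' em 420-470) and Peak C+ (red-shifted humic-like, ex 400 / em 470-505)
#' are the primary set; Peak B (tyrosine-like, ex 275 / em 305) and Peak M
#' (marine humic-like, ex 300 / em 370-420, the midpoint of its
#' conventional excitation range) are included for completeness.
#'
#' @param names which peaks to return (default all five).
#' @return A named list of \code{\linkS4class{PeakDefinition}} objects.
#' @examples
#' standardPeaks(c("T", "C", "C+"))
#' @export
standardPeaks <- function(names = c("T", "C", "C+", "B", "M")) {
  all <- list(
    "T"  = peakDefinition("T", 275, 340),
    "C"  = peakDefinition("C", 340, 420, 470),
    "C+" = peakDefinition("C+", 400, 470, 505),
    "B"  = peakDefinition("B", 275, 305),
    "M"  = peakDefinition("M", 300, 370, 420)
  )
  unknown <- setdiff(names, base::names(all))
  if (length(unknown))
    stop("unknown standard peak(s): ", paste(unknown, collapse = ", "))
  all[names]
}

#' Load peak definitions from a config list
#'
#' Accepts a list of entries with fields \code{name}, \code{ex_nm},
#' \code{em_lo_nm} and optional \code{em_hi_nm}, as parsed from a JSON
#' config block; overrides or extends the standard set.
#'
#' @param entries list of peak entries.
#' @return A named list of \code{\linkS4class{PeakDefinition}} objects.
#' @export
peaksFromConfig <- function(entries) {
  peaks <- lapply(entries, function(e) {
    if (is.null(e$name) || is.null(e$ex_nm) || is.null(e$em_lo_nm))
      stop("peak config entries need fields: name, ex_nm, em_lo_nm")
    peakDefinition(e$name, e$ex_nm, e$em_lo_nm,
                   if (is.null(e$em_hi_nm)) e$em_lo_nm else e$em_hi_nm)
  })
  names(peaks) <- vapply(peaks, function(p) p@name, "")
  peaks
}

#' Pick a peak intensity from a corrected EEM
#'
#' Takes the emission cross-section at the excitation column nearest the
#' peak's excitation wavelength and averages the unmasked intensities over
#' grid points whose emission lies in the peak's band.  Point peaks (band
#' lo == hi) read the single nearest emission pixel, optionally widened by
#' \code{emHalfWidthNm}.
#'
#' @param eem a QSU-unit \code{\linkS4class{EEMatrix}}.
#' @param peak a \code{\linkS4class{PeakDefinition}} or standard peak label.
#' @param emHalfWidthNm half-width (nm) added around point-peak emission
#'   coordinates (default 0: single pixel).
#' @return The mean QSU intensity over the peak region.
#' @examples
#' e <- EEMatrix(matrix(2, 220, 260), excitation = seq(240, 499),
#'               emission = seq(250, 469), unit = "QSU")
#' pickPeak(e, "T")
#' @export
pickPeak <- function(eem, peak, emHalfWidthNm = 0) {
  stopifnot(is(eem, "EEMatrix"))
  if (is.character(peak)) peak <- standardPeaks(peak)[[1]]
  stopifnot(is(peak, "PeakDefinition"))
  if (eem@unit != "QSU")
    stop("pickPeak requires a QSU-normalized EEM")
  j <- nearestIndex(eem@excitation, peak@excitationNm)
  band <- peak@emissionBand
  if (band[1] == band[2]) {
    ctr <- nearestIndex(eem@emission, band[1])
    if (emHalfWidthNm > 0) {
      rows <- which(abs(eem@emission - eem@emission[ctr]) <= emHalfWidthNm)
    } else rows <- ctr
  } else {
    rows <- which(eem@emission >= band[1] & eem@emission <= band[2])
    if (!length(rows))
      stop(sprintf("no emission grid points inside band [%g, %g] nm",
                   band[1], band[2]))
  }
  masked <- eem@mask[rows, j]
  if (mean(masked) > 0.5)
    stop(sprintf(
      "peak %s: %d of %d band pixels masked (> 50%%), intensity unreliable",
      peak@name, sum(masked), length(rows)))
  mean(eem@intensity[rows, j][!masked])
}

#' Construct a peak time series
#'
#' @param timesH strictly increasing sampling times (h).
#' @param values numeric matrix (time rows x peak columns, named) of QSU
#'   intensities.
#' @param replicate,condition identifying labels.
#' @return A \code{\linkS4class{PeakSeries}}.
#' @export
PeakSeries <- function(timesH, values, replicate = "rep1",
                       condition = "unknown") {
  values <- as.matrix(values)
  new("PeakSeries", timesH = as.numeric(timesH), values = values,
      replicate = replicate, condition = condition)
}

#' @describeIn PeakSeries peak labels
#' @param x a \code{PeakSeries}
#' @export
setMethod("peakNames", "PeakSeries", function(x) colnames(x@values))

#' @describeIn PeakSeries sampling times (h)
#' @export
setMethod("sampleTimes", "PeakSeries", function(x) x@timesH)

#' @describeIn PeakSeries QSU intensities of one peak (or the full matrix
#'   when \code{peak} is missing)
#' @param peak peak label
#' @export
setMethod("peakValues", "PeakSeries", function(x, peak) {
  if (missing(peak)) return(x@values)
  if (!peak %in% colnames(x@values))
    stop(sprintf("peak '%s' not in series (has: %s)", peak,
                 paste(colnames(x@values), collapse = ", ")))
  x@values[, peak]
})

setMethod("show", "PeakSeries", function(object) {
  cat(sprintf("PeakSeries [%s / %s]: %d times (%g-%g h), peaks: %s\n",
              object@condition, object@replicate, length(object@timesH),
              if (length(object@timesH)) min(object@timesH) else NA,
              if (length(object@timesH)) max(object@timesH) else NA,
              paste(colnames(object@values), collapse = ", ")))
  invisible(NULL)
})

#' @export
as.data.frame.PeakSeries <- function(x, ...) {
  v <- x@values
  data.frame(
    condition = x@condition, replicate = x@replicate,
    time_h = rep(x@timesH, times = ncol(v)),
    peak = rep(colnames(v), each = nrow(v)),
    qsu = as.vector(v), row.names = NULL)
}

#' Extract per-peak kinetics from a set of corrected EEMs
#'
#' Applies \code{\link{pickPeak}} to every (time, peak) combination.
#'
#' @param eems list of QSU \code{\linkS4class{EEMatrix}} objects.
#' @param timesH numeric sampling times (h), one per EEM; duplicates are an
#'   error.
#' @param peaks list of \code{\linkS4class{PeakDefinition}} objects
#'   (default: Peaks T, C, C+).
#' @param replicate,condition labels carried into the result.
#' @param emHalfWidthNm passed to \code{\link{pickPeak}}.
#' @return A \code{\linkS4class{PeakSeries}}.
#' @export
extractSeries <- function(eems, timesH, peaks = standardPeaks(c("T", "C", "C+")),
                          replicate = "rep1", condition = "unknown",
                          emHalfWidthNm = 0) {
  stopifnot(length(eems) == length(timesH))
  if (anyDuplicated(timesH))
    stop("duplicate sampling times: ",
         paste(unique(timesH[duplicated(timesH)]), collapse = ", "))
  ord <- order(timesH)
  timesH <- timesH[ord]; eems <- eems[ord]
  labels <- vapply(peaks, function(p) p@name, "")
  vals <- matrix(NA_real_, length(timesH), length(peaks),
                 dimnames = list(NULL, labels))
  for (i in seq_along(eems))
    for (k in seq_along(peaks))
      vals[i, k] <- pickPeak(eems[[i]], peaks[[k]], emHalfWidthNm)
  PeakSeries(timesH, vals, replicate = replicate, condition = condition)
}

#' Percent change of a peak between two time points
#'
#' \code{100 * (v(t2) - v(t1)) / v(t1)}.  A zero baseline is an error: the
#' very large percentages seen in peak kinetics arise from near-zero (not
#' zero) baselines, and a zero denominator has no defined percent change.
#'
#' @param series a \code{\linkS4class{PeakSeries}}.
#' @param peak peak label.
#' @param t1,t2 times (h) present in the series, \code{t1 < t2}.
#' @return Percent change (e.g. +100 for a doubling).
#' @export
percentChange <- function(series, peak, t1, t2) {
  stopifnot(is(series, "PeakSeries"), t1 < t2)
  v <- peakValues(series, peak)
  i1 <- which(abs(series@timesH - t1) < 1e-9)
  i2 <- which(abs(series@timesH - t2) < 1e-9)
  if (!length(i1) || !length(i2))
    stop(sprintf("times %g and %g h must both be present in the series",
                 t1, t2))
  if (v[i1] == 0)
    stop(sprintf("peak %s is zero at t1 = %g h: percent change undefined",
                 peak, t1))
  100 * (v[i2] - v[i1]) / v[i1]
}
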