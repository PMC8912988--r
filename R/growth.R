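#' @include eem-io.R
NULL

#' Viable count from a plate count
#'
#' \code{colonies * dilutionFactor / platedVolumeMl}.  Zero colonies give
#' 0 CFU/ml, which downstream readers treat as below the detection limit
#' (\code{NA}) rather than as a true zero density.
#'
#' @param colonies non-negative colony counts.
#' @param dilutionFactor dilution factors (>= 1, e.g. 1e3 for a 10^-3
#'   dilution).
#' @param platedVolumeMl plated volumes in ml (> 0).
#' @return CFU per ml (vectorized).
#' @examples
#' cfuFromPlate(50, 1e3, 0.05)  # 1e6 CFU/ml
#' @export
cfuFromPlate <- function(colonies, dilutionFactor, platedVolumeMl) {
  if (any(colonies < 0, na.rm = TRUE)) stop("colony counts must be >= 0")
  if (any(dilutionFactor < 1, na.rm = TRUE))
    stop("dilution factors must be >= 1")
  if (any(platedVolumeMl <= 0, na.rm = TRUE))
    stop("plated volume must be > 0 ml")
  colonies * dilutionFactor / platedVolumeMl
}

#' Enumeration-corrected per-cell fluorescence
#'
#' Normalizes a QSU intensity to the fluorescence produced per 10^6 cells:
#' \code{f = qsu / (cfuPerMl / 1e6)}, with \code{log10(f)} as a derived
#' column (the usual plotting scale).  A non-positive or missing viable
#' count is an error: per-cell fluorescence is undefined without cells.
#'
#' @param qsu fluorescence intensities (QSU).
#' @param cfuPerMl matching viable counts (CFU per ml, > 0).
#' @param peak optional peak labels.
#' @param timeH optional times (h).
#' @return A data.frame with columns \code{peak}, \code{time_h}, \code{f}
#'   (QSU per 10^6 CFU) and \code{log10_f}.
#' @examples
#' perCellFluorescence(55.2, 1e6)$f  # 55.2 QSU per 10^6 cells
#' @export
perCellFluorescence <- function(qsu, cfuPerMl, peak = NA_character_,
                                timeH = NA_real_) {
  if (any(is.na(cfuPerMl)) || any(cfuPerMl <= 0))
    stop("per-cell fluorescence undefined for non-positive or missing CFU/ml")
  f <- qsu / (cfuPerMl / 1e6)
  data.frame(peak = peak, time_h = timeH, f = f,
             log10_f = ifelse(f > 0, log10(f), NA_real_))
}

#' Classify lag, exponential and stationary growth phases
#'
#' Computes piecewise slopes of log10(CFU/ml) between consecutive
#' observations.  The lag phase is the initial run of slopes below
#' \code{lagSlopeMax}; the exponential phase is the following run of slopes
#' at or above \code{statSlopeMax}; the remainder is stationary.  The
#' returned intervals partition the observed time range in the order lag,
#' exponential, stationary; absent phases are omitted.
#'
#' A curve with no slope ever reaching \code{lagSlopeMax} is returned as a
#' single lag interval with attribute \code{no_growth = TRUE}.
#'
#' @param curve a \code{\linkS4class{GrowthCurve}} with at least 4 observed
#'   points.
#' @param lagSlopeMax slope (log10 CFU per h) below which growth counts as
#'   lag (default 0.05).
#' @param statSlopeMax slope below which the exponential run ends (default
#'   0.05).
#' @return A data.frame with columns \code{phase}, \code{t_start},
#'   \code{t_end} (h).
#' @examples
#' g <- GrowthCurve(c(0, 2, 4, 6, 8, 10, 12, 24, 48),
#'                  1e5 * 10^pmin(pmax(c(0, 2, 4, 6, 8, 10, 12, 24, 48) - 6,
#'                                     0) / 3, 2))
#' classifyPhases(g)
#' @export
classifyPhases <- function(curve, lagSlopeMax = 0.05, statSlopeMax = 0.05) {
  stopifnot(is(curve, "GrowthCurve"))
  ok <- !is.na(curve@cfuPerMl)
  t <- curve@timesH[ok]
  v <- log10(curve@cfuPerMl[ok])
  if (length(t) < 4L)
    stop(sprintf("need at least 4 observed time points, have %d", length(t)))
  slope <- diff(v) / diff(t)
  firstGrow <- which(slope >= lagSlopeMax)
  if (!length(firstGrow)) {
    out <- data.frame(phase = "lag", t_start = t[1], t_end = t[length(t)])
    attr(out, "no_growth") <- TRUE
    return(out)
  }
  i1 <- firstGrow[1]                 # first growing interval
  after <- which(slope < statSlopeMax)
  after <- after[after > i1]
  i2 <- if (length(after)) after[1] else length(slope) + 1L
  # boundaries: lag [t1, t[i1]], exponential [t[i1], t[i2]], stationary rest
  rows <- list()
  if (i1 > 1L)
    rows$lag <- c(t[1], t[i1])
  rows$exponential <- c(t[i1], t[i2])
  if (i2 <= length(slope))
    rows$stationary <- c(t[i2], t[length(t)])
  data.frame(phase = names(rows),
             t_start = vapply(rows, `[`, 0, 1),
             t_end = vapply(rows, `[`, 0, 2),
             row.names = NULL)
}

#' Per-cell fluorescence along a time course
#'
#' Joins a peak series with its matching growth curve on shared sampling
#' times and computes \code{f} (QSU per 10^6 CFU) for every peak at every
#' shared time with an observed (above-detection) viable count.
#'
#' @param series a \code{\linkS4class{PeakSeries}}.
#' @param growth the matching \code{\linkS4class{GrowthCurve}}.
#' @return A data.frame with columns \code{condition}, \code{replicate},
#'   \code{peak}, \code{time_h}, \code{qsu}, \code{cfu_per_ml}, \code{f},
#'   \code{log10_f}.
#' @export
perCellSeries <- function(series, growth) {
  stopifnot(is(series, "PeakSeries"), is(growth, "GrowthCurve"))
  shared <- intersect(series@timesH, growth@timesH)
  if (!length(shared))
    stop("series and growth curve share no sampling times")
  si <- match(shared, series@timesH)
  gi <- match(shared, growth@timesH)
  cfu <- growth@cfuPerMl[gi]
  det <- !is.na(cfu)
  out <- do.call(rbind, lapply(colnames(series@values), function(p) {
    pc <- perCellFluorescence(series@values[si, p][det], cfu[det],
                              peak = p, timeH = shared[det])
    pc$qsu <- series@values[si, p][det]
    pc$cfu_per_ml <- cfu[det]
    pc
  }))
  out$condition <- series@condition
  out$replicate <- series@replicate
  out[, c("condition", "replicate", "peak", "time_h", "qsu",
          "cfu_per_ml", "f", "log10_f")]
}
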