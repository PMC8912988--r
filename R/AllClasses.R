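#' @import methods
NULL

.validWavelengths <- function(values, what) {
  if (length(values) == 0L)
    return(sprintf("%s axis is empty", what))
  if (anyNA(values) || any(!is.finite(values)))
    return(sprintf("%s axis contains non-finite values", what))
  if (any(values <= 0))
    return(sprintf("%s axis contains non-positive wavelengths", what))
  if (is.unsorted(values, strictly = TRUE))
    return(sprintf("%s axis is not strictly increasing", what))
  NULL
}

#' EEMatrix: an excitation-emission matrix
#'
#' Fluorescence intensity on a rectangular grid of excitation and emission
#' wavelengths.  Rows follow the emission axis and columns the excitation
#' axis, matching the on-disk dialect (excitation wavelengths in the header
#' row, emission wavelengths in the first column).  Cells flagged in
#' \code{mask} are invalid (e.g. Rayleigh scatter) and are ignored by
#' downstream peak quantification.
#'
#' The \code{unit} tag is either \code{"raw"} (instrument counts) or
#' \code{"QSU"} (quinine sulfate units); it changes only through
#' \code{\link{normalizeQSU}}.
#'
#' @slot excitation numeric, strictly increasing excitation wavelengths (nm).
#' @slot emission numeric, strictly increasing emission wavelengths (nm).
#' @slot intensity numeric matrix, \code{length(emission)} rows by
#'   \code{length(excitation)} columns.
#' @slot unit character, \code{"raw"} or \code{"QSU"}.
#' @slot mask logical matrix, same shape as \code{intensity}; \code{TRUE}
#'   marks masked/invalid cells.
#' @slot meta list of free-form labels (sample id, time in h, condition,
#'   processing log).
#'
#' @seealso \code{\link{EEMatrix}} (constructor), \code{\link{readEEM}},
#'   \code{\link{preprocessPipeline}}
#' @exportClass EEMatrix
setClass("EEMatrix",
  representation(
    excitation = "numeric",
    emission   = "numeric",
    intensity  = "matrix",
    unit       = "character",
    mask       = "matrix",
    meta       = "list"
  )
)

setValidity("EEMatrix", function(object) {
  msg <- .validWavelengths(object@excitation, "excitation")
  if (!is.null(msg)) return(msg)
  msg <- .validWavelengths(object@emission, "emission")
  if (!is.null(msg)) return(msg)
  d <- c(length(object@emission), length(object@excitation))
  if (!identical(dim(object@intensity), as.integer(d)))
    return("intensity shape does not match (emission x excitation) axes")
  if (!identical(dim(object@mask), as.integer(d)))
    return("mask shape does not match intensity shape")
  if (!is.logical(object@mask) || anyNA(object@mask))
    return("mask must be logical with no NA")
  if (length(object@unit) != 1L || !object@unit %in% c("raw", "QSU"))
    return("unit must be one of 'raw', 'QSU'")
  vals <- object@intensity[!object@mask]
  if (any(!is.finite(vals)))
    return("unmasked intensities must be finite")
  TRUE
})

#' AbsorbanceSpectrum: wavelength-resolved absorbance
#'
#' Dimensionless absorbance (1 cm reference path) on a wavelength grid,
#' queried by linear interpolation anywhere inside its coverage.  Used by
#' the inner-filter-effect correction.
#'
#' @slot wavelength numeric, strictly increasing wavelengths (nm).
#' @slot absorbance numeric, absorbance values (>= 0), same length.
#'
#' @seealso \code{\link{AbsorbanceSpectrum}}, \code{\link{absorbanceAt}},
#'   \code{\link{correctIFE}}
#' @exportClass AbsorbanceSpectrum
setClass("AbsorbanceSpectrum",
  representation(wavelength = "numeric", absorbance = "numeric")
)

setValidity("AbsorbanceSpectrum", function(object) {
  msg <- .validWavelengths(object@wavelength, "wavelength")
  if (!is.null(msg)) return(msg)
  if (length(object@absorbance) != length(object@wavelength))
    return("absorbance and wavelength lengths differ")
  if (anyNA(object@absorbance) || any(!is.finite(object@absorbance)))
    return("absorbance contains non-finite values")
  if (any(object@absorbance < 0))
    return("absorbance contains negative values (clip on construction)")
  TRUE
})

#' QsReference: quinine sulfate normalization reference
#'
#' Raw-count fluorescence intensity of a 1 ug/L quinine sulfate standard at
#' excitation 347.5 nm / emission 450 nm.  Dividing a raw EEM by this value
#' expresses it in quinine sulfate units (QSU): 1 QSU is the fluorescence of
#' a 1 ug/L quinine sulfate solution.
#'
#' @slot intensityRaw numeric scalar > 0, the reference raw intensity.
#' @slot source character, \code{"scalar"} or \code{"derived-from-EEM"}.
#'
#' @seealso \code{\link{qsReference}}, \code{\link{qsReferenceFromEEM}},
#'   \code{\link{normalizeQSU}}
#' @exportClass QsReference
setClass("QsReference",
  representation(intensityRaw = "numeric", source = "character")
)

setValidity("QsReference", function(object) {
  if (length(object@intensityRaw) != 1L || !is.finite(object@intensityRaw) ||
      object@intensityRaw <= 0)
    return("intensityRaw must be a single positive finite number")
  if (!object@source %in% c("scalar", "derived-from-EEM"))
    return("source must be 'scalar' or 'derived-from-EEM'")
  TRUE
})

#' PeakDefinition: a named optical peak region
#'
#' A Coble-style peak: a single excitation wavelength and a closed emission
#' band.  Point peaks (T, B) have a degenerate band (lo == hi) and read the
#' single nearest emission pixel.
#'
#' @slot name character peak label ("T", "B", "C", "C+", "M", or custom).
#' @slot excitationNm numeric scalar, excitation wavelength (nm).
#' @slot emissionBand numeric length-2, closed emission interval (nm),
#'   \code{lo <= hi}.
#'
#' @seealso \code{\link{standardPeaks}}, \code{\link{pickPeak}}
#' @exportClass PeakDefinition
setClass("PeakDefinition",
  representation(name = "character", excitationNm = "numeric",
                 emissionBand = "numeric")
)

setValidity("PeakDefinition", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a non-empty string")
  if (length(object@excitationNm) != 1L || !is.finite(object@excitationNm) ||
      object@excitationNm <= 0)
    return("excitationNm must be a single positive wavelength")
  b <- object@emissionBand
  if (length(b) != 2L || anyNA(b) || b[1] > b[2] || any(b <= 0))
    return("emissionBand must be c(lo, hi) with 0 < lo <= hi")
  TRUE
})

#' PeakSeries: time-resolved peak intensities
#'
#' Per-peak QSU intensities over an ordered set of sampling times, for one
#' replicate of one experimental condition.
#'
#' @slot timesH numeric, strictly increasing sampling times (h).
#' @slot values numeric matrix, one row per time, one column per peak
#'   (column names are the peak labels); values in QSU.
#' @slot replicate character replicate identifier.
#' @slot condition character condition label (e.g. "SFW0").
#'
#' @seealso \code{\link{extractSeries}}, \code{\link{percentChange}}
#' @exportClass PeakSeries
setClass("PeakSeries",
  representation(timesH = "numeric", values = "matrix",
                 replicate = "character", condition = "character")
)

setValidity("PeakSeries", function(object) {
  t <- object@timesH
  if (length(t) && (anyNA(t) || is.unsorted(t, strictly = TRUE)))
    return("timesH must be strictly increasing")
  if (nrow(object@values) != length(t))
    return("values must have one row per time")
  if (is.null(colnames(object@values)) && ncol(object@values) > 0)
    return("values columns must be named by peak label")
  TRUE
})

#' GrowthCurve: viable-count time series
#'
#' Colony-forming-unit densities (CFU per ml) over an ordered set of
#' sampling times for one replicate of one condition.  Observations below
#' the plating detection limit are carried as \code{NA} (not zero) and are
#' excluded from per-cell fluorescence.
#'
#' @slot timesH numeric, strictly increasing sampling times (h).
#' @slot cfuPerMl numeric, CFU per ml; positive or \code{NA} (below
#'   detection).
#' @slot replicate character replicate identifier.
#' @slot condition character condition label.
#' @slot meta list of free-form attributes (e.g. simulation ground truth).
#'
#' @seealso \code{\link{classifyPhases}}, \code{\link{perCellFluorescence}}
#' @exportClass GrowthCurve
setClass("GrowthCurve",
  representation(timesH = "numeric", cfuPerMl = "numeric",
                 replicate = "character", condition = "character",
                 meta = "list")
)

setValidity("GrowthCurve", function(object) {
  t <- object@timesH
  if (length(t) == 0L) return("empty growth curve")
  if (anyNA(t) || is.unsorted(t, strictly = TRUE))
    return("timesH must be strictly increasing")
  if (length(object@cfuPerMl) != length(t))
    return("cfuPerMl and timesH lengths differ")
  v <- object@cfuPerMl[!is.na(object@cfuPerMl)]
  if (any(!is.finite(v)) || any(v <= 0))
    return("observed cfuPerMl values must be positive (use NA below detection)")
  TRUE
})

#' FractionTable: per-peak share of total per-cell fluorescence
#'
#' For Peaks T, C and C+: the enumeration-corrected fluorescence f (QSU per
#' 10^6 CFU), their sum \code{fTotal}, and each peak's integer percent share
#' of the total (nearest integer, ties rounded half-up).
#'
#' @slot f named numeric length 3 (names "T", "C", "C+"), QSU per 10^6 CFU.
#' @slot percent named numeric length 3, integer percent shares.
#' @slot fTotal numeric scalar, \code{sum(f)}.
#'
#' @seealso \code{\link{peakFractionTable}}
#' @exportClass FractionTable
setClass("FractionTable",
  representation(f = "numeric", percent = "numeric", fTotal = "numeric")
)

setValidity("FractionTable", function(object) {
  if (length(object@f) != 3L || is.null(names(object@f)))
    return("f must be a named length-3 vector")
  if (!identical(names(object@f), names(object@percent)))
    return("f and percent names differ")
  if (any(object@f < 0)) return("f values must be >= 0")
  if (!isTRUE(all.equal(object@fTotal, sum(object@f))))
    return("fTotal must equal sum(f)")
  if (any(object@percent != round(object@percent)))
    return("percent entries must be integers")
  TRUE
})

#' SimulationSpec: forward-model parameters for synthetic data
#'
#' Everything the synthetic generator needs: the wavelength grid,
#' fluorophore list, scatter-ridge model, absorbance model, measurement
#' noise, growth parameters, the quinine sulfate reference intensity, the
#' sampling schedule and the RNG seed.  Build with
#' \code{\link{simulationSpec}}.
#'
#' @slot excitation numeric excitation grid (nm).
#' @slot emission numeric emission grid (nm).
#' @slot fluorophores list of fluorophore specs (see
#'   \code{\link{fluorophoreSpec}}).
#' @slot scatter list: \code{amp1}, \code{amp2} (QSU-scale ridge amplitudes)
#'   and \code{sd1}, \code{sd2} (Gaussian ridge widths, nm).
#' @slot absorbance list: \code{a250} (absorbance at 250 nm), \code{slope}
#'   (exponential decay per nm), \code{perQsu} (absorbance added at a
#'   fluorophore's excitation per QSU of amplitude).
#' @slot baseline numeric flat instrument baseline (QSU-scale), present in
#'   sample and blank alike.
#' @slot noiseSd numeric additive Gaussian noise SD (QSU-scale); 0 disables.
#' @slot growth list: \code{inoculum} (CFU/ml), \code{lagH} (h),
#'   \code{maxRate} (log10 CFU per h), \code{capacity} (CFU/ml),
#'   \code{noiseSdlog} (lognormal observation noise, natural-log SD).
#' @slot qsReferenceIntensity numeric raw counts of the 1 ug/L quinine
#'   sulfate standard (raw counts per QSU).
#' @slot schedule numeric sampling times (h).
#' @slot seed integer RNG seed.
#'
#' @exportClass SimulationSpec
setClass("SimulationSpec",
  representation(
    excitation = "numeric", emission = "numeric",
    fluorophores = "list", scatter = "list", absorbance = "list",
    baseline = "numeric", noiseSd = "numeric", growth = "list",
    qsReferenceIntensity = "numeric", schedule = "numeric", seed = "integer"
  )
)

setValidity("SimulationSpec", function(object) {
  msg <- .validWavelengths(object@excitation, "excitation")
  if (!is.null(msg)) return(msg)
  msg <- .validWavelengths(object@emission, "emission")
  if (!is.null(msg)) return(msg)
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  g <- object@growth
  need <- c("inoculum", "lagH", "maxRate", "capacity", "noiseSdlog")
  if (!all(need %in% names(g)))
    return(paste("growth must contain:", paste(need, collapse = ", ")))
  if (g$capacity < g$inoculum)
    return("growth carrying capacity below inoculum")
  if (g$inoculum <= 0 || g$maxRate < 0 || g$lagH < 0 || g$noiseSdlog < 0)
    return("invalid growth parameters")
  if (object@qsReferenceIntensity <= 0)
    return("qsReferenceIntensity must be > 0")
  if (anyNA(object@schedule) || is.unsorted(object@schedule, strictly = TRUE))
    return("schedule must be strictly increasing")
  for (fl in object@fluorophores) {
    if (fl$sigmaEx <= 0 || fl$sigmaEm <= 0)
      return("fluorophore widths must be > 0")
    if (any(fl$amplitude < 0))
      return("fluorophore amplitudes must be >= 0")
  }
  TRUE
})
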