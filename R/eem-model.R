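#' @include AllGenerics.R
NULL

#' Construct an excitation-emission matrix
#'
#' @param intensity numeric matrix, emission rows by excitation columns.
#' @param excitation numeric excitation wavelengths (nm), strictly
#'   increasing; length must match \code{ncol(intensity)}.
#' @param emission numeric emission wavelengths (nm), strictly increasing;
#'   length must match \code{nrow(intensity)}.
#' @param unit \code{"raw"} (default) or \code{"QSU"}.
#' @param mask optional logical matrix of masked cells; defaults to
#'   all-\code{FALSE}.
#' @param meta optional list of labels (sample id, time, condition).
#'
#' @return An \code{\linkS4class{EEMatrix}}.
#' @examples
#' e <- EEMatrix(matrix(1, 3, 2), excitation = c(300, 310),
#'               emission = c(350, 360, 370))
#' dim(intensity(e))
#' @export
EEMatrix <- function(intensity, excitation, emission, unit = "raw",
                     mask = NULL, meta = list()) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  dimnames(intensity) <- NULL
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(intensity), ncol(intensity))
  } else {
    mask <- as.matrix(mask)
    storage.mode(mask) <- "logical"
    dimnames(mask) <- NULL
  }
  new("EEMatrix", excitation = as.numeric(excitation),
      emission = as.numeric(emission), intensity = intensity,
      unit = unit, mask = mask, meta = meta)
}

#' @describeIn EEMatrix excitation axis (nm)
#' @param x an \code{EEMatrix}
#' @export
setMethod("excitation", "EEMatrix", function(x) x@excitation)

#' @describeIn EEMatrix emission axis (nm)
#' @export
setMethod("emission", "EEMatrix", function(x) x@emission)

#' @describeIn EEMatrix intensity matrix (emission x excitation)
#' @export
setMethod("intensity", "EEMatrix", function(x) x@intensity)

#' @describeIn EEMatrix unit tag, "raw" or "QSU"
#' @export
setMethod("eemUnit", "EEMatrix", function(x) x@unit)

#' @describeIn EEMatrix logical mask matrix (TRUE = masked)
#' @export
setMethod("eemMask", "EEMatrix", function(x) x@mask)

#' @describeIn EEMatrix metadata list
#' @export
setMethod("eemMeta", "EEMatrix", function(x) x@meta)

setMethod("dim", "EEMatrix", function(x) dim(x@intensity))

setMethod("show", "EEMatrix", function(object) {
  cat(sprintf("EEMatrix: %d emission x %d excitation [%s]\n",
              length(object@emission), length(object@excitation),
              object@unit))
  cat(sprintf("  excitation: %.2f-%.2f nm, emission: %.2f-%.2f nm\n",
              min(object@excitation), max(object@excitation),
              min(object@emission), max(object@emission)))
  nm <- sum(object@mask)
  cat(sprintf("  masked cells: %d (%.1f%%)\n", nm,
              100 * nm / length(object@mask)))
  if (length(object@meta)) {
    lab <- object@meta[setdiff(names(object@meta), "processing_log")]
    if (length(lab))
      cat("  meta:", paste(names(lab), vapply(lab, function(v)
        paste(format(v), collapse = ","), ""), sep = "=", collapse = " "),
        "\n")
  }
  invisible(NULL)
})

.replaceIntensity <- function(eem, intensity = eem@intensity,
                              mask = eem@mask, unit = eem@unit,
                              excitation = eem@excitation,
                              emission = eem@emission, meta = eem@meta) {
  new("EEMatrix", excitation = excitation, emission = emission,
      intensity = intensity, unit = unit, mask = mask, meta = meta)
}

.logStage <- function(meta, msg) {
  meta$processing_log <- c(meta$processing_log, msg)
  meta
}

#' Index of the grid point nearest a target wavelength
#'
#' Resolves nominal peak coordinates (e.g. emission 340 nm) onto an
#' instrument grid (e.g. 247.88 nm + k * 1.16 nm).  Ties between two
#' equidistant grid points break toward the lower wavelength.
#'
#' @param axis numeric, strictly increasing wavelengths (nm).
#' @param target numeric scalar, wavelength sought (nm).
#' @param tolerance maximum acceptable distance (nm); defaults to one grid
#'   spacing of \code{axis} (its median step).
#'
#' @return Integer index into \code{axis}.
#' @examples
#' nearestIndex(seq(200, 600), 275)
#' @export
nearestIndex <- function(axis, target, tolerance = NULL) {
  stopifnot(length(target) == 1L, is.finite(target))
  if (is.null(tolerance))
    tolerance <- if (length(axis) > 1L) stats::median(diff(axis)) else Inf
  if (tolerance <= 0) stop("tolerance must be > 0")
  d <- abs(axis - target)
  i <- which.min(d)  # first minimum = lower wavelength on ties
  if (d[i] > tolerance + 1e-12)
    stop(sprintf(
      "no wavelength within %.4g nm of %.4g nm on axis [%.4g, %.4g]",
      tolerance, target, min(axis), max(axis)))
  i
}

#' Crop an EEM to excitation and emission windows
#'
#' Keeps exactly the grid points lying inside the closed intervals.  The
#' standard analysis window is excitation 240-490 nm, emission 250-500 nm,
#' which discards the instrument-noise-dominated deep-UV region.
#'
#' @param eem an \code{\linkS4class{EEMatrix}}.
#' @param exRange numeric length-2 closed excitation interval (nm).
#' @param emRange numeric length-2 closed emission interval (nm).
#'
#' @return The cropped \code{EEMatrix}; metadata preserved.
#' @export
cropEEM <- function(eem, exRange = c(240, 490), emRange = c(250, 500)) {
  stopifnot(is(eem, "EEMatrix"), length(exRange) == 2L, length(emRange) == 2L)
  exRange <- sort(exRange); emRange <- sort(emRange)
  keepEx <- which(eem@excitation >= exRange[1] & eem@excitation <= exRange[2])
  keepEm <- which(eem@emission >= emRange[1] & eem@emission <= emRange[2])
  if (!length(keepEx) || !length(keepEm))
    stop(sprintf(
      "crop range (ex [%g, %g], em [%g, %g]) leaves no grid points",
      exRange[1], exRange[2], emRange[1], emRange[2]))
  meta <- .logStage(eem@meta, sprintf("crop ex [%g,%g] em [%g,%g]",
                                      exRange[1], exRange[2],
                                      emRange[1], emRange[2]))
  .replaceIntensity(eem,
    intensity = eem@intensity[keepEm, keepEx, drop = FALSE],
    mask = eem@mask[keepEm, keepEx, drop = FALSE],
    excitation = eem@excitation[keepEx],
    emission = eem@emission[keepEm],
    meta = meta)
}

#' Construct an absorbance spectrum
#'
#' Negative absorbance readings (instrument baseline noise) are clipped to
#' zero with a warning.
#'
#' @param wavelength numeric, strictly increasing wavelengths (nm).
#' @param absorbance numeric absorbance values (1 cm reference path).
#' @return An \code{\linkS4class{AbsorbanceSpectrum}}.
#' @export
AbsorbanceSpectrum <- function(wavelength, absorbance) {
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (any(absorbance < 0, na.rm = TRUE)) {
    warning(sprintf("clipped %d negative absorbance value(s) to 0",
                    sum(absorbance < 0, na.rm = TRUE)))
    absorbance <- pmax(absorbance, 0)
  }
  new("AbsorbanceSpectrum", wavelength = wavelength, absorbance = absorbance)
}

#' @describeIn AbsorbanceSpectrum absorbance at arbitrary wavelengths by
#'   linear interpolation; errors outside the covered range.
#' @param x an \code{AbsorbanceSpectrum}
#' @param wavelength numeric wavelengths (nm) at which to evaluate
#' @export
setMethod("absorbanceAt", "AbsorbanceSpectrum", function(x, wavelength) {
  rng <- range(x@wavelength)
  bad <- wavelength < rng[1] - 1e-9 | wavelength > rng[2] + 1e-9
  if (any(bad))
    stop(sprintf(
      "wavelength %.4g nm outside absorbance coverage [%.4g, %.4g]",
      wavelength[which(bad)[1]], rng[1], rng[2]))
  if (length(x@wavelength) == 1L)
    return(rep(x@absorbance, length(wavelength)))
  stats::approx(x@wavelength, x@absorbance, xout = wavelength,
                rule = 1)$y
})

setMethod("show", "AbsorbanceSpectrum", function(object) {
  cat(sprintf("AbsorbanceSpectrum: %d points, %.2f-%.2f nm, A in [%.4g, %.4g]\n",
              length(object@wavelength), min(object@wavelength),
              max(object@wavelength), min(object@absorbance),
              max(object@absorbance)))
  invisible(NULL)
})
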