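#' @include eem-model.R
NULL

#' Quinine sulfate reference
#'
#' The raw-count intensity of a 1 ug/L quinine sulfate standard at
#' excitation 347.5 nm / emission 450 nm.  \code{qsReference} wraps a known
#' scalar; \code{qsReferenceFromEEM} reads the value off a measured
#' standard EEM at the grid point nearest (347.5, 450) nm.
#'
#' @param intensityRaw positive raw-count intensity of the standard.
#' @return A \code{\linkS4class{QsReference}}.
#' @export
qsReference <- function(intensityRaw) {
  new("QsReference", intensityRaw = as.numeric(intensityRaw),
      source = "scalar")
}

#' @rdname qsReference
#' @param eem a raw-unit \code{\linkS4class{EEMatrix}} of the quinine
#'   sulfate standard.
#' @param exNm,emNm standard coordinates (defaults 347.5 and 450 nm).
#' @export
qsReferenceFromEEM <- function(eem, exNm = 347.5, emNm = 450) {
  stopifnot(is(eem, "EEMatrix"))
  if (eem@unit != "raw")
    stop("quinine sulfate reference must come from a raw-unit EEM")
  i <- nearestIndex(eem@emission, emNm)
  j <- nearestIndex(eem@excitation, exNm)
  if (eem@mask[i, j])
    stop("reference grid cell nearest (347.5, 450) nm is masked")
  new("QsReference", intensityRaw = eem@intensity[i, j],
      source = "derived-from-EEM")
}

setMethod("show", "QsReference", function(object) {
  cat(sprintf("QsReference: %.6g raw counts per QSU (%s)\n",
              object@intensityRaw, object@source))
  invisible(NULL)
})

.checkAxesMatch <- function(a, b, what = "blank") {
  if (length(a@excitation) != length(b@excitation) ||
      length(a@emission) != length(b@emission) ||
      max(abs(a@excitation - b@excitation)) > 1e-6 ||
      max(abs(a@emission - b@emission)) > 1e-6)
    stop(sprintf("sample and %s EEMs are on different wavelength grids", what))
}

#' Subtract a blank EEM
#'
#' Element-wise sample minus blank on identical grids.  The result's mask is
#' the union of both masks.  Negative differences are retained (clipping
#' would bias near-zero signals); if any fall below -5 percent of the grid
#' maximum a note is added to the metadata.
#'
#' @param sample,blank \code{\linkS4class{EEMatrix}} objects with identical
#'   axes and unit tags.
#' @return The blank-subtracted \code{EEMatrix}.
#' @export
subtractBlank <- function(sample, blank) {
  stopifnot(is(sample, "EEMatrix"), is(blank, "EEMatrix"))
  .checkAxesMatch(sample, blank)
  if (sample@unit != blank@unit)
    stop("sample and blank units differ")
  out <- sample@intensity - blank@intensity
  mask <- sample@mask | blank@mask
  meta <- .logStage(sample@meta, "blank subtraction")
  gmax <- max(abs(out[!mask]), 0)
  neg <- out[!mask]
  if (gmax > 0 && any(neg < -0.05 * gmax))
    meta$warnings <- c(meta$warnings, sprintf(
      "%d cell(s) below -5%% of grid maximum after blank subtraction",
      sum(neg < -0.05 * gmax)))
  out[mask] <- 0
  .replaceIntensity(sample, intensity = out, mask = mask, meta = meta)
}

#' Inner-filter-effect correction
#'
#' Multiplies each cell by \code{10^(L * (A(ex) + A(em)) / 2)} — the
#' absorbance (ABA) method — undoing primary (excitation) and secondary
#' (emission) inner-filter attenuation for a cuvette of pathlength \code{L}
#' cm.  Absorbance is interpolated linearly from \code{absSpec}, which must
#' cover every grid wavelength.
#'
#' @param eem an \code{\linkS4class{EEMatrix}}.
#' @param absSpec an \code{\linkS4class{AbsorbanceSpectrum}}.
#' @param pathlengthCm cuvette pathlength in cm (default 1, a 10 mm cell).
#' @return The corrected \code{EEMatrix}.
#' @export
correctIFE <- function(eem, absSpec, pathlengthCm = 1) {
  stopifnot(is(eem, "EEMatrix"), is(absSpec, "AbsorbanceSpectrum"),
            pathlengthCm > 0)
  aEx <- absorbanceAt(absSpec, eem@excitation)
  aEm <- absorbanceAt(absSpec, eem@emission)
  factor <- 10^(pathlengthCm * outer(aEm, aEx, "+") / 2)
  meta <- .logStage(eem@meta,
                    sprintf("inner-filter correction (ABA, %g cm path)",
                            pathlengthCm))
  .replaceIntensity(eem, intensity = eem@intensity * factor, meta = meta)
}

#' Mask Rayleigh scatter ridges
#'
#' Adds to the mask every cell within \code{hw1} nm of the first-order
#' ridge (emission = excitation) or within \code{hw2} nm of the
#' second-order ridge (emission = 2 x excitation).  Intensities elsewhere
#' are untouched.
#'
#' @param eem an \code{\linkS4class{EEMatrix}}.
#' @param hw1,hw2 half-widths (nm) of the first- and second-order bands
#'   (defaults 10 nm each).
#' @return The \code{EEMatrix} with an augmented mask.
#' @export
maskRayleigh <- function(eem, hw1 = 10, hw2 = 10) {
  stopifnot(is(eem, "EEMatrix"), hw1 >= 0, hw2 >= 0)
  d1 <- abs(outer(eem@emission, eem@excitation, "-"))
  d2 <- abs(outer(eem@emission, 2 * eem@excitation, "-"))
  add <- d1 <= hw1 | d2 <= hw2
  meta <- .logStage(eem@meta, sprintf(
    "Rayleigh masking (1st order +/-%g nm, 2nd order +/-%g nm): %d cell(s)",
    hw1, hw2, sum(add & !eem@mask)))
  mask <- eem@mask | add
  intensity <- eem@intensity
  intensity[mask] <- 0
  .replaceIntensity(eem, intensity = intensity, mask = mask, meta = meta)
}

#' Normalize an EEM to quinine sulfate units
#'
#' Divides every intensity by the reference raw intensity of the 1 ug/L
#' quinine sulfate standard, so a cell equal to the standard's reading
#' becomes exactly 1 QSU.  Refuses already-normalized input.
#'
#' @param eem a raw-unit \code{\linkS4class{EEMatrix}}.
#' @param ref a \code{\linkS4class{QsReference}}.
#' @return The \code{EEMatrix} in QSU.
#' @export
normalizeQSU <- function(eem, ref) {
  stopifnot(is(eem, "EEMatrix"), is(ref, "QsReference"))
  if (eem@unit == "QSU")
    stop("EEM is already in QSU; refusing to normalize twice")
  meta <- .logStage(eem@meta, sprintf(
    "QSU normalization (reference %.6g raw counts)", ref@intensityRaw))
  .replaceIntensity(eem, intensity = eem@intensity / ref@intensityRaw,
                    unit = "QSU", meta = meta)
}

#' Default preprocessing configuration
#'
#' @return A nested list with the documented defaults: 1 cm pathlength,
#'   10 nm scatter half-widths, crop window excitation 240-490 nm /
#'   emission 250-500 nm.
#' @export
preprocessConfig <- function() {
  list(
    ife = list(pathlength_cm = 1),
    scatter = list(hw1_nm = 10, hw2_nm = 10),
    crop = list(ex = c(240, 490), em = c(250, 500))
  )
}

.mergeConfig <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- .mergeConfig(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Full EEM preprocessing pipeline
#'
#' Applies, in order: inner-filter correction of sample and blank, blank
#' subtraction, Rayleigh scatter masking, cropping to the analysis window,
#' and quinine sulfate normalization.  Inner-filter correction precedes
#' subtraction because attenuation acts on each measured field
#' multiplicatively; masking precedes cropping so the scatter geometry is
#' intact when the bands are located.  The stages applied are recorded in
#' the result's \code{processing_log} metadata.
#'
#' @param sample,blank raw-unit \code{\linkS4class{EEMatrix}} objects on the
#'   same grid.
#' @param absSpec an \code{\linkS4class{AbsorbanceSpectrum}} covering the
#'   grid.
#' @param ref a \code{\linkS4class{QsReference}}.
#' @param config optional overrides of \code{\link{preprocessConfig}}.
#' @return The corrected \code{EEMatrix} in QSU.
#' @examples
#' sim <- simulationSpec(seed = 1)
#' obs <- simulateEEM(sim, t = 12)
#' qsu <- preprocessPipeline(obs$sample, obs$blank, obs$absorbance, obs$ref)
#' eemUnit(qsu)
#' @export
preprocessPipeline <- function(sample, blank, absSpec, ref,
                               config = list()) {
  cfg <- .mergeConfig(preprocessConfig(), config)
  s <- correctIFE(sample, absSpec, cfg$ife$pathlength_cm)
  b <- correctIFE(blank, absSpec, cfg$ife$pathlength_cm)
  s <- subtractBlank(s, b)
  s <- maskRayleigh(s, cfg$scatter$hw1_nm, cfg$scatter$hw2_nm)
  s <- cropEEM(s, cfg$crop$ex, cfg$crop$em)
  normalizeQSU(s, ref)
}
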