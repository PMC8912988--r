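#' @include preprocess.R peaks.R growth.R summary.R
NULL

# run expr under a fixed seed without disturbing the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' The paper-style sampling schedule
#'
#' Hourly sampling for the first 8 h, then 12, 16, 20, 24, 36 and 48 h —
#' 15 time points resolving lag, exponential and stationary growth.
#'
#' @return Numeric vector of times (h).
#' @export
samplingSchedule <- function() c(0:8, 12, 16, 20, 24, 36, 48)

#' Wavelength grids for simulation
#'
#' \code{instrumentGrid} is the full spectrometer grid: excitation 200-600
#' nm in 1 nm steps, emission 247.88-829.85 nm in 1.16 nm steps.
#' \code{coarseGrid} is a reduced grid (excitation 240-500 nm in 5 nm
#' steps, emission in 4.64 nm steps, i.e. every 4th instrument pixel) that
#' keeps the standard peak excitations (275, 340, 400 nm) on-grid while
#' making multi-condition simulations fast; it is the default for
#' \code{\link{simulateConditionSet}}.
#'
#' @return A list with numeric elements \code{excitation} and
#'   \code{emission} (nm).
#' @export
instrumentGrid <- function() {
  list(excitation = seq(200, 600, by = 1),
       emission = seq(247.88, 829.85, by = 1.16))
}

#' @rdname instrumentGrid
#' @export
coarseGrid <- function() {
  list(excitation = seq(240, 500, by = 5),
       emission = seq(247.88, 598, by = 4.64))
}

#' Amplitude kinetics for a simulated fluorophore
#'
#' A phenomenological time course in QSU: a small initial baseline
#' \code{a0}, a logistic rise to \code{aMax} centred at \code{midH} (the
#' fluorescence surge accompanying exponential growth, plateauing after
#' ~16 h), plus an optional early rise \code{earlyAmp} centred at
#' \code{earlyMidH} emulating the pre-exponential metabolic signal seen for
#' the tryptophan-like peak.
#'
#' @param aMax plateau amplitude (QSU).
#' @param a0 baseline amplitude at inoculation (QSU).
#' @param midH,scaleH logistic midpoint and scale (h).
#' @param earlyAmp,earlyMidH,earlyScaleH early-rise component (QSU, h, h).
#' @param times evaluation times (h).
#' @return A data.frame with columns \code{time_h}, \code{amplitude}.
#' @export
amplitudeKinetics <- function(aMax, a0 = 0, midH = 11, scaleH = 1.8,
                              earlyAmp = 0, earlyMidH = 4, earlyScaleH = 0.8,
                              times = samplingSchedule()) {
  amp <- a0 + earlyAmp * stats::plogis((times - earlyMidH) / earlyScaleH) +
    (aMax - a0) * stats::plogis((times - midH) / scaleH)
  data.frame(time_h = times, amplitude = pmax(amp, 0))
}

#' Define a simulated fluorophore
#'
#' A separable 2-D Gaussian emitter: intensity
#' \code{a(t) * exp(-((ex - cEx) / sEx)^2 / 2) * exp(-((em - cEm) / sEm)^2
#' / 2)} in QSU.  Amplitudes between the supplied kinetic time points are
#' linearly interpolated (held constant beyond the range).
#'
#' @param name label, conventionally the peak it underlies.
#' @param centerExNm,centerEmNm peak coordinates (nm).
#' @param sigmaExNm,sigmaEmNm Gaussian widths (nm; defaults 15 and 20).
#' @param kinetics a data.frame with columns \code{time_h},
#'   \code{amplitude} (see \code{\link{amplitudeKinetics}}), or a single
#'   constant amplitude.
#' @return A fluorophore spec (list) for \code{\link{simulationSpec}}.
#' @export
fluorophoreSpec <- function(name, centerExNm, centerEmNm, sigmaExNm = 15,
                            sigmaEmNm = 20, kinetics = 1) {
  if (is.numeric(kinetics) && length(kinetics) == 1L)
    kinetics <- data.frame(time_h = c(0, 48), amplitude = rep(kinetics, 2))
  stopifnot(all(c("time_h", "amplitude") %in% names(kinetics)))
  list(name = name, centerEx = as.numeric(centerExNm),
       centerEm = as.numeric(centerEmNm), sigmaEx = sigmaExNm,
       sigmaEm = sigmaEmNm, times = kinetics$time_h,
       amplitude = kinetics$amplitude)
}

.amplitudeAt <- function(fl, t) {
  if (length(fl$times) == 1L) return(fl$amplitude)
  stats::approx(fl$times, fl$amplitude, xout = t, rule = 2)$y
}

#' Default fluorophore set
#'
#' Three Gaussian emitters centred on the standard peak coordinates
#' (T at 275/340, C at 340/445, C+ at 400/487.5 nm — band peaks centred in
#' their emission bands) with logistic kinetics rising from the observed
#' inoculation baselines (2.2, 0.9, 0.6 QSU) to plateau amplitudes
#' \code{aMax}; the T emitter carries the early pre-exponential rise.
#'
#' @param aMax named plateau amplitudes (QSU) for "T", "C", "C+".
#' @param earlyAmpT early-rise amplitude of the T emitter (QSU).
#' @param times kinetic time points (h).
#' @return List of fluorophore specs.
#' @export
defaultFluorophores <- function(aMax = c("T" = 51.8, "C" = 162.7,
                                         "C+" = 1215.8),
                                earlyAmpT = 1.5,
                                times = samplingSchedule()) {
  a0 <- c("T" = 2.2, "C" = 0.9, "C+" = 0.6)
  list(
    fluorophoreSpec("T", 275, 340, kinetics = amplitudeKinetics(
      aMax[["T"]], a0[["T"]], earlyAmp = earlyAmpT, times = times)),
    fluorophoreSpec("C", 340, 445, sigmaEmNm = 25,
      kinetics = amplitudeKinetics(aMax[["C"]], a0[["C"]], times = times)),
    fluorophoreSpec("C+", 400, 487.5, sigmaEmNm = 25,
      kinetics = amplitudeKinetics(aMax[["C+"]], a0[["C+"]], times = times))
  )
}

#' Build a simulation specification
#'
#' Collects grid, fluorophores, scatter, absorbance, noise and growth
#' parameters into a validated \code{\linkS4class{SimulationSpec}}.  The
#' defaults describe a high-nutrient, limited-DOC culture: inoculum 1e5
#' CFU/ml, 6 h lag, 1/3 log10/h exponential growth to 1e7 CFU/ml, and
#' fluorescence plateaus at the 48 h intensities of that condition.
#'
#' @param grid list with \code{excitation} and \code{emission} axes
#'   (default \code{\link{instrumentGrid}}).
#' @param fluorophores list of \code{\link{fluorophoreSpec}} entries.
#' @param scatter list: ridge amplitudes \code{amp1}, \code{amp2}
#'   (QSU-scale) and Gaussian widths \code{sd1}, \code{sd2} (nm).
#' @param absorbance list: \code{a250} (absorbance at 250 nm),
#'   \code{slope} (exponential decay per nm), \code{perQsu} (absorbance
#'   added at each fluorophore's excitation per QSU of amplitude).
#' @param baseline flat instrument offset (QSU-scale), in sample and blank.
#' @param noiseSd additive Gaussian noise SD in QSU-equivalents (0 = off).
#' @param growth list: \code{inoculum}, \code{lagH}, \code{maxRate},
#'   \code{capacity}, \code{noiseSdlog}.
#' @param qsReferenceIntensity raw counts per QSU (the quinine sulfate
#'   standard's raw reading).
#' @param schedule sampling times (h).
#' @param seed integer RNG seed.
#' @return A \code{\linkS4class{SimulationSpec}}.
#' @export
simulationSpec <- function(grid = instrumentGrid(),
                           fluorophores = defaultFluorophores(),
                           scatter = list(amp1 = 50, amp2 = 10,
                                          sd1 = 5, sd2 = 5),
                           absorbance = list(a250 = 0.01, slope = 0.005,
                                             perQsu = 1e-5),
                           baseline = 1,
                           noiseSd = 0.1,
                           growth = list(inoculum = 1e5, lagH = 6,
                                         maxRate = 1 / 3, capacity = 1e7,
                                         noiseSdlog = 0),
                           qsReferenceIntensity = 1e4,
                           schedule = samplingSchedule(),
                           seed = 1L) {
  g <- list(inoculum = 1e5, lagH = 6, maxRate = 1 / 3, capacity = 1e7,
            noiseSdlog = 0)
  g[names(growth)] <- growth
  s <- list(amp1 = 50, amp2 = 10, sd1 = 5, sd2 = 5)
  s[names(scatter)] <- scatter
  a <- list(a250 = 0.01, slope = 0.005, perQsu = 1e-5)
  a[names(absorbance)] <- absorbance
  new("SimulationSpec", excitation = grid$excitation,
      emission = grid$emission, fluorophores = fluorophores,
      scatter = s, absorbance = a, baseline = baseline, noiseSd = noiseSd,
      growth = g, qsReferenceIntensity = qsReferenceIntensity,
      schedule = schedule, seed = as.integer(seed))
}

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(
    "SimulationSpec: %d x %d grid, %d fluorophore(s), noiseSd %g QSU, seed %d\n",
    length(object@emission), length(object@excitation),
    length(object@fluorophores), object@noiseSd, object@seed))
  g <- object@growth
  cat(sprintf(
    "  growth: inoculum %.3g CFU/ml, lag %g h, rate %.3g log10/h, capacity %.3g\n",
    g$inoculum, g$lagH, g$maxRate, g$capacity))
  invisible(NULL)
})

.growthLog10 <- function(g, t) {
  log10(g$inoculum) +
    pmin(pmax(t - g$lagH, 0) * g$maxRate, log10(g$capacity / g$inoculum))
}

#' Simulate a three-phase growth curve
#'
#' Deterministic lag / exponential / stationary dynamics: flat at the
#' inoculum until \code{lagH}, then log-linear growth at \code{maxRate}
#' (log10 CFU per h) until the carrying capacity, flat thereafter; sampled
#' at the spec's schedule.  If \code{growth$noiseSdlog > 0}, multiplicative
#' lognormal observation noise is applied under the spec's seed.
#'
#' @param spec a \code{\linkS4class{SimulationSpec}}.
#' @param replicate,condition labels for the returned curve.
#' @return A \code{\linkS4class{GrowthCurve}} whose \code{meta$truth}
#'   records the generating change-points (\code{lag_end_h},
#'   \code{stationary_start_h}) and parameters.
#' @examples
#' g <- simulateGrowth(simulationSpec(seed = 7))
#' classifyPhases(g)
#' @export
simulateGrowth <- function(spec, replicate = "rep1", condition = "unknown") {
  stopifnot(is(spec, "SimulationSpec"))
  g <- spec@growth
  t <- spec@schedule
  cfu <- 10^.growthLog10(g, t)
  if (g$noiseSdlog > 0)
    cfu <- .withSeed((as.numeric(spec@seed) + 104729) %% 2^31,
                     cfu * exp(stats::rnorm(length(cfu), 0, g$noiseSdlog)))
  truth <- list(
    lag_end_h = g$lagH,
    stationary_start_h =
      if (g$maxRate > 0) g$lagH + log10(g$capacity / g$inoculum) / g$maxRate
      else Inf,
    inoculum = g$inoculum, max_rate = g$maxRate, capacity = g$capacity)
  GrowthCurve(t, cfu, replicate = replicate, condition = condition,
              meta = list(truth = truth))
}

.gaussianField <- function(spec, t) {
  sig <- matrix(0, length(spec@emission), length(spec@excitation))
  for (fl in spec@fluorophores) {
    a <- .amplitudeAt(fl, t)
    if (a <= 0) next
    gx <- exp(-0.5 * ((spec@excitation - fl$centerEx) / fl$sigmaEx)^2)
    gm <- exp(-0.5 * ((spec@emission - fl$centerEm) / fl$sigmaEm)^2)
    sig <- sig + a * outer(gm, gx)
  }
  sig
}

.scatterField <- function(spec) {
  s <- spec@scatter
  d1 <- outer(spec@emission, spec@excitation, "-")
  d2 <- outer(spec@emission, 2 * spec@excitation, "-")
  s$amp1 * exp(-0.5 * (d1 / s$sd1)^2) + s$amp2 * exp(-0.5 * (d2 / s$sd2)^2)
}

.absorbanceSpectrumAt <- function(spec, t,
                                  wavelengths = seq(190, 840, by = 2)) {
  a <- spec@absorbance
  A <- a$a250 * exp(-a$slope * (wavelengths - 250))
  if (a$perQsu > 0)
    for (fl in spec@fluorophores) {
      amp <- .amplitudeAt(fl, t)
      if (amp > 0)
        A <- A + a$perQsu * amp *
          exp(-0.5 * ((wavelengths - fl$centerEx) / fl$sigmaEx)^2)
    }
  AbsorbanceSpectrum(wavelengths, A)
}

#' Simulate one EEM observation
#'
#' Forward model at time \code{t}: the ideal fluorophore field (QSU) plus
#' Rayleigh scatter ridges and a flat baseline, converted to raw counts by
#' the quinine sulfate reference intensity, attenuated by
#' \code{10^-((A(ex) + A(em)) / 2)} (the inner-filter effect of the
#' sample's own absorbance), with additive Gaussian noise under the seed.
#' The blank carries scatter, baseline, attenuation and noise but no
#' fluorophores — so the preprocessing pipeline is the model's exact
#' inverse when noise is off.
#'
#' @param spec a \code{\linkS4class{SimulationSpec}}.
#' @param t observation time (h) within the schedule span.
#' @param streamOffset integer added to the seed for independent replicate
#'   noise streams.
#' @param nScans technical scans averaged into the stored EEM (default 1;
#'   triplicate scanning at every time point divides the effective noise SD
#'   by sqrt(3)).
#' @return A list: \code{sample} and \code{blank} (raw
#'   \code{\linkS4class{EEMatrix}}), \code{absorbance}
#'   (\code{\linkS4class{AbsorbanceSpectrum}}), \code{ref}
#'   (\code{\linkS4class{QsReference}}) and \code{ideal} (the noise-free
#'   fluorophore-only field in QSU).
#' @export
simulateEEM <- function(spec, t, streamOffset = 0L, nScans = 1L) {
  stopifnot(is(spec, "SimulationSpec"))
  if (t < min(spec@schedule) || t > max(spec@schedule))
    stop(sprintf("t = %g h outside the schedule span [%g, %g]", t,
                 min(spec@schedule), max(spec@schedule)))
  ref <- spec@qsReferenceIntensity
  signal <- .gaussianField(spec, t)
  scatter <- .scatterField(spec) + spec@baseline
  absSpec <- .absorbanceSpectrumAt(spec, t)
  aEx <- absorbanceAt(absSpec, spec@excitation)
  aEm <- absorbanceAt(absSpec, spec@emission)
  atten <- 10^(-outer(aEm, aEx, "+") / 2)
  sampleRaw <- (signal + scatter) * ref * atten
  blankRaw <- scatter * ref * atten
  if (spec@noiseSd > 0) {
    n <- length(sampleRaw)
    # mean of nScans iid scans = one draw at sd / sqrt(nScans)
    sdEff <- spec@noiseSd * ref / sqrt(nScans)
    noise <- .withSeed(
      (spec@seed + 131071 * (streamOffset + 1) + round(100 * t)) %% 2^31,
      matrix(stats::rnorm(2L * n, 0, sdEff), ncol = 2L))
    sampleRaw <- sampleRaw + matrix(noise[, 1], nrow(sampleRaw))
    blankRaw <- blankRaw + matrix(noise[, 2], nrow(blankRaw))
  }
  meta <- list(time_h = t)
  list(
    sample = EEMatrix(sampleRaw, spec@excitation, spec@emission,
                      unit = "raw", meta = meta),
    blank = EEMatrix(blankRaw, spec@excitation, spec@emission,
                     unit = "raw", meta = c(meta, list(role = "blank"))),
    absorbance = absSpec,
    ref = qsReference(ref),
    ideal = EEMatrix(signal, spec@excitation, spec@emission,
                     unit = "QSU", meta = c(meta, list(role = "ideal")))
  )
}

#' Ideal peak readings of a simulation
#'
#' What a perfect instrument and pipeline would report: the noise-free
#' fluorophore-only field at time \code{t}, Rayleigh-masked and cropped as
#' in preprocessing, read through \code{\link{pickPeak}}.  This is the
#' ground truth the end-to-end tests compare recovered intensities against.
#'
#' @param spec a \code{\linkS4class{SimulationSpec}}.
#' @param t time (h).
#' @param peaks list of \code{\linkS4class{PeakDefinition}}s.
#' @param config preprocessing overrides (crop window, scatter widths).
#' @return Named numeric vector of QSU intensities.
#' @export
truePeakReadings <- function(spec, t,
                             peaks = standardPeaks(c("T", "C", "C+")),
                             config = list()) {
  cfg <- .mergeConfig(preprocessConfig(), config)
  ideal <- EEMatrix(.gaussianField(spec, t), spec@excitation, spec@emission,
                    unit = "QSU")
  ideal <- maskRayleigh(ideal, cfg$scatter$hw1_nm, cfg$scatter$hw2_nm)
  ideal <- cropEEM(ideal, cfg$crop$ex, cfg$crop$em)
  vapply(peaks, function(p) pickPeak(ideal, p), 0)
}

#' Condition presets for the six-condition synthetic dataset
#'
#' Plateau amplitudes follow the observed 48 h intensities per condition;
#' carrying capacities grow with DOC (5e6 without DOC, 2e7 with limited,
#' 5e7 with excess DOC) with rates reaching capacity by ~12 h from a 6 h
#' lag; amplitude ordering across conditions thus tracks DOC availability.
#'
#' @return Named list (SFW0-SFW5) of per-condition overrides: \code{aMax}
#'   and \code{growth}.
#' @export
sfwPresets <- function() {
  aMax <- list(
    SFW0 = c("T" = 6.5,  "C" = 14.8,  "C+" = 6.2),
    SFW1 = c("T" = 11.3, "C" = 21.5,  "C+" = 28.6),
    SFW2 = c("T" = 56,   "C" = 81.5,  "C+" = 599.7),
    SFW3 = c("T" = 51.8, "C" = 162.7, "C+" = 1215.8),
    SFW4 = c("T" = 45.5, "C" = 449,   "C+" = 592),
    SFW5 = c("T" = 58,   "C" = 332.6, "C+" = 612.7))
  capacity <- c(SFW0 = 5e6, SFW1 = 5e6, SFW2 = 2e7, SFW3 = 2e7,
                SFW4 = 5e7, SFW5 = 5e7)
  out <- lapply(names(aMax), function(lab) {
    K <- capacity[[lab]]
    list(aMax = aMax[[lab]],
         growth = list(inoculum = 1e5, lagH = 6,
                       maxRate = (log10(K) - 5) / 6, capacity = K,
                       noiseSdlog = 0.02))
  })
  names(out) <- names(aMax)
  out
}

.repSpec <- function(preset, grid, seed, noiseSd, ampScale = c("T" = 1,
                     "C" = 1, "C+" = 1)) {
  aMax <- preset$aMax * ampScale[names(preset$aMax)]
  simulationSpec(grid = grid,
                 fluorophores = defaultFluorophores(aMax = aMax),
                 noiseSd = noiseSd, growth = preset$growth, seed = seed)
}

#' Generate the full six-condition synthetic dataset on disk
#'
#' Writes, for every condition (SFW0-SFW5) and replicate: one sample EEM,
#' one blank EEM and one absorbance file per scheduled time point, plus a
#' growth-curve file — in the package's delimited-text dialects — and a
#' JSON ground-truth manifest (\code{manifest.json}) recording the
#' jittered true amplitudes, ideal peak readings, true viable counts,
#' growth change-points, and the per-peak true per-cell fluorescence
#' (per replicate, and at condition level as the maximum of the
#' replicate-mean f curve) with its fraction shares.  Replicate
#' variability is biological: per-replicate, per-peak lognormal amplitude
#' jitter under seeds derived from the master seed, so any file is
#' independently reproducible.
#'
#' @param outDir output directory (layout
#'   \code{<condition>/<replicate>/eem_t*.csv} etc.).
#' @param seed master integer seed.
#' @param replicates biological replicates per condition (default 3).
#' @param presets per-condition overrides (default \code{\link{sfwPresets}}).
#' @param grid wavelength grid (default \code{\link{coarseGrid}} for speed).
#' @param noiseSd per-scan instrument noise SD in QSU (default 0.1; 0
#'   disables).
#' @param nScans technical scans averaged per stored EEM (default 3,
#'   triplicate measurement at every time point).
#' @param ampJitterSdlog lognormal SD of the per-replicate amplitude
#'   jitter (default 0.1).
#' @return Invisibly, the manifest list.
#' @export
simulateConditionSet <- function(outDir, seed = 1L, replicates = 3L,
                                 presets = sfwPresets(),
                                 grid = coarseGrid(), noiseSd = 0.1,
                                 nScans = 3L, ampJitterSdlog = 0.1) {
  labels <- paste0("SFW", 0:5)
  missing <- setdiff(labels, names(presets))
  if (length(missing))
    stop("presets missing condition(s): ", paste(missing, collapse = ", "))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  schedule <- samplingSchedule()
  peaks <- standardPeaks(c("T", "C", "C+"))
  manifest <- list(seed = seed, noise_sd = noiseSd, n_scans = nScans,
                   qs_reference_intensity = 1e4,
                   schedule = schedule,
                   amp_jitter_sdlog = ampJitterSdlog,
                   conditions = list())
  for (ci in seq_along(labels)) {
    lab <- labels[ci]
    preset <- presets[[lab]]
    condDir <- file.path(outDir, lab)
    reps <- list()
    for (ri in seq_len(replicates)) {
      # spread master seeds far apart so nearby seeds share no noise streams
      repSeed <- (seed * 104729 + 1000 * ci + 10 * ri) %% 2^31
      jitter <- .withSeed(repSeed + 1L, stats::setNames(
        exp(stats::rnorm(3, 0, ampJitterSdlog)), c("T", "C", "C+")))
      spec <- .repSpec(preset, grid, repSeed, noiseSd, ampScale = jitter)
      repDir <- file.path(condDir, sprintf("rep%d", ri))
      dir.create(repDir, recursive = TRUE, showWarnings = FALSE)
      growth <- simulateGrowth(spec, replicate = sprintf("rep%d", ri),
                               condition = lab)
      writeGrowthCurves(growth, file.path(repDir, "growth.csv"))
      trueQsu <- matrix(NA_real_, length(schedule), 3,
                        dimnames = list(NULL, c("T", "C", "C+")))
      for (ti in seq_along(schedule)) {
        t <- schedule[ti]
        obs <- simulateEEM(spec, t, streamOffset = ti, nScans = nScans)
        stem <- sprintf("t%02d", as.integer(t))
        writeEEM(obs$sample, file.path(repDir, sprintf("eem_%s.csv", stem)))
        writeEEM(obs$blank, file.path(repDir, sprintf("blank_%s.csv", stem)))
        writeAbsorbance(obs$absorbance,
                        file.path(repDir, sprintf("absorbance_%s.csv", stem)))
        trueQsu[ti, ] <- truePeakReadings(spec, t, peaks)
      }
      trueCfu <- 10^.growthLog10(spec@growth, schedule)
      trueF <- apply(trueQsu / (trueCfu / 1e6), 2, max)
      reps[[sprintf("rep%d", ri)]] <- list(
        seed = repSeed,
        amp_scale = as.list(jitter),
        true_peak_qsu = as.list(as.data.frame(trueQsu, check.names = FALSE)),
        true_cfu_per_ml = trueCfu,
        true_f = as.list(trueF))
    }
    # condition-level truth: per-peak max of the replicate-mean f curve
    fCurves <- lapply(reps, function(r)
      vapply(r$true_peak_qsu, identity, numeric(length(schedule))) /
        (r$true_cfu_per_ml / 1e6))
    fMean <- apply(Reduce(`+`, fCurves) / length(fCurves), 2, max)
    manifest$conditions[[lab]] <- list(
      growth_truth = simulateGrowth(
        .repSpec(preset, grid, seed, 0))@meta$truth,
      replicates = reps,
      true_f_mean = as.list(fMean),
      true_f_total = sum(fMean),
      true_percent = as.list(.roundHalfUp(100 * fMean / sum(fMean))))
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
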