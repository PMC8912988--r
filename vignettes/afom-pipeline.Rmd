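---
title: "Quantifying bacterial AFOM production from EEMs: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bacterial AFOM production from EEMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afomtools)
```

## The measurement problem

Bacteria growing in otherwise non-fluorescent water produce aquatic
fluorescent organic matter (AFOM): protein-like fluorescence (Peak T,
tryptophan-like, λ~ex~/λ~em~ 275/340 nm) and humic-like fluorescence
(Peak C at 340/420–470 nm, Peak C+ at 400/470–505 nm). Relating these
signals to the population requires (i) turning a raw instrument EEM into
comparable, quantitative intensities, and (ii) normalizing those
intensities by viable counts so production per cell can be compared
across nutrient and carbon conditions. This vignette records the models
used, every tunable that matters, and the reasoning behind choices the
design left open.

## Preprocessing model

A raw EEM is transformed in a fixed stage order:

1. **Inner-filter correction** (sample, then blank). The sample's own
   absorbance attenuates both the excitation beam and the emitted light;
   with a cuvette pathlength $L$ (cm) each cell is multiplied by
   $10^{\,L\,(A(\lambda_{ex}) + A(\lambda_{em}))/2}$ — the standard
   absorbance (ABA) method. Instruments correct this internally with
   either absorbance or transmittance; the absorbance form is fixed here
   because a paired absorbance spectrum is the input this package
   defines. Absorbance is interpolated linearly and must cover every
   grid wavelength; negative absorbance readings (baseline noise) are
   clipped to zero with a warning at construction.
2. **Blank subtraction.** Element-wise, on identical grids, after both
   fields are inner-filter corrected: attenuation acts multiplicatively
   on each measured field, so subtracting a differently-absorbing blank
   before correction would mix the two effects. Negative differences are
   retained — clipping would bias near-zero signals upward; cells below
   −5 % of the grid maximum add a metadata note instead.
3. **Rayleigh masking.** First-order ($|\lambda_{em} - \lambda_{ex}|
   \le h_1$) and second-order ($|\lambda_{em} - 2\lambda_{ex}| \le h_2$)
   bands are masked, defaults $h_1 = h_2 = 10$ nm; no half-width is
   standard across instruments, and 10 nm covers the ridge width of
   common CCD spectrometers at these slit widths. Raman scatter is not
   masked: it is weak relative to the signals of interest here and would
   cost usable band pixels.
4. **Cropping** to λ~ex~ 240–490 / λ~em~ 250–500 nm, discarding the
   deep-UV region dominated by instrument noise. Masking precedes
   cropping so scatter geometry is located on the uncut grid.
5. **Quinine sulfate normalization.** Division by the raw intensity of a
   1 µg L⁻¹ quinine sulfate standard at 347.5/450 nm; the unit tag flips
   to QSU and a second normalization is refused. Because both this stage
   and the inner-filter correction are multiplicative, their order is
   immaterial (verified to 10⁻¹² relative in the tests).

Wavelength lookups resolve nominal coordinates onto the instrument grid
(emission pixels sit at 247.88 nm + k·1.16 nm, so "340 nm" is really the
pixel at 339.52 nm). The default lookup tolerance is one grid spacing of
the axis in question and ties break toward the lower wavelength — an
arbitrary but documented rule.

## Peak quantification

A peak reading is the mean of the unmasked emission cross-section at the
nearest excitation column over the peak's emission band. Point peaks
(T, B) are specified by a single emission value and read the single
nearest pixel; a configurable half-width (`emHalfWidthNm`) widens them to
a band for users who prefer window averaging — the literature is split on
this, and the single-pixel default matches the band definitions used
here. Peak C uses the single excitation 340 nm rather than the broader
320–365 nm excitation range sometimes quoted, consistent with
cross-section peak picking. If more than half of a band's pixels are
masked the reading is an error, not a silently thin mean.

Percent change between two times is $100\,(v_2 - v_1)/v_1$; a zero
baseline is an error. Reported multi-thousand-percent increases in peak
kinetics arise from near-zero, not zero, baselines.

## Growth curves and per-cell fluorescence

Viable counts come from plate arithmetic (colonies × dilution ÷ plated
volume); zero-colony observations are carried as below-detection (`NA`)
rather than as zero cells, and are excluded from per-cell quantities.
Phases are classified from piecewise slopes of log₁₀(CFU ml⁻¹): the lag
phase is the initial run of slopes below 0.05 log₁₀ h⁻¹, the exponential
phase the following run at or above it, the remainder stationary. The
0.05 threshold is a convention — phase calls in practice are made by
inspection — chosen an order of magnitude below typical exponential
rates (~0.3 log₁₀ h⁻¹ at 37 °C) yet above plate-count jitter for
technical-triplicate counts. The classifier is deliberately simple;
single-interval count noise near the threshold can shift a boundary by
one sampling interval, which is the resolution claimed for it.

Per-cell fluorescence is $f_{QSU/CFU} = \mathrm{QSU} / (\mathrm{CFU\,
ml^{-1}} / 10^6)$, with log₁₀ f as the derived plotting scale. The
condition summary reports, per peak, the **per-condition maximum** of f:
replicate f values are averaged at each sampling time and the maximum of
that mean curve is taken. Averaging before the maximum matters — the
maximum of a noisy curve is upward-biased where the curve is flat near
its peak, and replicate averaging first reduces that bias. An endpoint
mode (`mode = "endpoint"`) is provided because summary tables built from
a fixed endpoint are also common. Percent contributions are rounded to
the nearest integer, ties half-up; integer rounding means a column can
sum to 99–101, and reported tables rounded by other software can differ
by one point in an entry.

## The synthetic world

The generator is a stated world, not a tuning knob. Its defaults:

- **Fluorophores:** separable 2-D Gaussians at the three peak centres
  (T 275/340, C 340/445, C+ 400/487.5 nm; σ~ex~ 15 nm, σ~em~ 20–25 nm).
  Real AFOM spectra are broader and asymmetric; Gaussians are the
  simplest shape that exercises peak picking, and nothing downstream
  depends on the tails.
- **Kinetics:** baseline amplitudes at inoculation of 2.2 / 0.9 / 0.6
  QSU (T / C / C+), a logistic rise centred at 11 h (scale 1.8 h) that
  plateaus after ~16 h at the condition's 48-h amplitude, and for Peak T
  an additional small early rise (1.5 QSU, centred 4 h) reproducing the
  pre-exponential protein-like signal of an upregulating population.
- **Conditions:** six SFW presets crossing nutrients with dissolved
  organic carbon; plateau amplitudes follow the observed 48-h
  intensities per condition, and carrying capacities grow with DOC
  (5×10⁶ / 2×10⁷ / 5×10⁷ CFU ml⁻¹ for none / limited / excess DOC) with
  exponential rates reaching capacity by ~12 h from a 6-h lag at a 10⁵
  CFU ml⁻¹ inoculum.
- **Instrument model:** scatter ridges along λ~em~ = λ~ex~ and λ~em~ =
  2λ~ex~ (Gaussian cross-sections, 50 and 10 QSU), a flat 1-QSU
  baseline, exponential CDOM-like absorbance (0.01 at 250 nm, slope
  0.005 nm⁻¹) plus a small per-fluorophore contribution, and additive
  Gaussian noise of 0.1 QSU per scan. Stored EEMs are technical
  triplicate means (noise ÷ √3), matching triplicate measurement at
  every time point.
- **Variability:** biological replicates jitter each peak's amplitude by
  a lognormal factor (σ~log~ = 0.1), tracked in the ground-truth
  manifest; viable counts carry 2 % lognormal observation noise
  (triplicate-mean plate counts).
- **Reproducibility:** every stream derives from the master seed by
  fixed offsets spread far apart, so identical seeds give byte-identical
  file trees and any single file is independently regenerable.

What a green end-to-end test establishes: the pipeline inverts the
forward model it defines — attenuation, blank, scatter, scaling — and
recovers known per-cell yields within the noise budget. What it does not
establish: anything about real instrument artefacts (detector
nonlinearity, wavelength calibration error, Raman bands), non-Gaussian
fluorophore shapes, or the biology linking growth phase to amplitude,
which the generator takes as phenomenological input.

## Numerical choices and degenerate inputs

- EEM files carry ≥ 12 significant digits; masked cells serialize as the
  sentinel `NA` for interoperability with ordinary table tools.
- Read errors (ragged rows, non-monotone axes, non-numeric cells) report
  row/column positions; decreasing axes are rejected rather than sorted.
- A flat growth curve classifies as a single lag phase flagged
  `no_growth`; growth from the first sample yields an empty lag.
- Fraction tables reject all-zero inputs (shares undefined) and negative
  per-cell values.
- Replicate spread is the sample standard deviation (n − 1), the usual
  small-n estimator for biological replicates.

## Known limitations

- The absorbance-based inner-filter correction is accurate to roughly
  A < 1.5 per cm; strongly absorbing samples need dilution, which the
  package does not model.
- Phase classification assumes a monotone lag → exponential → stationary
  progression; diauxic growth or death phases are out of scope.
- The per-condition maximum-f statistic remains mildly upward-biased
  under noise when the f curve is flat around its maximum (order-
  statistic bias); replicate averaging reduces but cannot remove it.
- Peak readings are cross-contaminated by spectrally adjacent
  fluorophores (a large C+ emitter contributes ~0.1 % at the C band in
  the synthetic world); no spectral unmixing is attempted.
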