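test_that("subtractBlank: self-subtraction, shifts, mask union, alignment", {
  e <- smallEEM()
  zero <- subtractBlank(e, e)
  expect_true(all(intensity(zero) == 0))

  shifted <- EEMatrix(intensity(e) + 5, excitation(e), emission(e))
  expect_true(all(intensity(subtractBlank(shifted, e)) == 5))

  # blank mask propagates regardless of sample values
  m <- matrix(FALSE, nrow(intensity(e)), ncol(intensity(e))); m[3, 2] <- TRUE
  blank <- EEMatrix(intensity(e), excitation(e), emission(e), mask = m)
  expect_true(eemMask(subtractBlank(shifted, blank))[3, 2])

  other <- smallEEM(ex = seq(251, 301, by = 10))
  expect_error(subtractBlank(e, other), "different wavelength grids")
  qsuE <- flatEEM(1)
  expect_error(subtractBlank(qsuE, flatEEM(1, unit = "raw",
                                           ex = excitation(qsuE),
                                           em = emission(qsuE))),
               "units differ")
})

test_that("correctIFE applies the ABA factor and inverts attenuation", {
  e <- smallEEM()
  aZero <- AbsorbanceSpectrum(c(200, 700), c(0, 0))
  expect_equal(intensity(correctIFE(e, aZero)), intensity(e))

  # A = 0.1 at both wavelengths, 1 cm -> every cell scaled by 10^0.1
  aFlat <- AbsorbanceSpectrum(c(200, 700), c(0.1, 0.1))
  expect_equal(intensity(correctIFE(e, aFlat)), intensity(e) * 10^0.1,
               tolerance = 1e-12)

  # forward-attenuate then correct recovers the original
  wl <- seq(200, 700, by = 2)
  aSpec <- AbsorbanceSpectrum(wl, 0.3 * exp(-(wl - 200) / 180))
  aEx <- absorbanceAt(aSpec, excitation(e))
  aEm <- absorbanceAt(aSpec, emission(e))
  att <- EEMatrix(intensity(e) * 10^(-outer(aEm, aEx, "+") / 2),
                  excitation(e), emission(e))
  rec <- correctIFE(att, aSpec)
  expect_equal(intensity(rec), intensity(e), tolerance = 1e-9)

  # pathlength scales the exponent
  half <- correctIFE(e, aFlat, pathlengthCm = 0.5)
  expect_equal(intensity(half), intensity(e) * 10^0.05, tolerance = 1e-12)

  shortCover <- AbsorbanceSpectrum(c(260, 320), c(0.1, 0.1))
  expect_error(correctIFE(e, shortCover), "coverage")
})

test_that("maskRayleigh masks both scatter orders and nothing else", {
  ex <- seq(250, 450, by = 25)
  em <- seq(250, 550, by = 25)
  e <- EEMatrix(matrix(1, length(em), length(ex)), ex, em)
  m <- eemMask(maskRayleigh(e, 10, 10))
  expect_true(m[which(em == 300), which(ex == 300)])   # first order
  expect_true(m[which(em == 500), which(ex == 250)])   # second order
  expect_false(m[which(em == 340 - 15), which(ex == 275)])

  # peak T coordinates survive default masking on a fine grid
  f <- flatEEM(1, unit = "raw")
  mf <- maskRayleigh(f)
  i <- nearestIndex(emission(f), 340); j <- nearestIndex(excitation(f), 275)
  expect_false(eemMask(mf)[i, j])
})

test_that("masked-cell set equals brute-force band predicates", {
  ex <- seq(240, 485, by = 5)[1:50]
  em <- seq(250, 495, by = 5)[1:50]
  e <- EEMatrix(matrix(0, 50, 50), ex, em)
  got <- eemMask(maskRayleigh(e, 12, 8))
  want <- matrix(FALSE, 50, 50)
  for (i in 1:50) for (j in 1:50)
    want[i, j] <- abs(em[i] - ex[j]) <= 12 || abs(em[i] - 2 * ex[j]) <= 8
  expect_identical(got, want)
})

test_that("normalizeQSU divides by the reference and guards the unit tag", {
  ref <- qsReference(1234.5)
  e <- flatEEM(1234.5, unit = "raw")
  n <- normalizeQSU(e, ref)
  expect_equal(eemUnit(n), "QSU")
  expect_true(all(abs(intensity(n) - 1) < 1e-12))
  expect_error(normalizeQSU(n, ref), "already in QSU")

  two <- flatEEM(2 * 1234.5, unit = "raw")
  expect_true(all(abs(intensity(normalizeQSU(two, ref)) - 2) < 1e-12))

  # ratios between cells are preserved
  set.seed(1)
  r <- smallEEM(fill = function(i, j) abs(rnorm(length(i))) + 0.1)
  rn <- normalizeQSU(r, qsReference(321))
  expect_equal(intensity(rn)[2, 3] / intensity(rn)[4, 1],
               intensity(r)[2, 3] / intensity(r)[4, 1])
})

test_that("a measured QS-standard EEM normalizes to 1 QSU at (347.5, 450)", {
  qs <- gaussianEEM(8e3, 347.5, 450, 20, 30,
                    ex = seq(300, 400, by = 2.5),
                    em = seq(401.48, 502.68, by = 1.16), unit = "raw")
  ref <- qsReferenceFromEEM(qs)
  n <- normalizeQSU(qs, ref)
  i <- nearestIndex(emission(n), 450)
  j <- nearestIndex(excitation(n), 347.5)
  expect_identical(intensity(n)[i, j], 1)
})

test_that("pipeline: zero signal and order-invariance of scaling stages", {
  spec <- simulationSpec(grid = coarseGrid(), noiseSd = 0, seed = 2)
  obs <- simulateEEM(spec, 8)

  # blank == sample with no absorbance -> zero field
  aZero <- AbsorbanceSpectrum(c(200, 700), c(0, 0))
  z <- preprocessPipeline(obs$sample, obs$sample, aZero, obs$ref)
  expect_true(all(abs(intensity(z)[!eemMask(z)]) < 1e-12))

  # IFE and QSU normalization commute (both multiplicative)
  cfg <- preprocessConfig()
  a <- normalizeQSU(correctIFE(obs$sample, obs$absorbance), obs$ref)
  b <- correctIFE(normalizeQSU(obs$sample, obs$ref), obs$absorbance)
  expect_equal(intensity(a), intensity(b), tolerance = 1e-12)

  # processing log names every stage
  full <- preprocessPipeline(obs$sample, obs$blank, obs$absorbance, obs$ref)
  log <- eemMeta(full)$processing_log
  expect_true(any(grepl("inner-filter", log)))
  expect_true(any(grepl("blank", log)))
  expect_true(any(grepl("Rayleigh", log)))
  expect_true(any(grepl("crop", log)))
  expect_true(any(grepl("QSU", log)))
})

test_that("sterile control stays below 5 QSU for every peak", {
  # a blank-level sample: no fluorophores, realistic noise on
  spec <- simulationSpec(grid = coarseGrid(), fluorophores = list(),
                         noiseSd = 0.1, seed = 5)
  obs <- simulateEEM(spec, 48)
  qsu <- preprocessPipeline(obs$sample, obs$blank, obs$absorbance, obs$ref)
  for (p in standardPeaks(c("T", "C", "C+")))
    expect_lt(abs(pickPeak(qsu, p)), 5)
})
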