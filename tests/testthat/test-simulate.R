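# a light spec for fast simulator tests
tinyGrid <- function() list(excitation = seq(240, 500, by = 10),
                            emission = seq(247.88, 598, by = 9.28))

test_that("simulateGrowth follows the closed-form three-phase curve", {
  spec <- simulationSpec(grid = tinyGrid(), noiseSd = 0,
                         growth = list(inoculum = 1e5, lagH = 6,
                                       maxRate = 1 / 3, capacity = 1e7),
                         seed = 1)
  g <- simulateGrowth(spec)
  t <- sampleTimes(g)
  expect_equal(t, c(0:8, 12, 16, 20, 24, 36, 48))
  expect_equal(cfuPerMl(g)[t <= 6], rep(1e5, 7))
  expect_equal(cfuPerMl(g)[t == 12], 1e7)          # capacity reached at 12 h
  expect_equal(cfuPerMl(g)[t == 8], 1e5 * 10^(2 / 3))
  expect_equal(cfuPerMl(g)[t > 12], rep(1e7, 5))

  ph <- classifyPhases(g)
  expect_equal(ph$t_end[ph$phase == "lag"], 6)
  expect_equal(ph$t_start[ph$phase == "stationary"], 12)

  # degenerate: lag spanning the whole experiment
  flat <- simulationSpec(grid = tinyGrid(), growth = list(lagH = 48), seed = 1)
  expect_equal(cfuPerMl(simulateGrowth(flat)), rep(1e5, 15))

  expect_error(simulationSpec(growth = list(capacity = 1e4)),
               "capacity below inoculum")
})

test_that("growth observation noise is seeded and reproducible", {
  spec <- simulationSpec(grid = tinyGrid(),
                         growth = list(noiseSdlog = 0.05), seed = 9)
  g1 <- simulateGrowth(spec); g2 <- simulateGrowth(spec)
  expect_identical(cfuPerMl(g1), cfuPerMl(g2))
  expect_false(identical(cfuPerMl(g1),
                         cfuPerMl(simulateGrowth(simulationSpec(
                           grid = tinyGrid(),
                           growth = list(noiseSdlog = 0.05), seed = 10)))))
  # noise is multiplicative around the deterministic curve
  det <- simulateGrowth(simulationSpec(grid = tinyGrid(), seed = 9))
  expect_true(all(abs(log(cfuPerMl(g1) / cfuPerMl(det))) < 0.05 * 5))
})

test_that("exponential-segment rate estimate recovers the generating rate", {
  for (seed in 1:10) {
    rate <- runif(1, 0.2, 0.45)
    spec <- simulationSpec(grid = tinyGrid(),
                           growth = list(maxRate = rate,
                                         noiseSdlog = 0.02),
                           seed = seed)
    g <- simulateGrowth(spec)
    truth <- g@meta$truth
    t <- sampleTimes(g)
    inWin <- t >= truth$lag_end_h & t <= truth$stationary_start_h
    fit <- stats::lm(log10(cfuPerMl(g)[inWin]) ~ t[inWin])
    expect_lt(abs(coef(fit)[2] - rate) / rate, 0.05)
  }
})

test_that("simulateEEM: determinism, attenuation closed form, null model", {
  spec <- simulationSpec(grid = tinyGrid(), noiseSd = 0.1, seed = 21)
  a <- simulateEEM(spec, 12); b <- simulateEEM(spec, 12)
  expect_identical(intensity(a$sample), intensity(b$sample))
  expect_identical(intensity(a$blank), intensity(b$blank))

  # flat absorbance 0.2: raw field is the zero-absorbance field x 10^-0.2
  mk <- function(a250) simulationSpec(
    grid = tinyGrid(), noiseSd = 0,
    absorbance = list(a250 = a250, slope = 0, perQsu = 0), seed = 1)
  e0 <- simulateEEM(mk(0), 16); e2 <- simulateEEM(mk(0.2), 16)
  expect_equal(intensity(e2$sample), intensity(e0$sample) * 10^-0.2,
               tolerance = 1e-12)

  # no fluorophores: preprocessed sample - blank vanishes within noise
  null <- simulationSpec(grid = tinyGrid(), fluorophores = list(),
                         noiseSd = 0.05, seed = 3)
  obs <- simulateEEM(null, 24)
  qsu <- preprocessPipeline(obs$sample, obs$blank, obs$absorbance, obs$ref)
  resid <- intensity(qsu)[!eemMask(qsu)]
  expect_lt(max(abs(resid)), 3 * 0.05 * sqrt(2) * 5)  # generous noise bound
  expect_lt(abs(mean(resid)), 0.01)
})

test_that("single on-peak fluorophore is recovered through the pipeline", {
  # noise off, no absorbance, no scatter: pickPeak(T) returns amplitude(t)
  # up to the nearest-pixel offset (< 0.1% on the instrument grid)
  fl <- list(fluorophoreSpec("T", 275, 340, kinetics = 7.3))
  spec <- simulationSpec(fluorophores = fl, noiseSd = 0,
                         scatter = list(amp1 = 0, amp2 = 0),
                         absorbance = list(a250 = 0, slope = 0, perQsu = 0),
                         baseline = 0, seed = 1)
  obs <- simulateEEM(spec, 10)
  qsu <- preprocessPipeline(obs$sample, obs$blank, obs$absorbance, obs$ref)
  expect_lt(abs(pickPeak(qsu, "T") - 7.3) / 7.3, 0.001)
})

test_that("amplitude kinetics interpolate and clamp", {
  k <- amplitudeKinetics(100, a0 = 2, times = c(0, 6, 12, 24, 48))
  fl <- fluorophoreSpec("X", 300, 400, kinetics = k)
  expect_equal(afomtools:::.amplitudeAt(fl, 48), k$amplitude[5])
  expect_equal(afomtools:::.amplitudeAt(fl, 60), k$amplitude[5])  # clamp
  mid <- (k$amplitude[2] + k$amplitude[3]) / 2
  expect_equal(afomtools:::.amplitudeAt(fl, 9), mid)              # linear
  expect_true(all(diff(k$amplitude) > 0))
})

test_that("simulateConditionSet writes a reproducible, complete dataset", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- simulateConditionSet(d1, seed = 5, replicates = 1,
                             grid = tinyGrid())
  m2 <- simulateConditionSet(d2, seed = 5, replicates = 1,
                             grid = tinyGrid())
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  # 6 conditions x 1 replicate x 15 times x (eem + blank + absorbance)
  expect_length(grep("eem_t", files), 90)
  expect_length(grep("blank_t", files), 90)
  expect_length(grep("growth.csv", files), 6)
  # identical content under the same master seed
  for (f in c("manifest.json", "SFW3/rep1/eem_t06.csv",
              "SFW5/rep1/growth.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  expect_error(simulateConditionSet(d1, presets = sfwPresets()[1:5]),
               "SFW5")

  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_named(man$conditions, paste0("SFW", 0:5))
  # DOC-scaled amplitudes: recovered true f_total ordering tracks DOC
  ftot <- vapply(man$conditions, function(cc) cc$true_f_total, 0)
  expect_gt(ftot[["SFW4"]], ftot[["SFW1"]])
  expect_gt(ftot[["SFW2"]], ftot[["SFW0"]])
})
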