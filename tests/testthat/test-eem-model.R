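test_that("nearestIndex resolves grid points, ties and tolerance", {
  ax <- seq(200, 600)
  expect_equal(nearestIndex(ax, 275, 1), which(ax == 275))

  # 1.16 nm emission grid: oracle enumerates 247.88 + 1.16 k
  emAx <- seq(247.88, 829.85, by = 1.16)
  oracle <- which.min(abs(emAx - 340))
  expect_equal(nearestIndex(emAx, 340, 1.16), oracle)
  expect_equal(emAx[oracle], 339.52, tolerance = 1e-9)

  # ties break toward the lower wavelength
  expect_equal(nearestIndex(c(250, 260), 255, 10), 1L)

  expect_error(nearestIndex(ax, 700, 1), "no wavelength within")
  expect_error(nearestIndex(ax, 275, 0), "tolerance")
})

test_that("nearestIndex errors exactly when min distance exceeds tolerance", {
  set.seed(42)
  ax <- sort(runif(25, 200, 600))
  for (target in runif(50, 150, 650)) {
    tol <- runif(1, 0.5, 60)
    shouldFail <- min(abs(ax - target)) > tol  # brute-force scan
    if (shouldFail) expect_error(nearestIndex(ax, target, tol))
    else expect_equal(ax[nearestIndex(ax, target, tol)],
                      ax[which.min(abs(ax - target))])
  }
})

test_that("cropEEM keeps exactly the grid points inside the ranges", {
  full <- EEMatrix(matrix(rnorm(502 * 401), 502, 401),
                   excitation = seq(200, 600, by = 1),
                   emission = seq(247.88, 829.85, by = 1.16))
  cr <- cropEEM(full, c(240, 490), c(250, 500))
  expect_length(excitation(cr), 251)  # 240..490 inclusive
  # emission points: 247.88 + 1.16 k within [250, 500], counted brute force
  emAx <- seq(247.88, 829.85, by = 1.16)
  expect_length(emission(cr), sum(emAx >= 250 & emAx <= 500))
  expect_equal(dim(intensity(cr)), c(length(emission(cr)), 251L))

  # identity crop and idempotence
  e <- smallEEM()
  expect_equal(intensity(cropEEM(e, range(excitation(e)), range(emission(e)))),
               intensity(e))
  c1 <- cropEEM(e, c(260, 290), c(270, 330))
  c2 <- cropEEM(c1, c(260, 290), c(270, 330))
  expect_equal(excitation(c1), excitation(c2))
  expect_equal(intensity(c1), intensity(c2))

  expect_error(cropEEM(e, c(700, 800), c(260, 340)), "no grid points")
})

test_that("EEMatrix validity rejects malformed objects", {
  expect_error(EEMatrix(matrix(1, 2, 2), excitation = c(300, 290),
                        emission = c(350, 360)), "strictly increasing")
  expect_error(EEMatrix(matrix(1, 2, 3), excitation = c(300, 310),
                        emission = c(350, 360)), "shape")
  expect_error(EEMatrix(matrix(c(1, NA, 1, 1), 2, 2),
                        excitation = c(300, 310),
                        emission = c(350, 360)), "finite")
  # NA under a mask is allowed
  m <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)
  e <- EEMatrix(matrix(c(1, 0, 1, 1), 2, 2), excitation = c(300, 310),
                emission = c(350, 360), mask = m)
  expect_equal(sum(eemMask(e)), 1L)
})

test_that("EEM write/read round-trips axes, intensities and mask", {
  set.seed(7)
  mask <- matrix(FALSE, 5, 5); mask[2, 3] <- TRUE
  e <- EEMatrix(matrix(rnorm(25) * 1e3, 5, 5),
                excitation = seq(300, 340, by = 10),
                emission = seq(350.5, 390.5, by = 10),
                mask = mask)
  for (delim in c(",", "\t")) {
    path <- withr::local_tempfile(fileext = ".csv")
    writeEEM(e, path, delim = delim)
    back <- readEEM(path)
    expect_equal(excitation(back), excitation(e), tolerance = 1e-9)
    expect_equal(emission(back), emission(e), tolerance = 1e-9)
    expect_equal(eemMask(back), eemMask(e))
    expect_equal(intensity(back)[!mask], intensity(e)[!mask],
                 tolerance = 1e-9)
  }
})

test_that("readEEM reports malformed files with positions", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",300,290", "350,1,2", "360,3,4"), p)  # decreasing header
  expect_error(readEEM(p), "not strictly increasing")

  writeLines(c(",300,310", "350,1,2", "360,3"), p)    # ragged row
  expect_error(readEEM(p), "ragged row 3")

  writeLines(c(",300,310", "350,1,x", "360,3,4"), p)  # non-numeric body
  expect_error(readEEM(p), "row 2, column 3")

  writeLines(c(",300,310", "350,1,NA", "360,3,4"), p) # sentinel -> mask
  e <- readEEM(p)
  expect_equal(sum(eemMask(e)), 1L)
  expect_true(eemMask(e)[1, 2])
})

test_that("AbsorbanceSpectrum clips negatives and interpolates linearly", {
  expect_warning(a <- AbsorbanceSpectrum(c(300, 400), c(-0.01, 0.2)),
                 "clipped")
  expect_equal(absorbanceAt(a, 300), 0)
  expect_equal(absorbanceAt(a, 350), 0.1)  # linear midpoint of 0 and 0.2
  expect_error(absorbanceAt(a, 250), "coverage")

  b <- AbsorbanceSpectrum(seq(200, 800, by = 2), rep(0.05, 301))
  expect_equal(absorbanceAt(b, c(247.88, 601.3)), c(0.05, 0.05))
})

test_that("absorbance file round trip", {
  a <- AbsorbanceSpectrum(seq(240, 600, by = 5), runif(73, 0, 0.3))
  p <- withr::local_tempfile(fileext = ".csv")
  writeAbsorbance(a, p)
  b <- readAbsorbance(p)
  expect_equal(absorbanceAt(b, c(250, 333.3, 599)),
               absorbanceAt(a, c(250, 333.3, 599)), tolerance = 1e-9)
})
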