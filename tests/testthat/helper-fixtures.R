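# shared fixtures: tiny grids and brute-force oracles built in code

# a small rectangular EEM with deterministic intensities
smallEEM <- function(ex = seq(250, 300, by = 10), em = seq(260, 340, by = 8),
                     fill = function(i, j) i + 10 * j, unit = "raw") {
  grid <- outer(seq_along(em), seq_along(ex), fill)
  EEMatrix(grid, excitation = ex, emission = em, unit = unit)
}

# constant-intensity EEM on an analysis-window grid (QSU by default)
flatEEM <- function(value = 1, unit = "QSU",
                    ex = seq(240, 500, by = 5),
                    em = seq(247.88, 598, by = 4.64)) {
  EEMatrix(matrix(value, length(em), length(ex)), excitation = ex,
           emission = em, unit = unit)
}

# evaluate a separable Gaussian fluorophore on a grid (brute-force oracle)
gaussianEEM <- function(amp, cex, cem, sex, sem,
                        ex = seq(240, 500, by = 5),
                        em = seq(247.88, 598, by = 4.64), unit = "QSU") {
  grid <- amp * outer(exp(-0.5 * ((em - cem) / sem)^2),
                      exp(-0.5 * ((ex - cex) / sex)^2))
  EEMatrix(grid, excitation = ex, emission = em, unit = unit)
}

# brute-force mean of a Gaussian over a peak's pixel set
bruteForcePeakMean <- function(amp, cex, cem, sex, sem, peak, ex, em) {
  j <- which.min(abs(ex - peak@excitationNm))
  b <- peak@emissionBand
  rows <- if (b[1] == b[2]) which.min(abs(em - b[1]))
          else which(em >= b[1] & em <= b[2])
  vals <- amp * exp(-0.5 * ((ex[j] - cex) / sex)^2) *
    exp(-0.5 * ((em[rows] - cem) / sem)^2)
  mean(vals)
}
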