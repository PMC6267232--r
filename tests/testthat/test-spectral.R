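toneTs <- function(freqs, fs = 625, nT = 1250, phase = 0) {
  t <- seq_len(nT) - 1
  data <- do.call(rbind, lapply(freqs, function(f)
    sin(2 * pi * f * t / fs + phase)))
  roiTimeSeries(data, fs, roiLabels = sprintf("roi%d", seq_along(freqs)))
}

test_that("brick-wall band-pass keeps in-band tones and kills out-of-band ones", {
  ts <- toneTs(c(6, 20))                  # both on-bin for nT = 1250
  out <- as.matrix(bandpass(ts, thetaBand()))
  expect_lt(max(abs(out[1, ] - as.matrix(ts)[1, ])), 0.01)     # 6 Hz kept
  expect_lt(sqrt(mean(out[2, ]^2)), 1e-10 * sqrt(mean(as.matrix(ts)[2, ]^2)))
})

test_that("band-passed white noise has spectral support only inside the band", {
  set.seed(5)
  ts <- roiTimeSeries(matrix(rnorm(2 * 2000), 2), 625,
                      roiLabels = c("a", "b"))
  out <- as.matrix(bandpass(ts, thetaBand()))
  spec <- abs(fft(out[1, ]))
  f <- pmin((0:1999) * 625 / 2000, 625 - (0:1999) * 625 / 2000)
  expect_lt(max(spec[f < 4 | f > 8]), 1e-9)
  expect_gt(max(spec[f >= 4 & f <= 8]), 1)
})

test_that("band-pass is a projection (idempotent) and respects Nyquist", {
  set.seed(6)
  ts <- roiTimeSeries(matrix(rnorm(2 * 500), 2), 625,
                      roiLabels = c("a", "b"))
  once <- bandpass(ts, thetaBand())
  twice <- bandpass(once, thetaBand())
  expect_lt(max(abs(as.matrix(twice) - as.matrix(once))), 1e-12)
  expect_error(bandpass(ts, bandDefinition("huge", 100, 400)),
               "Nyquist")
})

test_that("instantaneous phase advances linearly for a pure tone", {
  ts <- toneTs(c(6, 6), nT = 2500)
  ph <- instantaneousPhase(ts)
  core <- 200:2300                        # away from epoch edges
  inc <- diff(ph[1, core])
  inc <- inc[abs(inc) < pi]               # drop wrap-arounds
  expect_lt(max(abs(inc - 2 * pi * 6 / 625)), 1e-3)
  # wrap-around count matches the number of completed cycles
  wraps <- sum(diff(ph[1, ]) < -pi)
  expect_lte(abs(wraps - floor(6 * 2500 / 625)), 1)
})

test_that("cos leads sin by a quarter cycle in phase", {
  t <- (0:2499)
  data <- rbind(cos(2 * pi * 6 * t / 625), sin(2 * pi * 6 * t / 625))
  ts <- roiTimeSeries(data, 625, roiLabels = c("cos", "sin"))
  ph <- instantaneousPhase(ts)
  d <- ph[1, 300:2200] - ph[2, 300:2200]
  d <- atan2(sin(d), cos(d))
  expect_lt(max(abs(d - pi / 2)), 1e-3)
})

test_that("phase matches the closed-form analytic signal of sinusoid mixtures", {
  # fixture built from on-bin cosines, whose analytic signal is known in
  # closed form (sum of complex exponentials) without any FFT
  set.seed(7)
  nT <- 1024; fs <- 625
  bins <- sample(8:120, 5)                # strictly inside (0, Nyquist)
  amp <- runif(5, 0.5, 2); pha <- runif(5, -pi, pi)
  t <- 0:(nT - 1)
  x <- colSums(amp * t(sapply(seq_along(bins), function(m)
    cos(2 * pi * bins[m] * t / nT + pha[m]))))
  zRef <- colSums(amp * t(sapply(seq_along(bins), function(m)
    exp(1i * (2 * pi * bins[m] * t / nT + pha[m])))))
  ts <- roiTimeSeries(rbind(x, x), fs, roiLabels = c("a", "b"))
  ph <- instantaneousPhase(ts)
  d <- ph[1, ] - atan2(Im(zRef), Re(zRef))
  expect_lt(max(abs(atan2(sin(d), cos(d)))), 1e-9)
})

test_that("constant signals have undefined phase", {
  ts <- roiTimeSeries(rbind(rnorm(100), rep(1, 100)), 625,
                      roiLabels = c("ok", "flat"))
  expect_error(instantaneousPhase(ts), "undefined phase.*flat")
})

test_that("epoch segmentation is non-overlapping with remainder discarded", {
  ts <- roiTimeSeries(matrix(seq_len(2 * 20480), 2, byrow = TRUE), 625,
                      roiLabels = c("a", "b"))
  eps <- segmentEpochs(ts, 4096)
  expect_length(eps, 5L)
  expect_true(all(vapply(eps, nSamples, integer(1)) == 4096L))
  expect_identical(unname(as.matrix(eps[[2]])[1, 1]), 4097L)

  short <- roiTimeSeries(matrix(rnorm(2 * 4095), 2), 625,
                         roiLabels = c("a", "b"))
  expect_error(segmentEpochs(short, 4096), "too short")

  odd <- roiTimeSeries(matrix(rnorm(2 * 8193), 2), 625,
                       roiLabels = c("a", "b"))
  eps <- segmentEpochs(odd, 4096)
  expect_length(eps, 2L)                  # trailing sample dropped
})

test_that("phaseEpochs composes band-pass, segmentation and per-epoch phase", {
  set.seed(8)
  ts <- roiTimeSeries(matrix(rnorm(3 * 2048), 3), 625,
                      roiLabels = c("a", "b", "c"))
  eps <- phaseEpochs(ts, thetaBand(), 1024)
  expect_length(eps, 2L)
  expect_s4_class(eps[[1]], "PhaseEpoch")
  expect_identical(roiLabels(eps[[1]]), c("a", "b", "c"))
  # equals the explicit composition
  manual <- instantaneousPhase(segmentEpochs(bandpass(ts, thetaBand()),
                                             1024)[[2]])
  expect_identical(eps[[2]]@phases, manual)
})
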