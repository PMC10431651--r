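test_that("optical density conversion follows -log10(I/Ibar)", {
  lay <- default_layout()
  par <- default_paradigm(baseline_s = 10, n_trials = 1L, task_s = 5,
                          rest_s = 5)
  n <- ceiling(par$total_s * 7.8125)
  # constant intensity -> zero OD
  rec <- nirs_recording(array(500, c(25, 2, n)), lay, par)
  od <- intensity_to_od(rec)
  expect_true(all(od$od == 0))
  # a dip to Ibar/10 gives OD = 1 at that sample (up to the mean shift)
  s <- seq(0, 0.2, length.out = n)  # arbitrary smooth log-attenuation
  arr <- array(rep(1000 * exp(-s), each = 50), c(25, 2, n))
  rec2 <- nirs_recording(arr, lay, par)
  od2 <- intensity_to_od(rec2)
  ibar <- mean(arr[1, 1, ])
  expect_equal(od2$od[1, 1, ], -log10(arr[1, 1, ] / ibar), tolerance = 1e-12)
  expect_equal(od2$od[1, 1, ] - mean(od2$od[1, 1, ]),
               (s - mean(s)) / log(10), tolerance = 1e-12)
})

test_that("band-pass magnitude response matches the Butterworth contract", {
  fs <- 7.8125
  t <- seq(0, 1200, by = 1 / fs)
  # DC removal
  const <- rep(2, length(t))
  out <- bandpass(const, fs, c(0.01, 0.09), "zero_phase")
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  expect_lt(max(abs(out[mid])), 1e-6 * 2)
  # 0.05 Hz in-band sinusoid: amplitude in [0.9, 1] after zero-phase pass
  x <- sin(2 * pi * 0.05 * t)
  y <- bandpass(x, fs, c(0.01, 0.09), "zero_phase")
  expect_gte(max(abs(y[mid])), 0.9)
  expect_lte(max(abs(y[mid])), 1.0)
  # no lag: cross-correlation peaks at lag zero
  cc <- stats::ccf(y[mid], x[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # 1 Hz stop-band tone: single causal pass attenuates >= 60 dB
  x1 <- sin(2 * pi * 1 * t)
  y1 <- bandpass(x1, fs, c(0.01, 0.09), "causal")
  att_db <- -20 * log10(max(abs(y1[mid])))
  expect_gte(att_db, 60)
  expect_error(bandpass(x, fs, c(0.01, 4)), "Nyquist")
})

test_that("polyphase resampling preserves in-band content and length", {
  fs <- 7.8125
  n <- 7969
  t <- (seq_len(n) - 1) / fs
  # constant -> constant of the resampled length
  yc <- resample_4hz(rep(3, n), fs)
  expect_equal(length(yc), 4080)
  expect_equal(range(yc), c(3, 3), tolerance = 1e-12)
  # 0.05 Hz sinusoid amplitude within 1%
  y <- resample_4hz(sin(2 * pi * 0.05 * t), fs)
  mid <- seq(200, length(y) - 200)
  expect_lt(abs(max(abs(y[mid])) - 1), 0.01)
  # and it matches the analytic sinusoid on the new grid
  t4 <- (seq_along(y) - 1) / 4
  expect_lt(max(abs(y[mid] - sin(2 * pi * 0.05 * t4[mid]))), 0.01)
  expect_error(resample_4hz(y, -1), "positive")
  expect_error(resample_4hz(y, 2), "exceed")
})

test_that("Beer-Lambert inversion solves the pinned 2x2 system", {
  lay <- default_layout()
  cons <- mbll_constants(lay)
  # hand-solved inversion for dOD = (0.01, 0.02) on a 30 mm channel
  E <- cons$extinction
  d <- 3 * 6.0  # cm x DPF
  od_pair <- c(0.01, 0.02) / d
  det_e <- E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1]
  hbo_hand <- (E[2, 2] * od_pair[1] - E[1, 2] * od_pair[2]) / det_e
  hbr_hand <- (-E[2, 1] * od_pair[1] + E[1, 1] * od_pair[2]) / det_e
  par <- default_paradigm(baseline_s = 1, n_trials = 1L, task_s = 1,
                          rest_s = 1)
  arr <- array(0, c(25, 2, 24))
  arr[, 1, ] <- 0.01
  arr[, 2, ] <- 0.02
  od <- structure(list(od = arr, fs = 8, layout = lay, paradigm = par,
                       reference = "test"),
                  class = "optical_density")
  dimnames(od$od) <- list(lay$channels$name, c("760", "850"), NULL)
  hemo <- mbll(od, cons)
  expect_equal(unname(hemo$hbo["S1-D1", 1]), hbo_hand, tolerance = 1e-12)
  expect_equal(unname(hemo$hbr["S1-D1", 1]), hbr_hand, tolerance = 1e-12)
  # zero OD -> zero concentrations
  od$od[] <- 0
  hemo0 <- mbll(od, cons)
  expect_true(all(hemo0$hbo == 0) && all(hemo0$hbr == 0))
})

test_that("forward and inverse Beer-Lambert maps are exact inverses", {
  lay <- default_layout()
  cons <- mbll_constants(lay)
  par <- default_paradigm(baseline_s = 1, n_trials = 1L, task_s = 1,
                          rest_s = 1)
  for (seed in 1:3) {
    set.seed(seed)
    hbo <- matrix(stats::rnorm(25 * 50), 25, 50,
                  dimnames = list(lay$channels$name, NULL))
    hbr <- matrix(stats::rnorm(25 * 50), 25, 50,
                  dimnames = list(lay$channels$name, NULL))
    hemo <- hemo_ts(hbo, hbr, fs = 8, layout = lay, paradigm = par)
    back <- mbll(forward_mbll(hemo, cons), cons)
    expect_lt(max(abs(back$hbo - hbo)), 1e-9)
    expect_lt(max(abs(back$hbr - hbr)), 1e-9)
  }
  # linearity of the forward map
  hemo1 <- hemo_ts(hbo, hbr, fs = 8, layout = lay, paradigm = par)
  hemo2 <- hemo_ts(2 * hbo, 2 * hbr, fs = 8, layout = lay, paradigm = par)
  expect_equal(forward_mbll(hemo2, cons)$od, 2 * forward_mbll(hemo1, cons)$od,
               tolerance = 1e-12)
})

test_that("filtering commutes with the (linear) Beer-Lambert map", {
  s <- noiseless_subject()
  rec <- s$recording
  # pipeline order: OD -> filter -> resample -> MBLL
  h1 <- preprocess_recording(rec, band = c(0.01, 0.09), channels = "S1-D1")
  # alternative order: OD -> MBLL -> filter -> resample
  od <- intensity_to_od(rec)
  hemo_raw <- mbll(od)
  x <- bandpass(hemo_raw$hbo["S1-D1", ], rec$fs, c(0.01, 0.09), "zero_phase")
  x4 <- resample_4hz(x, rec$fs)
  # the two orders agree up to the rounding-noise gain of the narrow-band
  # recursion (poles near the unit circle amplify last-bit differences)
  expect_lt(max(abs(h1$hbo["S1-D1", ] - x4)), 1e-6)
})
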