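disk_mask <- function(shape, cx, cy, r) {
  x <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  y <- matrix(seq_len(shape[1]), shape[1], shape[2])
  (x - cx)^2 + (y - cy)^2 <= r^2
}

test_that("neuropil ring grows until the area criterion is met", {
  shape <- c(120, 120)
  roi <- disk_mask(shape, 60, 60, 20)
  ring <- build_neuropil_ring(1, list(roi), shape)
  # continuous-area oracle: the 14-px ring of a 20-px disk is ~2375 px
  # (< 2500), so dilation must increment to 15 px (~2592 px)
  expect_equal(ring$dilation_used, 15)
  expect_gte(ring$ring_area, 2500)
  expect_lt(abs(ring$ring_area - pi * (35^2 - 20^2)) / ring$ring_area, 0.03)
  expect_false(ring$flag_small)
  expect_false(any(ring$mask & roi))
})

test_that("rings exclude all ROI masks, not just their own", {
  shape <- c(100, 100)
  a <- disk_mask(shape, 40, 50, 10)
  b <- disk_mask(shape, 60, 50, 10)
  ring_a <- build_neuropil_ring(1, list(a, b), shape)
  expect_false(any(ring_a$mask & a))
  expect_false(any(ring_a$mask & b))
})

test_that("degenerate geometry is flagged, not fatal", {
  shape <- c(60, 60)
  full <- matrix(TRUE, 60, 60)
  ring <- build_neuropil_ring(1, list(full), shape)
  expect_true(ring$flag_small)
  expect_equal(ring$ring_area, 0)
})

test_that("neuropil subtraction removes exactly the shared component", {
  s <- sin(seq(0, 10, length.out = 200))
  g <- cumsum(rnorm(200, sd = 0.1))
  expect_equal(neuropil_subtract(s + g, g), s)
  expect_equal(neuropil_subtract(s, rep(0, 200)), s)
  expect_equal(neuropil_subtract(g, g), rep(0, 200))
  expect_error(neuropil_subtract(1:5, 1:4), "equal length")
})

test_that("bleach fit recovers a known mono-exponential", {
  t <- seq(0, 600, by = 0.02)
  y <- 100 * exp(-t / 300)
  bl <- bleach_correct(y, t, baseline_seconds = 240)
  expect_equal(bl$method, "exponential")
  expect_lt(abs(bl$tau - 300) / 300, 0.05)
  expect_lt(max(abs(bl$corrected)), 1)   # residual < 1% of amplitude
  set.seed(42)
  yn <- y + rnorm(length(t))
  bln <- bleach_correct(yn, t, baseline_seconds = 240)
  expect_lt(abs(bln$tau - 300) / 300, 0.10)
})

test_that("bleach correction of a flat trace is a constant shift", {
  t <- seq(0, 500, by = 0.1)
  bl <- bleach_correct(rep(7, length(t)), t)
  expect_lt(max(abs(bl$corrected)), 1e-6)
})

test_that("bleach correction is idempotent", {
  t <- seq(0, 600, by = 0.05)
  y <- 50 * exp(-t / 200) + 10
  once <- bleach_correct(y, t)
  twice <- bleach_correct(once$corrected, t)
  expect_lt(abs(twice$amplitude), abs(once$amplitude) * 0.02 + 1e-8)
})

test_that("trial alignment computes dF/F0 with the sign convention", {
  fr <- 10
  n <- 200 * fr
  tr <- matrix(100, 2, n)
  time <- (seq_len(n) - 1) / fr
  # ROI 2: drops to 90 after the onset (cADDis-like dip)
  tr[2, time >= 60] <- 90
  tt <- trigger_trials(tr, stim_onsets = 60, frame_rate = fr,
                       polarity = -1)
  expect_equal(dim(tt$values), c(2, 1, 130 * fr))
  expect_true(all(abs(tt$values[1, 1, ]) < 1e-12))      # constant -> 0
  post <- tt$time >= 5
  expect_true(all(abs(tt$values[2, 1, post] + 0.10) < 1e-12))
  resp <- tensor_response(tt)
  expect_true(all(abs(resp[2, 1, post] - 0.10) < 1e-12)) # increment +
})

test_that("trials without full windows are dropped and logged", {
  fr <- 10
  tr <- matrix(rnorm(2500, 100), 1, 2500)   # 250 s recording
  tt <- trigger_trials(tr, stim_onsets = c(5, 60), frame_rate = fr)
  expect_equal(tt$dropped_trials, 0)        # onset 5 s lacks history
  expect_equal(dim(tt$values)[2], 1)
  expect_error(trigger_trials(tr, stim_onsets = 5, frame_rate = fr),
               "no trial")
})

test_that("pre-window mean of every trial is zero by construction", {
  b <- generate_session(tiny_config(), seed = 21)
  tt <- trigger_trials(b)
  pre <- tt$time < 0
  for (i in seq_len(dim(tt$values)[1]))
    for (j in seq_len(dim(tt$values)[2]))
      expect_lt(abs(mean(tt$values[i, j, pre])), 1e-10)
})

test_that("photometry demux is robust and filters at 10 Hz", {
  # median robustness: one outlier inside a pulse does not move it
  cfg <- tiny_config(noise_sd = 0, bleach_tau = Inf)
  raw <- generate_photometry_raw(cfg, seed = 1, duration_s = 2,
                                 sample_rate = 1000, signal = 1 / 1000)
  raw$trace[3] <- 1e6    # spike inside the first pulse
  dm <- demux_photometry(raw)
  expect_lt(abs(dm$demuxed[1] - 1), 1e-9)
  # 20 Hz sinusoid attenuated > 10x by the 10 Hz low-pass at 50 Hz fs
  t50 <- seq(0, 20, by = 1 / 50)
  x <- sin(2 * pi * 20 * t50)
  y <- lowpass_zerophase(x, 10, 50)
  mid <- seq(100, length(y) - 100)
  expect_lt(max(abs(y[mid])) / 1, 0.1)
  # degenerate variance -> zeros with flag
  raw2 <- generate_photometry_raw(cfg, seed = 1, duration_s = 400,
                                  sample_rate = 200, signal = 1 / 1000)
  dm2 <- demux_photometry(raw2)
  expect_true(dm2$flag_zero_variance)
  expect_true(all(dm2$z == 0))
  # empty pulse list -> empty output
  dm3 <- demux_photometry(raw$trace, pulse_times = numeric(),
                          sample_rate = 1000)
  expect_length(dm3$z, 0)
})

test_that("demux recovers the generator bleach constant within 5%", {
  cfg <- tiny_config(noise_sd = 0.001, bleach_tau = 300)
  raw <- generate_photometry_raw(cfg, seed = 6, duration_s = 500,
                                 sample_rate = 500)
  dm <- demux_photometry(raw, baseline_seconds = 240)
  expect_equal(dm$bleach$method, "exponential")
  expect_lt(abs(dm$bleach$tau - 300) / 300, 0.05)
})
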