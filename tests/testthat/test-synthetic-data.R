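test_that("presets carry the anchored release probabilities", {
  expect_equal(make_preset("pomc_fasted")$release_prob, 0.15)
  expect_equal(make_preset("pomc_fed")$release_prob, 0.15)
  expect_equal(make_preset("agrp_fasted")$release_prob, 0.25)
  expect_equal(make_preset("null_no_stim")$release_prob, 0)
  expect_equal(make_preset("npylight_slice")$magnification, 1)
  expect_lt(make_preset("agrp_fasted")$event_sign, 0)
  expect_error(make_preset("nonsense"), "valid presets")
})

test_that("config invariants are enforced", {
  expect_error(generator_config(release_prob = 1.2), "release_prob")
  expect_error(generator_config(tau_rise = 5, tau_decay = 3), "tau_decay")
  expect_error(generator_config(frame_rate = 0), "frame_rate")
  expect_error(generator_config(plume_fwhm = -1), "plume_fwhm")
  expect_error(generator_config(noise_sd = NaN), "non-finite")
})

test_that("generation is deterministic for identical (config, seed)", {
  cfg <- tiny_config()
  a <- generate_session(cfg, seed = 11)
  b <- generate_session(cfg, seed = 11)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- generate_session(cfg, seed = 12)
  expect_false(identical(a$traces, c$traces))
})

test_that("adding ROIs does not perturb the event draws", {
  cfg1 <- tiny_config(n_somas = 8)
  cfg2 <- tiny_config(n_somas = 8, n_neurites_per_soma = 2)
  e1 <- generate_session(cfg1, seed = 5)$events
  e2 <- generate_session(cfg2, seed = 5)$events
  expect_equal(e1$trial_index, e2$trial_index)
  expect_equal(e1$site_id, e2$site_id)
  expect_equal(e1$amplitude_scale, e2$amplitude_scale)
})

test_that("zero release probability yields an event-free session", {
  b <- generate_session(make_preset("null_no_stim", n_somas = 6,
                                    n_neurites_per_soma = 0), seed = 3)
  expect_equal(nrow(b$events), 0)
})

test_that("saturating config: every ROI responds on every trial", {
  cfg <- tiny_config(release_prob = 1, plume_fwhm = 1e5, noise_sd = 0,
                     bleach_tau = Inf)
  b <- generate_session(cfg, seed = 2)
  expect_true(all(truth_matrix(b)))
  tt <- trigger_trials(b)
  resp <- tensor_response(tt)
  # peak response in every trial well above zero
  pk <- apply(resp, c(1, 2), max)
  expect_true(all(pk > 0.1))
})

test_that("event fraction matches the binomial law (3 SD)", {
  cfg <- isolated_config("pomc_fasted", n_somas = 500, noise_sd = 0)
  b <- generate_session(cfg, seed = 17)
  n <- 500 * 10
  frac <- nrow(b$events) / n
  expect_lt(abs(frac - 0.15), 3 * sqrt(0.15 * 0.85 / n))
})

test_that("noise-free, bleach-free traces equal the kinetic template", {
  cfg <- tiny_config(n_somas = 1, n_release_sites = 1, n_trials = 1,
                     site_placement = "per_soma", release_prob = 1,
                     amp_cv = 0, noise_sd = 0, bleach_tau = Inf,
                     facilitation = 1)
  b <- generate_session(cfg, seed = 9)
  tt <- trigger_trials(b)
  resp <- tensor_response(tt, 1, 1)
  t0 <- cfg$stim_duration
  expected <- kinetic_template(tt$time - t0, cfg$tau_rise, cfg$tau_decay,
                               amp = cfg$amp_mean)
  expect_equal(resp, expected, tolerance = 1e-10)
})

test_that("plume weight is a half-max-truncated Gaussian", {
  expect_equal(plume_weight(0, 100), 1)
  expect_equal(plume_weight(50, 100), 0.5)
  expect_equal(plume_weight(50.01, 100), 0)
  expect_equal(plume_weight(25, 100), 2^(-1/4), tolerance = 1e-12)
})

test_that("FLIM stack conserves photons and flags QC", {
  cfg <- tiny_config(release_prob = 0)
  st <- generate_flim_stack(cfg, lifetime_baseline = 2.5,
                            lifetime_delta = 0, seed = 4, n_frames = 2,
                            img_size = c(16, 16), photons_per_pixel = 20)
  for (f in st$counts) {
    expect_true(all(f >= 0))
    expect_equal(sum(f), sum(apply(f, c(1, 2), sum)))
  }
  expect_true(all(st$qc_pass))  # 20 photons/px at 2 um pitch >> 1e6/mm^2
  low <- generate_flim_stack(cfg, 2.5, 0, seed = 4, n_frames = 1,
                             img_size = c(16, 16),
                             photons_per_pixel = 2, pixel_size_um = 10)
  expect_false(any(low$qc_pass))
  expect_error(generate_flim_stack(cfg, 20, 0, seed = 1),
               "exceeds histogram span")
})

test_that("FLIM photon arrival times follow the truncated exponential", {
  cfg <- tiny_config(release_prob = 0)
  st <- generate_flim_stack(cfg, lifetime_baseline = 2.5,
                            lifetime_delta = 0, seed = 8, n_frames = 1,
                            img_size = c(32, 32), photons_per_pixel = 100)
  h <- apply(st$counts[[1]], 3, sum)
  est <- first_moment(h, t_ref = 0)
  span <- 256 * 48.86 / 1000
  expect_equal(est, truncated_exp_mean(2.5, span), tolerance = 0.01)
})

test_that("photometry raw trace has the pulse structure", {
  cfg <- tiny_config(noise_sd = 0, bleach_tau = Inf)
  raw <- generate_photometry_raw(cfg, seed = 2, duration_s = 2,
                                 sample_rate = 1000, signal = 2 / 1000)
  expect_equal(length(raw$pulse_times), 100)  # 50 Hz for 2 s
  # constant true signal of 2.0 -> every pulse median is 2.0
  dm <- demux_photometry(raw)
  expect_true(all(abs(dm$demuxed - 2) < 1e-12))
})
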