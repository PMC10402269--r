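test_that("first moment handles canonical histograms", {
  h <- numeric(256); h[40] <- 123
  expect_equal(first_moment(h), 0)              # delta at the reference
  expect_true(is.na(first_moment(numeric(256))))
  expect_error(first_moment(c(-1, rep(0, 255))), "negative")
})

test_that("first moment matches the truncated-exponential closed form", {
  h <- expected_exp_histogram(2.5, total = 1e5)
  span <- 256 * 48.86 / 1000
  truth <- truncated_exp_mean(2.5, span)
  expect_equal(truth, 2.416, tolerance = 1e-3)
  est <- first_moment(h, t_ref = 0)
  expect_lt(abs(est - truth) / truth, 0.01)
  # scale invariance
  expect_equal(first_moment(2 * h, t_ref = 0), est)
})

test_that("binned lifetime image applies the 5-photon exclusion", {
  counts <- array(0L, dim = c(11, 11, 256))
  counts[6, 6, 10] <- 4L                       # isolated 4-photon pixel
  fr <- binned_lifetime_image(counts, pixel_size_um = 1)
  expect_true(fr$excluded[6, 6])
  expect_true(all(is.na(fr$lifetime)))
  counts[6, 6, 10] <- 5L
  fr2 <- binned_lifetime_image(counts, pixel_size_um = 1)
  expect_false(fr2$excluded[6, 6])
  expect_equal(fr2$lifetime[6, 6], 0)          # single bin -> zero
})

test_that("uniform one-photon field: binned peak 25 includes interior", {
  counts <- array(0L, dim = c(15, 15, 256))
  counts[, , 3] <- 1L
  fr <- binned_lifetime_image(counts, pixel_size_um = 1)
  interior <- fr$excluded[3:13, 3:13]
  expect_false(any(interior))
  expect_lt(max(abs(fr$lifetime[3:13, 3:13])), 1e-9)
  expect_equal(fr$binned_photons[8, 8], 25)
  # photon conservation in the unbinned image
  expect_equal(sum(fr$photons), sum(counts))
})

test_that("spatial binning equals a direct neighborhood sum", {
  set.seed(7)
  m <- matrix(rpois(9 * 8, 3), 9, 8)
  counts <- array(0L, dim = c(9, 8, 256))
  counts[, , 1] <- m
  fr <- binned_lifetime_image(counts, pixel_size_um = 1,
                              min_peak_photons = 0)
  naive <- matrix(0, 9, 8)
  for (i in 1:9) for (j in 1:8) {
    naive[i, j] <- sum(m[max(1, i - 2):min(9, i + 2),
                         max(1, j - 2):min(8, j + 2)])
  }
  expect_equal(fr$binned_photons, naive)
})

test_that("two-region frame recovers both lifetimes within 0.05 ns", {
  set.seed(11)
  nr <- 30; nc <- 30
  tau <- matrix(2.0, nr, nc); tau[, 16:30] <- 2.6
  w <- 48.86 / 1000; span <- 256 * w
  counts <- array(0L, dim = c(nr, nc, 256))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    n <- rpois(1, 20)
    if (n == 0) next
    u <- runif(n)
    tt <- -tau[i, j] * log(1 - u * (1 - exp(-span / tau[i, j])))
    counts[i, j, ] <- tabulate(pmin(floor(tt / w), 255) + 1, 256)
  }
  fr <- binned_lifetime_image(counts, pixel_size_um = 1, t_ref = 0)
  est_a <- mean(fr$lifetime[, 3:13], na.rm = TRUE)
  est_b <- mean(fr$lifetime[, 19:29], na.rm = TRUE)
  expect_lt(abs(est_a - truncated_exp_mean(2.0, span)), 0.05)
  expect_lt(abs(est_b - truncated_exp_mean(2.6, span)), 0.05)
})

test_that("ROI lifetime traces: neuropil cancellation and step recovery", {
  cfg <- tiny_config(release_prob = 0)
  mk_frame <- function(tau, seed) {
    set.seed(seed)
    nr <- 32; nc <- 32
    w <- 48.86 / 1000; span <- 256 * w
    counts <- array(0L, dim = c(nr, nc, 256))
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      n <- rpois(1, 60)
      u <- runif(n)
      tt <- -tau * log(1 - u * (1 - exp(-span / tau)))
      counts[i, j, ] <- tabulate(pmin(floor(tt / w), 255) + 1, 256)
    }
    binned_lifetime_image(counts, pixel_size_um = 1, t_ref = 0)
  }
  roi <- matrix(FALSE, 32, 32); roi[10:25, 10:25] <- TRUE
  ring <- matrix(FALSE, 32, 32); ring[4:31, 4:31] <- TRUE
  ring <- ring & !roi
  # frames 1-3 baseline 2.5 ns, frames 4-6 stepped down 0.15 ns
  frames <- c(lapply(1:3, function(s) mk_frame(2.5, s)),
              lapply(4:6, function(s) mk_frame(2.35, s)))
  tr <- roi_lifetime_trace(frames, list(r1 = roi), rings = list(r1 = ring),
                           baseline_frames = 1:3)
  # ring lifetime equals ROI lifetime -> correction introduces no bias
  expect_lt(abs(mean(tr$delta_lifetime[1:3, 1])), 0.02)
  step <- mean(tr$delta_lifetime[4:6, 1])
  expect_lt(abs(step - (-0.15)), 0.05)
  # baseline window delta is zero-mean by definition
  expect_equal(mean(tr$delta_lifetime[tr$baseline_frames, 1]), 0,
               tolerance = 1e-12)
})

test_that("generated FLIM event plumes shift the lifetime image", {
  cfg <- generator_config(n_somas = 4, n_release_sites = 2,
                          fov_size = c(96, 96), release_prob = 1,
                          plume_fwhm = 60)
  st <- generate_flim_stack(cfg, lifetime_baseline = 2.5,
                            lifetime_delta = -0.3, seed = 5,
                            n_frames = 2, img_size = c(48, 48),
                            pixel_size_um = 2, photons_per_pixel = 40)
  expect_gt(nrow(st$events), 0)
  fr <- binned_lifetime_image(st$counts[[1]], pixel_size_um = 2,
                              t_ref = 0)
  # pixels inside a plume should read a shorter lifetime
  ev <- st$events[st$events$trial_index == 0, ][1, ]
  px <- round(ev$site_x_um / 2); py <- round(ev$site_y_um / 2)
  px <- min(max(px, 3), 46); py <- min(max(py, 3), 46)
  inside <- fr$lifetime[py, px]
  corner <- mean(fr$lifetime[1:5, 1:5], na.rm = TRUE)
  if (!is.na(inside)) expect_lt(inside, corner)
})
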