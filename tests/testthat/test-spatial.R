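test_that("pair distance divides out the magnification", {
  a <- data.frame(centroid_x_um = 0, centroid_y_um = 0)
  b <- data.frame(centroid_x_um = 260, centroid_y_um = 0)
  expect_equal(pair_distance(a, a), 0)
  expect_equal(pair_distance(a, b, magnification = 2.6), 100)
  expect_equal(pair_distance(a, b, 2.6), pair_distance(b, a, 2.6))
  expect_equal(pair_distance(c(0, 0), c(3, 4), magnification = 1), 5)
})

test_that("similarity metrics match hand-enumerated truth tables", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  b <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(similarity(a, b, "xnor"), 0.5)
  expect_equal(similarity(a, b, "f1"), 0.5)    # TP=1, FP=1, FN=1
  expect_equal(similarity(a, a, "xnor"), 1)
  expect_equal(similarity(a, a, "f1"), 1)
  expect_equal(similarity(a, !a, "xnor"), 0)
  expect_equal(similarity(a, b, "xnor"), similarity(b, a, "xnor"))
  # all-miss pair: XNOR defined (1), F1 undefined
  z <- rep(FALSE, 4)
  expect_equal(similarity(z, z, "xnor"), 1)
  expect_true(is.na(similarity(z, z, "f1")))
  expect_error(similarity(a, b[1:3], "xnor"), "unequal")
})

test_that("XNOR expectation for independent Bernoulli sequences", {
  set.seed(5)
  for (p in c(0.1, 0.25, 0.5)) {
    sims <- replicate(20000, {
      similarity(runif(10) < p, runif(10) < p, "xnor")
    })
    expect_lt(abs(mean(sims) - (p^2 + (1 - p)^2)), 0.01)
  }
})

test_that("distance curve bins pairs and keeps empty bins", {
  rois <- data.frame(roi_id = 1:3, kind = "soma", parent_id = NA,
                     centroid_x_um = c(0, 10, 200), centroid_y_um = 0,
                     area_px = 100)
  ht <- data.frame(roi_id = rep(1:3, each = 4), trial = rep(0:3, 3),
                   auroc = 0.5,
                   label = rep(c("hit_increment", "miss", "miss", "miss"), 3),
                   peak_amplitude = 1)
  cv <- distance_curve(ht, rois, method = "xnor", bin_width = 20,
                       magnification = 1)
  expect_equal(cv$n_pairs[1], 1)            # the 10-um pair
  expect_true(any(cv$n_pairs == 0))         # intermediate bins retained
  expect_equal(cv$mean_similarity[1], 1)    # identical sequences
})

test_that("chance band covers independent data and excludes coupling", {
  set.seed(8)
  n_rois <- 60
  rois <- data.frame(roi_id = seq_len(n_rois), kind = "soma",
                     parent_id = NA,
                     centroid_x_um = runif(n_rois, 0, 300),
                     centroid_y_um = runif(n_rois, 0, 300),
                     area_px = 100)
  hits <- matrix(runif(n_rois * 10) < 0.25, n_rois, 10)
  # perfectly coupled close pair
  rois$centroid_x_um[2] <- rois$centroid_x_um[1] + 1
  rois$centroid_y_um[2] <- rois$centroid_y_um[1]
  hits[2, ] <- hits[1, ] <- c(rep(TRUE, 5), rep(FALSE, 5))
  ht <- data.frame(roi_id = rep(seq_len(n_rois), each = 10),
                   trial = rep(0:9, n_rois), auroc = 0.5,
                   label = ifelse(t(hits)[seq_len(n_rois * 10)],
                                  "hit_increment", "miss"),
                   peak_amplitude = 0)
  ht$label <- ifelse(as.vector(t(hits)), "hit_increment", "miss")
  cv <- distance_curve(ht, rois, method = "xnor", bin_width = 50,
                       magnification = 1)
  cv <- chance_band(cv, n_shuffle = 300, seed = 2)
  pop <- which(cv$n_pairs > 5)
  inside <- cv$mean_similarity[pop] <= cv$chance_hi[pop] + 1e-12
  # independent bins are mostly at or below the upper band edge
  expect_gte(mean(inside[-1]), 0.8)
  # the coupled pair's bin (first) sits above the band
  expect_gt(cv$mean_similarity[1], cv$chance_hi[1])
})

test_that("single-shuffle band is degenerate", {
  rois <- data.frame(roi_id = 1:4, kind = "soma", parent_id = NA,
                     centroid_x_um = c(0, 5, 10, 15), centroid_y_um = 0,
                     area_px = 1)
  ht <- data.frame(roi_id = rep(1:4, each = 5), trial = rep(0:4, 4),
                   auroc = 0.5,
                   label = sample(c("hit_increment", "miss"), 20, TRUE),
                   peak_amplitude = 0)
  cv <- distance_curve(ht, rois, method = "xnor", bin_width = 20,
                       magnification = 1)
  cv1 <- chance_band(cv, n_shuffle = 1, seed = 3)
  expect_equal(cv1$chance_lo, cv1$chance_hi)
})

test_that("estimated spatial scale is monotone in the plume FWHM", {
  scale_for <- function(fwhm, seed) {
    cfg <- make_preset("pomc_fasted", n_somas = 200,
                       n_neurites_per_soma = 0, fov_size = c(600, 600),
                       plume_fwhm = fwhm,
                       n_release_sites = round(600^2 / (pi * (fwhm / 2)^2)))
    b <- generate_session(cfg, seed = seed)
    ht_true <- truth_table_from(b)
    cv <- distance_curve(ht_true, b$rois, method = "xnor",
                         bin_width = 20, magnification = 2.6)
    cv <- chance_band(cv, n_shuffle = 300, seed = seed)
    spatial_scale(cv)$scale_um
  }
  truth_table_from <- function(b) {
    tm <- truth_matrix(b)
    data.frame(roi_id = rep(b$rois$roi_id, each = ncol(tm)),
               trial = rep(seq_len(ncol(tm)) - 1, nrow(tm)),
               auroc = ifelse(as.vector(t(tm)), 1, 0.5),
               label = ifelse(as.vector(t(tm)), "hit_increment", "miss"),
               peak_amplitude = 0)
  }
  s50 <- scale_for(50, 2)
  s100 <- scale_for(100, 2)
  s200 <- scale_for(200, 2)
  expect_lt(s50, s200)
  expect_lte(s50, s100)
  expect_lte(s100, s200)
  expect_lt(abs(s100 - 100), 40)
})

test_that("neurite responses split by parent soma outcome", {
  cfg <- make_preset("pomc_fasted", n_somas = 20,
                     n_neurites_per_soma = 1, noise_sd = 0.02)
  b <- generate_session(cfg, seed = 44)
  tt <- trigger_trials(b)
  ht <- classify_session(tt)
  ns <- neurite_by_soma_outcome(tt, ht, "increment")
  expect_equal(ns$n_soma_hit + ns$n_soma_miss, 20 * 10)
  # neurites sit ~30 um from their soma, inside the same plume:
  # soma-hit trials should carry a larger neurite response
  post <- ns$time >= 10 & ns$time < 40
  if (ns$n_soma_hit > 5)
    expect_gt(mean(ns$soma_hit[post]), mean(ns$soma_miss[post]))
})
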