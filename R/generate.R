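#' Gaussian plume weight with half-maximum support
#'
#' Spatial impact kernel of a single release event: an isotropic Gaussian
#' of the configured FWHM, truncated at its half-maximum radius. The
#' truncation encodes the working definition of the event's impact
#' region as a disc whose diameter equals the plume FWHM (~100 um for
#' the release events modeled here): ROIs inside the disc receive a
#' transient scaled by the Gaussian weight (between 1 and 0.5), ROIs
#' outside receive nothing.
#'
#' @param d distance from the release site, um.
#' @param fwhm plume full width at half maximum, um.
#' @return Weight in `{0} U [0.5, 1]`.
#' @export
plume_weight <- function(d, fwhm) {
  w <- exp(-4 * log(2) * (d / fwhm)^2)
  w[d > fwhm / 2] <- 0
  w
}

#' Closed-form transient kinetic template
#'
#' `A * (1 - exp(-t/tau_rise)) * ((1 - c) * exp(-t/tau_decay) +
#' c * exp(-t/tau_sustain))` for `t >= 0`, zero before; time is
#' measured from the transient onset (end of the stimulation train).
#' With `sustained_frac = c = 0` this is the basic
#' rise-times-exponential-decay transient. A nonzero `c` adds a
#' sustained component: with the default `tau_sustain = Inf` the
#' transient decays to a plateau of height `c * A`, the shape used for
#' the persistent (efficacious-state) presets, whose durations are
#' right-censored at the session length.
#'
#' @param t time from transient onset, s.
#' @param tau_rise,tau_decay kinetic constants, s.
#' @param amp peak scale `A`.
#' @param sustained_frac fraction `c` of the amplitude that persists.
#' @param tau_sustain decay constant of the sustained component
#'   (default `Inf`: a flat plateau).
#' @return Numeric vector of template values.
#' @export
kinetic_template <- function(t, tau_rise, tau_decay, amp = 1,
                             sustained_frac = 0, tau_sustain = Inf) {
  slow <- if (is.finite(tau_sustain)) exp(-t / tau_sustain) else 1
  y <- amp * (1 - exp(-t / tau_rise)) *
    ((1 - sustained_frac) * exp(-t / tau_decay) + sustained_frac * slow)
  y[t < 0] <- 0
  y
}

# Log-normal with mean 1 and the requested coefficient of variation.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# Independent RNG substreams so that, e.g., adding ROIs changes the
# noise draws but never the event draws.
seed_geometry <- function(seed) set.seed(seed %% .Machine$integer.max)
seed_events   <- function(seed) set.seed((seed + 1000003L) %% .Machine$integer.max)
seed_noise    <- function(seed) set.seed((seed + 2000033L) %% .Machine$integer.max)

#' Generate a synthetic imaging session with ground-truth events
#'
#' Simulates one recording: soma (and optional neurite) ROIs placed in
#' the field of view, point release sites that fire independently on
#' each stimulation trial with probability `release_prob`, and raw
#' fluorescence traces in which each firing site adds, to every ROI
#' inside its plume, a transient `A*(1-exp(-t/tau_r))*exp(-t/tau_d)`
#' starting at the stimulation-train offset. Traces are polarity-signed
#' (for cADDis-like sensors a cAMP increment is a fluorescence dip),
#' scaled by the baseline fluorescence, multiplied by a mono-exponential
#' bleaching envelope and corrupted by i.i.d. Gaussian noise. The
#' returned bundle carries the ground-truth event log, which the
#' analysis never sees in real data but which recovery tests compare
#' against.
#'
#' Identical `(config, seed)` pairs give bit-identical output.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; overrides `config$seed`.
#' @return A `session_bundle`: list with `meta`, `rois` (data frame),
#'   `traces` (ROI x frame matrix of raw fluorescence), `time` (s),
#'   and `events` (ground-truth data frame, possibly 0-row).
#' @export
generate_session <- function(config, seed = config$seed) {
  validate_config(config)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  cfg <- config

  # --- geometry -------------------------------------------------------
  seed_geometry(seed)
  soma_x <- runif(cfg$n_somas, 0, cfg$fov_size[1])
  soma_y <- runif(cfg$n_somas, 0, cfg$fov_size[2])
  rois <- data.frame(
    roi_id = seq_len(cfg$n_somas),
    kind = "soma",
    parent_id = NA_integer_,
    centroid_x_um = soma_x,
    centroid_y_um = soma_y,
    area_px = 1800L,
    stringsAsFactors = FALSE
  )
  if (cfg$n_neurites_per_soma > 0) {
    nn <- cfg$n_somas * cfg$n_neurites_per_soma
    ang <- runif(nn, 0, 2 * pi)
    parent <- rep(seq_len(cfg$n_somas), each = cfg$n_neurites_per_soma)
    neur <- data.frame(
      roi_id = cfg$n_somas + seq_len(nn),
      kind = "neurite",
      parent_id = parent,
      centroid_x_um = pmin(pmax(soma_x[parent] +
        cfg$neurite_offset_um * cos(ang), 0), cfg$fov_size[1]),
      centroid_y_um = pmin(pmax(soma_y[parent] +
        cfg$neurite_offset_um * sin(ang), 0), cfg$fov_size[2]),
      area_px = 400L,
      stringsAsFactors = FALSE
    )
    rois <- rbind(rois, neur)
  }
  if (cfg$site_placement == "per_soma") {
    site_x <- soma_x; site_y <- soma_y
  } else {
    site_x <- runif(cfg$n_release_sites, 0, cfg$fov_size[1])
    site_y <- runif(cfg$n_release_sites, 0, cfg$fov_size[2])
  }
  n_sites <- length(site_x)

  # --- events (own substream, drawn in fixed site-major order) --------
  seed_events(seed)
  fired <- matrix(rbinom(n_sites * cfg$n_trials, 1, cfg$release_prob) == 1,
                  nrow = n_sites, ncol = cfg$n_trials)
  amp_scale <- matrix(rlnorm_cv(n_sites * cfg$n_trials, cfg$amp_cv),
                      nrow = n_sites, ncol = cfg$n_trials)

  # --- time base ------------------------------------------------------
  onsets <- cfg$first_onset_s +
    (seq_len(cfg$n_trials) - 1) * cfg$inter_trial_interval
  total_s <- max(onsets) + 120
  n_frames <- ceiling(total_s * cfg$frame_rate)
  time <- (seq_len(n_frames) - 1) / cfg$frame_rate

  # --- responses ------------------------------------------------------
  n_rois <- nrow(rois)
  resp <- matrix(0, n_rois, n_frames)  # polarity-free response, dF/F0 units
  ev_list <- list()
  for (s in seq_len(n_sites)) {
    d <- sqrt((rois$centroid_x_um - site_x[s])^2 +
              (rois$centroid_y_um - site_y[s])^2)
    w <- plume_weight(d, cfg$plume_fwhm)
    hit_rois <- which(w > 0)
    for (k in seq_len(cfg$n_trials)) {
      if (!fired[s, k]) next
      facil <- if (k > 1 && fired[s, k - 1]) cfg$facilitation else 1
      t0 <- onsets[k] + cfg$stim_duration
      tpl <- kinetic_template(time - t0, cfg$tau_rise, cfg$tau_decay,
                              amp = cfg$amp_mean * amp_scale[s, k] * facil,
                              sustained_frac = cfg$sustained_frac,
                              tau_sustain = cfg$tau_sustain)
      for (r in hit_rois) resp[r, ] <- resp[r, ] + w[r] * tpl
      ev_list[[length(ev_list) + 1]] <- data.frame(
        trial_index = k - 1L,
        site_id = s,
        site_x_um = site_x[s],
        site_y_um = site_y[s],
        amplitude_scale = amp_scale[s, k] * facil,
        affected_roi_ids = paste(rois$roi_id[hit_rois], collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(trial_index = integer(), site_id = integer(),
               site_x_um = numeric(), site_y_um = numeric(),
               amplitude_scale = numeric(),
               affected_roi_ids = character(),
               stringsAsFactors = FALSE)

  # --- raw fluorescence ----------------------------------------------
  env <- if (is.finite(cfg$bleach_tau)) exp(-time / cfg$bleach_tau) else
    rep(1, n_frames)
  traces <- cfg$baseline_f0 *
    sweep(1 + cfg$polarity * cfg$event_sign * resp, 2, env, `*`)
  if (cfg$noise_sd > 0) {
    seed_noise(seed)
    traces <- traces + cfg$baseline_f0 * cfg$noise_sd *
      matrix(rnorm(n_rois * n_frames), n_rois, n_frames)
  }
  rownames(traces) <- rois$roi_id

  # ROI centroids are stored in image-plane um (specimen um times the
  # optical magnification), as a real acquisition would; pair_distance()
  # divides the magnification back out.
  rois$centroid_x_um <- rois$centroid_x_um * cfg$magnification
  rois$centroid_y_um <- rois$centroid_y_um * cfg$magnification

  bundle <- list(
    meta = list(
      frame_rate = cfg$frame_rate,
      stim_onsets_s = onsets,
      stim_duration_s = cfg$stim_duration,
      polarity = cfg$polarity,
      event_sign = cfg$event_sign,
      magnification = cfg$magnification,
      sensor = cfg$sensor,
      state = cfg$state,
      units = list(time = "s", distance = "um_image_plane",
                   traces = "raw_fluorescence_au"),
      schema_version = "1.0",
      preset = attr(config, "preset") %||% NA_character_,
      seed = as.integer(seed)
    ),
    rois = rois,
    traces = traces,
    time = time,
    events = events
  )
  class(bundle) <- "session_bundle"
  bundle
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> %d ROIs x %d frames @ %.3g Hz, %d trials, %d events\n",
              nrow(x$rois), ncol(x$traces), x$meta$frame_rate,
              length(x$meta$stim_onsets_s),
              nrow(x$events %||% data.frame())))
  invisible(x)
}

#' Generate a synthetic FLIM photon-histogram stack
#'
#' Produces per-pixel photon decay histograms (256 bins) for a series of
#' frames. Photon counts per pixel are Poisson around a uniform mean
#' intensity; per-photon arrival times follow an exponential with the
#' baseline lifetime, truncated at the histogram span, and are
#' discretized into bins. Each frame is treated as one trial: every
#' release site fires with `config$release_prob`, and pixels inside a
#' firing site's plume have their lifetime shifted by `lifetime_delta`
#' for that frame. A QC flag marks frames whose photon density falls
#' below the 1e6 photons/mm^2 criterion.
#'
#' @param config a [generator_config()]; `fov_size`, `release_prob`,
#'   `plume_fwhm` and `site_placement` are used.
#' @param lifetime_baseline ns, baseline fluorescence lifetime.
#' @param lifetime_delta ns, lifetime shift inside event plumes.
#' @param seed integer seed.
#' @param n_frames number of FLIM frames (trials).
#' @param img_size pixels, length-2 (rows, cols).
#' @param pixel_size_um um per pixel (specimen plane).
#' @param photons_per_pixel mean photons per pixel per frame.
#' @param bin_width_ps histogram bin width, ps (48.86 ps for the 80 MHz
#'   system modeled: 256 bins span 12.51 ns).
#' @return A `flim_stack`: list with `counts` (list of
#'   `[rows x cols x 256]` integer arrays), `bin_width_ps`, `times_s`,
#'   `pixel_size_um`, `qc_pass` (per frame), `lifetime_baseline`,
#'   `events` (ground truth).
#' @export
generate_flim_stack <- function(config, lifetime_baseline, lifetime_delta,
                                seed = config$seed, n_frames = 6,
                                img_size = c(48, 48), pixel_size_um = 2,
                                photons_per_pixel = 20,
                                bin_width_ps = 48.86) {
  validate_config(config)
  span_ns <- 256 * bin_width_ps / 1000
  if (lifetime_baseline <= 0) stop("lifetime_baseline must be > 0",
                                   call. = FALSE)
  if (lifetime_baseline >= span_ns || abs(lifetime_delta) >= span_ns)
    stop(sprintf("lifetime exceeds histogram span (%.2f ns)", span_ns),
         call. = FALSE)
  if (lifetime_baseline + lifetime_delta <= 0)
    stop("baseline + delta lifetime must be > 0", call. = FALSE)

  seed_geometry(seed)
  if (config$site_placement == "per_soma") {
    # sites reproduce the session generator's soma positions
    site_x <- runif(config$n_somas, 0, config$fov_size[1])
    site_y <- runif(config$n_somas, 0, config$fov_size[2])
  } else {
    site_x <- runif(config$n_release_sites, 0, config$fov_size[1])
    site_y <- runif(config$n_release_sites, 0, config$fov_size[2])
  }
  n_sites <- length(site_x)

  seed_events(seed)
  fired <- matrix(rbinom(n_sites * n_frames, 1, config$release_prob) == 1,
                  nrow = n_sites, ncol = n_frames)

  # pixel grid in specimen um
  px_x <- (seq_len(img_size[2]) - 0.5) * pixel_size_um
  px_y <- (seq_len(img_size[1]) - 0.5) * pixel_size_um
  gx <- matrix(px_x, img_size[1], img_size[2], byrow = TRUE)
  gy <- matrix(px_y, img_size[1], img_size[2])

  seed_noise(seed)
  frames <- vector("list", n_frames)
  qc <- logical(n_frames)
  ev_list <- list()
  for (f in seq_len(n_frames)) {
    tau <- matrix(lifetime_baseline, img_size[1], img_size[2])
    for (s in which(fired[, f])) {
      d <- sqrt((gx - site_x[s])^2 + (gy - site_y[s])^2)
      inside <- d <= config$plume_fwhm / 2
      tau[inside] <- lifetime_baseline + lifetime_delta
      ev_list[[length(ev_list) + 1]] <- data.frame(
        trial_index = f - 1L, site_id = s,
        site_x_um = site_x[s], site_y_um = site_y[s],
        n_pixels = sum(inside), stringsAsFactors = FALSE)
    }
    n_ph <- matrix(rpois(prod(img_size), photons_per_pixel),
                   img_size[1], img_size[2])
    counts <- array(0L, dim = c(img_size[1], img_size[2], 256))
    total <- sum(n_ph)
    if (total > 0) {
      pix <- rep.int(seq_len(prod(img_size)), as.vector(n_ph))
      tau_ph <- as.vector(tau)[pix]
      u <- runif(total)
      # inverse CDF of the exponential truncated at the histogram span
      t_ph <- -tau_ph * log(1 - u * (1 - exp(-span_ns / tau_ph)))
      bin <- pmin(floor(t_ph / (bin_width_ps / 1000)), 255)
      lin <- bin * prod(img_size) + (pix - 1L) + 1L
      acc <- tabulate(lin, nbins = prod(img_size) * 256L)
      counts <- array(as.integer(acc), dim = c(img_size[1], img_size[2], 256))
    }
    frames[[f]] <- counts
    area_mm2 <- prod(img_size) * (pixel_size_um^2) * 1e-6
    qc[f] <- total / area_mm2 >= 1e6
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(trial_index = integer(), site_id = integer(),
               site_x_um = numeric(), site_y_um = numeric(),
               n_pixels = integer(), stringsAsFactors = FALSE)
  stack <- list(counts = frames, bin_width_ps = bin_width_ps,
                times_s = (seq_len(n_frames) - 1) * 10,
                pixel_size_um = pixel_size_um, qc_pass = qc,
                lifetime_baseline = lifetime_baseline,
                lifetime_delta = lifetime_delta,
                events = events)
  class(stack) <- "flim_stack"
  stack
}

#' Generate a raw interleaved-LED photometry trace
#'
#' Emulates a time-division-multiplexed photometry acquisition: the
#' excitation LED is on for 6 ms out of every 20 ms cycle (50 Hz). The
#' photodetector samples at `sample_rate`; during LED-on epochs it sees
#' the bleached fluorescence signal plus noise, otherwise only the dark
#' level plus noise.
#'
#' @param config a [generator_config()]; `baseline_f0`, `bleach_tau`
#'   and `noise_sd` are used.
#' @param seed integer seed.
#' @param duration_s recording length, s.
#' @param sample_rate detector sampling rate, Hz.
#' @param pulse_rate_hz LED cycle rate (default 50).
#' @param pulse_width_s LED-on duration per cycle (default 6 ms).
#' @param dark_level detector output when the LED is off.
#' @param signal signal time course in units of `baseline_f0` (function
#'   of time in s, or a constant; default constant 1).
#' @return List with `trace`, `time`, `pulse_times` (LED-on onsets, s),
#'   `sample_rate`, `pulse_width_s`.
#' @export
generate_photometry_raw <- function(config, seed = config$seed,
                                    duration_s = 600, sample_rate = 1000,
                                    pulse_rate_hz = 50,
                                    pulse_width_s = 0.006,
                                    dark_level = 0, signal = 1) {
  validate_config(config)
  n <- round(duration_s * sample_rate)
  cyc <- sample_rate / pulse_rate_hz
  if (abs(cyc - round(cyc)) > 1e-9)
    stop("sample_rate must be an integer multiple of pulse_rate_hz",
         call. = FALSE)
  time <- (seq_len(n) - 1) / sample_rate
  pulse_times <- (seq_len(floor(duration_s * pulse_rate_hz)) - 1) /
    pulse_rate_hz
  sig_fun <- if (is.function(signal)) signal else function(t) rep(signal, length(t))
  env <- if (is.finite(config$bleach_tau)) exp(-time / config$bleach_tau) else
    rep(1, n)
  on <- ((seq_len(n) - 1) %% round(cyc)) <
    pulse_width_s * sample_rate - 1e-9
  trace <- rep(dark_level, n)
  trace[on] <- config$baseline_f0 * sig_fun(time[on]) * env[on]
  if (config$noise_sd > 0) {
    seed_noise(seed)
    trace <- trace + config$baseline_f0 * config$noise_sd * rnorm(n)
  }
  list(trace = trace, time = time, pulse_times = pulse_times,
       sample_rate = sample_rate, pulse_width_s = pulse_width_s)
}
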