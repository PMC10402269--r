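#' Build a neuropil ring around an ROI
#'
#' Dilates the ROI mask and removes every ROI mask from the dilated
#' region, yielding an annulus of background ("neuropil") pixels. The
#' dilation starts at 14 px; if the resulting ring has fewer than 2500
#' pixels the dilation radius is incremented by 1 px until the ring is
#' large enough or the cap (40 px) is reached, in which case the ring is
#' returned with a warning flag rather than an error. Dilation is
#' implemented with a Euclidean distance transform, so a dilation of
#' `d` px selects exactly the pixels within distance `d` of the ROI.
#'
#' @param roi_id id of the ROI the ring surrounds (index into
#'   `all_masks`).
#' @param all_masks named list of logical matrices, one per ROI, all of
#'   dimension `field_shape`.
#' @param field_shape integer length-2, the image dimensions.
#' @param start_dilation_px initial dilation radius (default 14).
#' @param min_area_px minimum ring area (default 2500).
#' @param max_dilation_px dilation cap (default 40).
#' @return A `neuropil_ring`: list with `roi_id`, `mask` (logical
#'   matrix), `dilation_used`, `ring_area`, `flag_small` (TRUE when the
#'   cap was reached before the area criterion).
#' @export
build_neuropil_ring <- function(roi_id, all_masks, field_shape,
                                start_dilation_px = 14,
                                min_area_px = 2500,
                                max_dilation_px = 40) {
  stopifnot(roi_id %in% seq_along(all_masks) ||
            as.character(roi_id) %in% names(all_masks))
  key <- if (as.character(roi_id) %in% names(all_masks))
    as.character(roi_id) else roi_id
  roi <- all_masks[[key]]
  stopifnot(identical(dim(roi), as.integer(field_shape)))
  any_roi <- Reduce(`|`, all_masks)
  if (!any(roi)) stop("ROI mask is empty", call. = FALSE)

  # distance from each pixel to the nearest ROI pixel
  dist_to_roi <- EBImage::distmap(!roi)
  dil <- start_dilation_px
  repeat {
    ring <- (dist_to_roi > 0) & (dist_to_roi <= dil) & !any_roi
    area <- sum(ring)
    if (area >= min_area_px || dil >= max_dilation_px) break
    dil <- dil + 1
  }
  structure(list(roi_id = roi_id, mask = ring, dilation_used = dil,
                 ring_area = area, flag_small = area < min_area_px),
            class = "neuropil_ring")
}

#' Subtract a neuropil ring trace from an ROI trace
#'
#' Elementwise subtraction at fixed 1:1 scaling: the neuropil photon
#' contribution at the ROI is assumed equal to that in the surrounding
#' annulus, so the ring's mean trace is removed without a fitted
#' coefficient.
#'
#' @param roi_trace,ring_trace numeric vectors of equal length.
#' @return Corrected trace.
#' @export
neuropil_subtract <- function(roi_trace, ring_trace) {
  if (length(roi_trace) != length(ring_trace))
    stop("roi_trace and ring_trace must have equal length", call. = FALSE)
  roi_trace - ring_trace
}

#' Fit and remove mono-exponential photobleaching
#'
#' Fits `a * exp(-t/tau) + c` to the baseline (pre-stimulation) portion
#' of the trace by nonlinear least squares and subtracts the
#' extrapolated fitted curve from every timepoint of the recording, so
#' the corrected trace fluctuates around zero. If the nonlinear fit
#' fails to converge a linear fit is used instead and flagged. The
#' fitted curve is returned as `fitted` for use as an F0 estimate.
#'
#' @param trace numeric vector.
#' @param time numeric vector of sample times, s.
#' @param baseline_seconds length of the baseline window from the start
#'   of the recording (default 240 s, i.e. 4 min).
#' @return List with `corrected`, `amplitude`, `tau`, `offset`,
#'   `method` (`"exponential"` or `"linear"`), `flag_fallback`.
#' @export
bleach_correct <- function(trace, time, baseline_seconds = 240) {
  stopifnot(length(trace) == length(time), baseline_seconds > 0)
  idx <- which(time < baseline_seconds)
  if (length(idx) < 10)
    stop("baseline window too short for a bleach fit", call. = FALSE)
  tb <- time[idx]; yb <- trace[idx]
  span <- diff(range(tb))
  a0 <- yb[1] - yb[length(yb)]
  if (abs(a0) < .Machine$double.eps) a0 <- sd(yb) + .Machine$double.eps
  resid_fn <- function(par) yb - (par[1] * exp(-tb / par[2]) + par[3])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(a = a0, tau = span / 2, c = min(yb)),
                       fn = resid_fn,
                       lower = c(-Inf, 1e-6, -Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit) && fit$info %in% 1:4) {
    p <- fit$par
    fitted <- p[["a"]] * exp(-time / p[["tau"]]) + p[["c"]]
    return(list(corrected = trace - fitted, fitted = fitted,
                amplitude = p[["a"]], tau = p[["tau"]],
                offset = p[["c"]], method = "exponential",
                flag_fallback = FALSE))
  }
  lf <- lm(yb ~ tb)
  fitted <- coef(lf)[[1]] + coef(lf)[[2]] * time
  list(corrected = trace - fitted, fitted = fitted,
       amplitude = coef(lf)[[2]], tau = NA_real_,
       offset = coef(lf)[[1]], method = "linear", flag_fallback = TRUE)
}

#' Align a session into a per-trial dF/F0 tensor
#'
#' Cuts each ROI trace into stimulation-aligned segments spanning
#' [-pre, +post) s around each onset and converts them to dF/F0 with F0
#' estimated as the mean of that trial's own pre-stimulation window
#' (the last `pre` seconds before the onset). Trials without a full
#' pre/post window inside the recording are dropped and listed in
#' `dropped_trials`.
#'
#' @param bundle a `session_bundle`, or a numeric matrix of traces
#'   (ROIs x frames) if `stim_onsets`/`frame_rate` are given.
#' @param stim_onsets,frame_rate,polarity used when `bundle` is a bare
#'   matrix.
#' @param pre,post window extents in s (defaults 20 and 110).
#' @return A `trial_tensor`: list with `values` (array
#'   `[n_rois, n_trials, n_samples]` of dF/F0), `time` (s relative to
#'   stimulation onset), `polarity`, `rois`, `meta`, `dropped_trials`.
#'   The polarity-corrected response (increments positive) is
#'   `polarity * values`; see [tensor_response()].
#' @export
trigger_trials <- function(bundle, stim_onsets = NULL, frame_rate = NULL,
                           polarity = NULL, pre = 20, post = 110) {
  if (inherits(bundle, "session_bundle")) {
    traces <- bundle$traces
    stim_onsets <- bundle$meta$stim_onsets_s
    frame_rate <- bundle$meta$frame_rate
    polarity <- bundle$meta$polarity
    rois <- bundle$rois
    meta <- bundle$meta
  } else {
    traces <- as.matrix(bundle)
    stopifnot(!is.null(stim_onsets), !is.null(frame_rate))
    polarity <- polarity %||% 1
    rois <- data.frame(roi_id = seq_len(nrow(traces)))
    meta <- list(frame_rate = frame_rate, stim_onsets_s = stim_onsets,
                 polarity = polarity)
  }
  n_frames <- ncol(traces)
  rec_time <- (seq_len(n_frames) - 1) / frame_rate
  n_pre <- round(pre * frame_rate)
  n_post <- round(post * frame_rate)
  rel_time <- (seq_len(n_pre + n_post) - 1 - n_pre) / frame_rate

  keep <- logical(length(stim_onsets))
  segs <- list()
  for (k in seq_along(stim_onsets)) {
    onset_idx <- which.min(abs(rec_time - stim_onsets[k]))
    lo <- onset_idx - n_pre
    hi <- onset_idx + n_post - 1
    keep[k] <- lo >= 1 && hi <= n_frames
    if (keep[k]) segs[[length(segs) + 1]] <- traces[, lo:hi, drop = FALSE]
  }
  if (!any(keep)) stop("no trial has a full pre/post window", call. = FALSE)
  n_trials <- sum(keep)
  n_rois <- nrow(traces)
  values <- array(NA_real_, dim = c(n_rois, n_trials, n_pre + n_post))
  pre_idx <- seq_len(n_pre)
  for (j in seq_len(n_trials)) {
    seg <- segs[[j]]
    f0 <- rowMeans(seg[, pre_idx, drop = FALSE])
    values[, j, ] <- sweep(seg, 1, f0, `-`) / f0
  }
  structure(list(values = values, time = rel_time, polarity = polarity,
                 rois = rois, meta = meta,
                 trial_index = which(keep) - 1L,
                 dropped_trials = which(!keep) - 1L),
            class = "trial_tensor")
}

#' Polarity-corrected response from a trial tensor
#'
#' Returns `polarity * dF/F0`, the convention in which an increment of
#' the signaled quantity (e.g. cAMP) is always positive regardless of
#' the sensor's sign.
#'
#' @param tensor a `trial_tensor`.
#' @param roi,trial optional indices; when both given, returns the
#'   single response vector.
#' @return Array or vector of response values.
#' @export
tensor_response <- function(tensor, roi = NULL, trial = NULL) {
  r <- tensor$polarity * tensor$values
  if (!is.null(roi) && !is.null(trial)) return(r[roi, trial, ])
  r
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<trial_tensor> %d ROIs x %d trials x %d samples, t in [%.3g, %.3g) s\n",
              d[1], d[2], d[3], min(x$time), max(x$time) + 1 / x$meta$frame_rate))
  invisible(x)
}

#' Demultiplex and condition an interleaved-LED photometry trace
#'
#' For each LED-on pulse the median of the detector samples within the
#' pulse is taken, giving one sample per pulse (a 50 Hz trace for the
#' 20 ms cycle modeled here). The demultiplexed trace is then low-pass
#' filtered at 10 Hz with a zero-phase (forward-backward) Butterworth
#' filter, bleach-corrected by a mono-exponential fit to the baseline
#' window, converted to dF/F against the fitted baseline, and z-scored
#' over the session. If the trace has zero variance the z-scored output
#' is all zeros and flagged.
#'
#' @param raw list as returned by [generate_photometry_raw()], or a
#'   numeric vector (then `pulse_times` and `sample_rate` are required).
#' @param pulse_times LED-on onset times, s.
#' @param sample_rate detector sampling rate, Hz.
#' @param pulse_width_s LED-on duration, s.
#' @param lowpass_hz filter cutoff (default 10).
#' @param baseline_seconds bleach-fit window (default 240).
#' @return List with `t` (pulse times), `demuxed`, `filtered`, `dff`,
#'   `z`, `bleach` (fit summary), `flag_zero_variance`.
#' @export
demux_photometry <- function(raw, pulse_times = NULL, sample_rate = NULL,
                             pulse_width_s = 0.006, lowpass_hz = 10,
                             baseline_seconds = 240) {
  if (is.list(raw)) {
    pulse_times <- raw$pulse_times
    sample_rate <- raw$sample_rate
    pulse_width_s <- raw$pulse_width_s %||% pulse_width_s
    trace <- raw$trace
  } else trace <- raw
  if (length(pulse_times) == 0)
    return(list(t = numeric(), demuxed = numeric(), filtered = numeric(),
                dff = numeric(), z = numeric(), bleach = NULL,
                flag_zero_variance = NA))
  demuxed <- vapply(pulse_times, function(t0) {
    # samples with time in [t0, t0 + pulse_width), robust to FP jitter
    i0 <- ceiling(t0 * sample_rate - 1e-6) + 1
    i1 <- ceiling((t0 + pulse_width_s) * sample_rate - 1e-6)
    median(trace[i0:min(max(i1, i0), length(trace))])
  }, numeric(1))
  fs <- 1 / median(diff(pulse_times))
  filtered <- lowpass_zerophase(demuxed, lowpass_hz, fs)
  bl <- bleach_correct(filtered, pulse_times,
                       baseline_seconds = min(baseline_seconds,
                                              max(pulse_times) * 0.9))
  f0 <- bl$fitted
  denom <- abs(mean(f0))
  if (denom < .Machine$double.eps) denom <- .Machine$double.eps
  dff <- bl$corrected / denom
  s <- sd(dff)
  degenerate <- sd(demuxed) < 1e-12 * max(1, abs(mean(demuxed)))
  if (is.na(s) || degenerate) {
    z <- rep(0, length(dff))
    flag <- TRUE
  } else {
    z <- (dff - mean(dff)) / s
    flag <- FALSE
  }
  list(t = pulse_times, demuxed = demuxed, filtered = filtered,
       dff = dff, z = z, bleach = bl[c("amplitude", "tau", "offset",
                                       "method", "flag_fallback")],
       flag_zero_variance = flag)
}
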