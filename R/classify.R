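#' Pre-classification smoothing of a single trial
#'
#' Zero-phase low-pass filter (default 0.5 Hz cutoff) applied to a
#' single-trial trace before auROC classification. The transients being
#' detected last tens of seconds, so a 0.5 Hz cutoff suppresses
#' frame-to-frame noise without distorting them.
#'
#' @param x numeric vector (one trial of one ROI).
#' @param frame_rate Hz.
#' @param cutoff_hz filter cutoff (default 0.5).
#' @return Smoothed vector, same length.
#' @export
smooth_trial <- function(x, frame_rate, cutoff_hz = 0.5) {
  stopifnot(all(is.finite(x)))
  lowpass_zerophase(x, cutoff_hz, frame_rate)
}

#' Rank-based auROC of two sample sets
#'
#' Area under the receiver operating characteristic curve for
#' discriminating `post` from `pre`, computed as the Mann-Whitney U
#' statistic over `n*m` with midrank (0.5) credit for ties. Equals the
#' probability that a random post sample exceeds a random pre sample.
#'
#' @param pre,post numeric vectors.
#' @return auROC in [0, 1].
#' @export
auroc <- function(pre, post) {
  n <- length(pre); m <- length(post)
  if (n < 1 || m < 1) stop("empty window", call. = FALSE)
  r <- rank(c(pre, post))
  u <- sum(r[(n + 1):(n + m)]) - m * (m + 1) / 2
  u / (n * m)
}

#' Two-tailed auROC classification of one ROI-trial
#'
#' Compares the pre-stimulation window `[-pre_len, 0)` s with a 30 s
#' post-stimulation window starting at `post_onset`, on the
#' polarity-corrected response (increments of the signaled quantity are
#' positive). Trials with auROC above `hi` are labeled
#' `hit_increment`, below `lo` `hit_decrement`, otherwise `miss`. At
#' the default thresholds 0.995/0.005 a null trial (both windows drawn
#' from the same distribution) has at most a 1% chance of being labeled
#' a hit.
#'
#' @param response numeric vector, one trial in response units.
#' @param time numeric vector of times relative to stimulation onset, s.
#' @param post_onset s, start of the post window (see
#'   [default_post_onset()]).
#' @param pre_len s, length of the pre window (default 20).
#' @param post_len s, length of the post window (default 30).
#' @param hi,lo hit thresholds (defaults 0.995 and 0.005).
#' @return List with `auroc` and `label`.
#' @export
auroc_classify <- function(response, time, post_onset,
                           pre_len = 20, post_len = 30,
                           hi = 0.995, lo = 0.005) {
  pre_i <- window_idx(time, -pre_len, 0)
  post_i <- window_idx(time, post_onset, post_onset + post_len)
  if (length(pre_i) < 2 || length(post_i) < 2)
    stop("pre/post windows must contain at least 2 samples", call. = FALSE)
  a <- auroc(response[pre_i], response[post_i])
  label <- if (a > hi) "hit_increment" else if (a < lo) "hit_decrement"
           else "miss"
  list(auroc = a, label = label)
}

#' Default post-window onset for a sensor
#'
#' The post-stimulation classification window opens at the end of the
#' stimulation train plus a sensor-specific delay: 2 s for the slow
#' cAMP sensor (its transients develop over seconds) and 0 s for the
#' extracellular NPY sensor, which reports release promptly.
#'
#' @param sensor `"cadis"` or `"npylight"`.
#' @param stim_duration s.
#' @return Onset in s relative to the stimulation onset.
#' @export
default_post_onset <- function(sensor, stim_duration) {
  stim_duration + if (identical(sensor, "npylight")) 0 else 2
}

#' Classify every ROI-trial of a session
#'
#' Applies [smooth_trial()] then [auroc_classify()] to each
#' (ROI, trial) of a trial tensor. The unit of classification is a
#' single trial of a single ROI; hit fractions therefore use
#' `n_rois * n_trials` as denominator.
#'
#' @param tensor a `trial_tensor` from [trigger_trials()].
#' @param post_onset s; default from [default_post_onset()] using the
#'   tensor's metadata.
#' @param smooth_cutoff_hz pre-smoothing cutoff (default 0.5); `NA`
#'   disables smoothing.
#' @param hi,lo auROC thresholds.
#' @return A `hit_table` data frame with columns `roi_id`, `trial`
#'   (0-based), `auroc`, `label`, `peak_amplitude` (peak of the smoothed
#'   response in the 20-40 s window, signed per direction). Attributes
#'   `hit_fraction`, `fractions` (per label), `windows`.
#' @export
classify_session <- function(tensor,
                             post_onset = NULL,
                             smooth_cutoff_hz = 0.5,
                             hi = 0.995, lo = 0.005) {
  stopifnot(inherits(tensor, "trial_tensor"))
  fr <- tensor$meta$frame_rate
  if (is.null(post_onset)) {
    sd_ <- tensor$meta$stim_duration_s %||% 8
    post_onset <- default_post_onset(tensor$meta$sensor %||% "cadis", sd_)
  }
  d <- dim(tensor$values)
  resp <- tensor_response(tensor)
  out <- vector("list", d[1] * d[2])
  idx <- 1
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      x <- resp[i, j, ]
      xs <- if (is.na(smooth_cutoff_hz)) x else
        smooth_trial(x, fr, smooth_cutoff_hz)
      cl <- auroc_classify(xs, tensor$time, post_onset, hi = hi, lo = lo)
      pk <- peak_amplitude(xs, tensor$time,
                           direction = if (cl$label == "hit_decrement")
                             "decrement" else "increment")
      out[[idx]] <- data.frame(
        roi_id = tensor$rois$roi_id[i],
        trial = tensor$trial_index[j],
        auroc = cl$auroc,
        label = cl$label,
        peak_amplitude = pk,
        stringsAsFactors = FALSE)
      idx <- idx + 1
    }
  }
  ht <- do.call(rbind, out)
  n <- nrow(ht)
  frac <- c(hit_increment = sum(ht$label == "hit_increment") / n,
            hit_decrement = sum(ht$label == "hit_decrement") / n,
            miss = sum(ht$label == "miss") / n)
  attr(ht, "hit_fraction") <- unname(frac["hit_increment"] +
                                     frac["hit_decrement"])
  attr(ht, "fractions") <- frac
  attr(ht, "windows") <- list(pre = c(-20, 0),
                              post = c(post_onset, post_onset + 30))
  class(ht) <- c("hit_table", class(ht))
  ht
}

#' Boolean hit matrix from a hit table
#'
#' @param hit_table a `hit_table` from [classify_session()].
#' @param direction which labels count as hits: `"increment"`,
#'   `"decrement"`, or `"any"`.
#' @return Logical matrix `[n_rois x n_trials]`, rows named by roi_id,
#'   trials in chronological order.
#' @export
hit_matrix <- function(hit_table,
                       direction = c("increment", "decrement", "any")) {
  direction <- match.arg(direction)
  lab <- switch(direction,
                increment = "hit_increment",
                decrement = "hit_decrement",
                any = c("hit_increment", "hit_decrement"))
  rois <- unique(hit_table$roi_id)
  trials <- sort(unique(hit_table$trial))
  m <- matrix(FALSE, length(rois), length(trials),
              dimnames = list(rois, trials))
  hit <- hit_table$label %in% lab
  m[cbind(match(hit_table$roi_id, rois),
          match(hit_table$trial, trials))] <- hit
  m
}

#' Log-amplitude transform for hit/miss amplitude distributions
#'
#' Offsets peak amplitudes by the sample minimum (increments) or
#' maximum (decrements), adds a small +/-0.001 offset to remove zeros,
#' and takes the natural log of the magnitude. Used to display the
#' bimodal (all-or-none) structure of single-trial amplitudes on a log
#' axis.
#'
#' @param peaks numeric vector of peak dF/F0 values.
#' @param direction `"increment"` or `"decrement"`.
#' @return Transformed values, `log(|peaks - offset +/- 0.001|)`.
#' @export
log_amplitude_transform <- function(peaks,
                                    direction = c("increment", "decrement")) {
  direction <- match.arg(direction)
  if (!length(peaks)) stop("empty amplitude list", call. = FALSE)
  if (direction == "increment") log(abs(peaks - min(peaks) + 0.001))
  else log(abs(peaks - max(peaks) - 0.001))
}
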