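#' Peak response amplitude in a window
#'
#' Extremum of the polarity-corrected response in the 20-40 s
#' post-stimulation window (the window used to sort single-trial
#' traces): the maximum for increment-direction responses, the minimum
#' (a signed, negative value) for decrements.
#'
#' @param response numeric vector, one trial in response units
#'   (typically smoothed).
#' @param time times relative to stimulation onset, s.
#' @param window half-open window, s (default `c(20, 40)`).
#' @param direction `"increment"` or `"decrement"`.
#' @return Scalar peak value.
#' @export
peak_amplitude <- function(response, time, window = c(20, 40),
                           direction = c("increment", "decrement")) {
  direction <- match.arg(direction)
  idx <- window_idx(time, window[1], window[2])
  if (!length(idx)) stop("peak window outside the trial span", call. = FALSE)
  if (direction == "increment") max(response[idx]) else min(response[idx])
}

#' Persistence index of a mean hit trace
#'
#' Ratio of late (80-100 s after stimulation onset) to early (20-40 s)
#' area under the curve of the polarity-corrected mean response,
#' integrated by the trapezoidal rule. A flat positive trace gives 1; a
#' pure exponential decay `exp(-t/tau)` gives `exp(-60/tau)` (the 60 s
#' separation of the window centers), so a larger index means a more
#' persistent transient. The index is scale-invariant.
#'
#' @param response numeric vector, mean response across hit trials.
#' @param time times relative to stimulation onset, s; must cover
#'   [20, 100).
#' @param early,late integration windows, s.
#' @return List with `pi`, `auc_early`, `auc_late`, `flag_undefined`
#'   (TRUE when the early AUC is not positive, in which case `pi` is
#'   NA).
#' @export
persistence_index <- function(response, time,
                              early = c(20, 40), late = c(80, 100)) {
  ei <- window_idx(time, early[1], early[2])
  li <- window_idx(time, late[1], late[2])
  if (length(ei) < 2 || length(li) < 2)
    stop("trace must cover both integration windows", call. = FALSE)
  auc_e <- trapz(time[ei], response[ei])
  auc_l <- trapz(time[li], response[li])
  if (auc_e <= 0)
    return(list(pi = NA_real_, auc_early = auc_e, auc_late = auc_l,
                flag_undefined = TRUE))
  list(pi = auc_l / auc_e, auc_early = auc_e, auc_late = auc_l,
       flag_undefined = FALSE)
}

#' Mean response across hit trials, excluding repeated hits
#'
#' Averages the polarity-corrected response over hit trials of the
#' requested direction. By default only isolated hits enter the
#' averaging set: a hit is excluded when the same ROI also has a hit
#' on the following trial (whose transient falls inside the averaging
#' window and would artificially sustain the mean) or on either of the
#' two preceding trials (whose tails are still decaying within the
#' window and distort the baseline). Neighbor trials are screened at a
#' looser auROC criterion (`neighbor_auroc`, default 0.9 in the hit
#' direction) than the strict hit call, so weak events that just miss
#' the 0.995 threshold still disqualify the trials around them. This
#' is the repeated-hit exclusion used for persistence estimates.
#'
#' @param tensor a `trial_tensor`.
#' @param hit_table the matching `hit_table`.
#' @param direction `"increment"` or `"decrement"`.
#' @param exclude_repeats apply the exclusion rule (default TRUE).
#' @param neighbor_auroc auROC screening threshold for neighbor trials
#'   (applied as `>= neighbor_auroc` for increments, `<= 1 -
#'   neighbor_auroc` for decrements).
#' @param smooth_cutoff_hz optional smoothing of each trial before
#'   averaging (`NA` = none).
#' @return List with `trace` (mean response, decrements sign-flipped so
#'   the transient is positive), `time`, `n_trials_used`.
#' @export
mean_hit_trace <- function(tensor, hit_table,
                           direction = c("increment", "decrement"),
                           exclude_repeats = TRUE,
                           neighbor_auroc = 0.9,
                           smooth_cutoff_hz = NA) {
  direction <- match.arg(direction)
  stopifnot(inherits(tensor, "trial_tensor"))
  hm <- hit_matrix(hit_table, direction)
  use <- hm
  if (exclude_repeats && ncol(hm) > 1) {
    au <- matrix(NA_real_, nrow(hm), ncol(hm), dimnames = dimnames(hm))
    au[cbind(match(hit_table$roi_id, rownames(hm)),
             match(hit_table$trial, as.integer(colnames(hm))))] <-
      hit_table$auroc
    near <- if (direction == "increment") au >= neighbor_auroc
            else au <= 1 - neighbor_auroc
    near[is.na(near)] <- FALSE
    shift <- function(m, k) {  # event k trials earlier (k<0: later)
      out <- matrix(FALSE, nrow(m), ncol(m))
      if (k > 0) out[, (k + 1):ncol(m)] <- m[, 1:(ncol(m) - k)]
      else out[, 1:(ncol(m) + k)] <- m[, (1 - k):ncol(m)]
      out
    }
    use <- hm & !(shift(near, -1) | shift(near, 1) | shift(near, 2))
  }
  resp <- tensor_response(tensor)
  sgn <- if (direction == "decrement") -1 else 1
  acc <- rep(0, length(tensor$time)); n_used <- 0L
  for (i in seq_len(nrow(use))) for (j in seq_len(ncol(use))) {
    if (!use[i, j]) next
    x <- sgn * resp[i, j, ]
    if (!is.na(smooth_cutoff_hz))
      x <- smooth_trial(x, tensor$meta$frame_rate, smooth_cutoff_hz)
    acc <- acc + x
    n_used <- n_used + 1L
  }
  if (n_used == 0)
    return(list(trace = rep(NA_real_, length(tensor$time)),
                time = tensor$time, n_trials_used = 0L))
  list(trace = acc / n_used, time = tensor$time, n_trials_used = n_used)
}

#' Transient duration estimate
#'
#' Time from the response onset (first sample at or above the noise
#' floor) until the trace first falls below `max(noise_floor, peak/e)`.
#' If the trace never falls below the criterion within the trace span
#' the estimate is right-censored at the remaining span and flagged.
#'
#' @param response mean hit trace, response units (transient positive).
#' @param time times relative to stimulation onset, s.
#' @param noise_floor response units; conventionally 2x the baseline
#'   SD.
#' @param onset optional known response onset, s; detected from the
#'   noise floor when omitted.
#' @return List with `duration_s`, `onset_s`, `criterion`, `censored`.
#' @export
duration_estimate <- function(response, time, noise_floor, onset = NULL) {
  peak <- max(response)
  if (peak <= noise_floor)
    stop("peak does not exceed the noise floor", call. = FALSE)
  if (is.null(onset)) {
    oi <- which(response >= noise_floor)[1]
    onset <- time[oi]
  }
  crit <- max(noise_floor, peak / exp(1))
  pk_i <- which.max(response)
  below <- which(response < crit & seq_along(response) > pk_i &
                   time > onset)
  if (!length(below))
    return(list(duration_s = max(time) - onset, onset_s = onset,
                criterion = crit, censored = TRUE))
  list(duration_s = time[below[1]] - onset, onset_s = onset,
       criterion = crit, censored = FALSE)
}

#' Paired amplitudes of consecutive (back-to-back) hits
#'
#' Finds ROI trial pairs (t, t+1) both labeled hits in the same
#' direction and returns their peak amplitudes, for testing whether a
#' second release event riding on residual peptide from the first is
#' strengthened.
#'
#' @param hit_table a `hit_table`.
#' @param direction `"increment"` or `"decrement"`.
#' @return Data frame with `roi_id`, `trial_first`, `amp_first`,
#'   `amp_second` (amplitude magnitudes); 0 rows when no consecutive
#'   pairs exist.
#' @export
repeated_hit_contrast <- function(hit_table,
                                  direction = c("increment", "decrement")) {
  direction <- match.arg(direction)
  lab <- paste0("hit_", direction)
  out <- list()
  for (roi in unique(hit_table$roi_id)) {
    h <- hit_table[hit_table$roi_id == roi, ]
    h <- h[order(h$trial), ]
    is_hit <- h$label == lab
    k <- which(is_hit[-length(is_hit)] & is_hit[-1])
    for (i in k) out[[length(out) + 1]] <- data.frame(
      roi_id = roi, trial_first = h$trial[i],
      amp_first = abs(h$peak_amplitude[i]),
      amp_second = abs(h$peak_amplitude[i + 1]))
  }
  if (!length(out))
    return(data.frame(roi_id = integer(), trial_first = integer(),
                      amp_first = numeric(), amp_second = numeric()))
  do.call(rbind, out)
}
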