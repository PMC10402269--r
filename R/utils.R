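#' @keywords internal
#' @importFrom stats median quantile rnorm runif rbinom rpois rlnorm
#'   rmultinom sd coef lm nls predict setNames approx
#' @importFrom utils head tail read.csv write.csv
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integral of y(t)
#' @param t numeric vector of sample times (strictly increasing).
#' @param y numeric vector of samples, same length as `t`.
#' @return Scalar integral estimate.
#' @keywords internal
trapz <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 2)
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order Butterworth applied forward and backward
#' (`signal::filtfilt`), so the output has no phase lag. Used both for
#' pre-classification smoothing of single trials and for the 10 Hz
#' photometry filter.
#'
#' @param x numeric vector.
#' @param cutoff_hz cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param order filter order (default 2).
#' @return Filtered vector, same length as `x`.
#' @export
lowpass_zerophase <- function(x, cutoff_hz, fs, order = 2) {
  stopifnot(is.numeric(x), cutoff_hz > 0, fs > 0)
  w <- cutoff_hz / (fs / 2)
  if (w >= 1) return(x)  # cutoff at/above Nyquist: nothing to remove
  n <- length(x)
  bf <- signal::butter(order, w, type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass
  L <- min(n - 1, ceiling(3 * fs / cutoff_hz))
  if (L < 1) return(x)
  xp <- c(2 * x[1] - x[(L + 1):2], x, 2 * x[n] - x[(n - 1):(n - L)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(L + 1):(L + n)]
}

# Half-open window [a, b) on a time axis; returns integer indices.
window_idx <- function(time, a, b) which(time >= a & time < b)

stop_if_not_finite <- function(x, name) {
  if (any(!is.finite(unlist(x))))
    stop(sprintf("non-finite value in '%s'", name), call. = FALSE)
  invisible(TRUE)
}
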