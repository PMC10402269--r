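#' Consecutive-run hit probabilities
#'
#' For each run length `n`, the fraction of all length-`n` windows of
#' consecutive trials (overlapping, within an ROI, pooled over ROIs)
#' whose trials are all hits. With overlapping windows `P_1` is the
#' plain hit fraction, and under a fixed per-trial hit probability
#' `E[P_n] ~ P_1^n` -- the dice model.
#'
#' @param hit_matrix logical matrix `[n_rois x n_trials]`.
#' @param max_n largest run length (default 4).
#' @return List with `p` (named vector `P_1..P_max_n`), `all_hit_counts`
#'   (numerator per n), `window_counts` (denominator per n).
#' @export
run_probabilities <- function(hit_matrix, max_n = 4) {
  m <- as.matrix(hit_matrix)
  storage.mode(m) <- "logical"
  n_trials <- ncol(m)
  if (max_n > n_trials)
    stop("max_n exceeds the number of trials", call. = FALSE)
  a <- run_count_rows(m, max_n)
  counts <- colSums(a)
  windows <- nrow(m) * (n_trials - seq_len(max_n) + 1)
  p <- counts / windows
  names(p) <- paste0("P_", seq_len(max_n))
  list(p = p, all_hit_counts = counts, window_counts = windows)
}

# Per-row counts of all-hit windows of length 1..max_n.
# Returns an [n_rois x max_n] matrix.
run_count_rows <- function(m, max_n) {
  n_trials <- ncol(m)
  a <- matrix(0, nrow(m), max_n)
  w <- m
  a[, 1] <- rowSums(w)
  if (max_n > 1) for (n in 2:max_n) {
    w <- w[, -ncol(w), drop = FALSE] & m[, n:n_trials, drop = FALSE]
    a[, n] <- rowSums(w)
  }
  a
}

#' Fit the dice model for the unitary hit probability
#'
#' Least-squares fit of `Ln(P_n) = n * Ln(P_1)` through the origin,
#' restricted to run lengths with `P_n > 0`; the unitary probability is
#' `P_1 = exp(slope)`. On inputs that follow an exact power law the fit
#' is exact. When every `P_n` is zero no fit is possible and `P_1 = 0`
#' is returned with a flag.
#'
#' @param p vector of run probabilities `P_1..P_max_n` (or the list
#'   from [run_probabilities()], which also supplies the counts).
#' @param counts all-hit window counts per n (numerators of `P_n`),
#'   used by `weights = "events"`.
#' @param windows window counts per n (denominators), used by
#'   `weights = "windows"`.
#' @param weights `"none"` (ordinary least squares, the default),
#'   `"events"` (weight by the all-hit count, an approximate
#'   inverse-variance weight for a log-transformed binomial proportion
#'   -- the estimator used for session-level fits), or `"windows"`.
#'   All three coincide on exact power-law inputs.
#' @return List with `p1`, `slope`, `n_used`, `flag_no_fit`.
#' @export
fit_dice <- function(p, counts = NULL, windows = NULL,
                     weights = c("none", "events", "windows")) {
  weights <- match.arg(weights)
  if (is.list(p)) {
    counts <- counts %||% p$all_hit_counts
    windows <- windows %||% p$window_counts
    p <- p$p
  }
  n <- seq_along(p)
  ok <- is.finite(p) & p > 0
  if (!any(ok))
    return(list(p1 = 0, slope = -Inf, n_used = 0L, flag_no_fit = TRUE))
  w <- switch(weights,
              none = rep(1, sum(ok)),
              events = counts[ok],
              windows = windows[ok])
  slope <- sum(w * n[ok] * log(p[ok])) / sum(w * n[ok]^2)
  list(p1 = exp(slope), slope = slope, n_used = sum(ok),
       flag_no_fit = FALSE)
}

# Vectorized dice fits from all-hit count matrices.
# counts: [max_n x B] all-hit window counts; windows: length max_n
# denominators. Returns numeric vector of B fitted P1 values.
fit_dice_from_counts <- function(counts, windows,
                                 weights = c("none", "events",
                                             "windows")) {
  weights <- match.arg(weights)
  max_n <- nrow(counts)
  p <- counts / windows
  n <- seq_len(max_n)
  mask <- p > 0
  w <- switch(weights,
              none = mask * 1,
              events = counts * mask,
              windows = windows * mask)
  lp <- ifelse(mask, log(pmax(p, .Machine$double.xmin)), 0)
  num <- colSums(w * n * lp)
  den <- colSums(w * n^2)
  ifelse(den > 0, exp(num / den), 0)
}

#' Bootstrap confidence interval for the unitary hit probability
#'
#' Resamples whole ROI rows of the hit matrix with replacement
#' (preserving each ROI's within-session trial order, which the run
#' statistics depend on), recomputes the run probabilities and refits
#' the dice model per iteration, and returns the percentile 2.5%/97.5%
#' interval.
#'
#' @param hit_matrix logical matrix `[n_rois x n_trials]`.
#' @param n_boot bootstrap iterations (default 100000).
#' @param seed integer seed.
#' @param max_n largest run length (default 4).
#' @param weights fit weighting (see [fit_dice()]; default `"events"`,
#'   the session-level estimator).
#' @return List with `p1_hat` (point fit on the full matrix), `ci`
#'   (length 2), `n_boot`, `boot_quantiles`.
#' @export
bootstrap_ci <- function(hit_matrix, n_boot = 100000, seed = 1,
                         max_n = 4, weights = "events") {
  m <- as.matrix(hit_matrix)
  if (nrow(m) < 2) stop("need at least 2 ROI rows", call. = FALSE)
  rp <- run_probabilities(m, max_n)
  p1_hat <- fit_dice(rp, weights = weights)$p1
  a <- run_count_rows(m, max_n)                 # [R x max_n]
  windows_per_row <- ncol(m) - seq_len(max_n) + 1
  set.seed(seed %% .Machine$integer.max)
  R <- nrow(m)
  boot <- numeric(n_boot)
  chunk <- 10000L
  done <- 0L
  while (done < n_boot) {
    b <- min(chunk, n_boot - done)
    mult <- rmultinom(b, R, rep(1, R))           # [R x b] row multiplicities
    cnt <- t(a) %*% mult                         # [max_n x b]
    boot[done + seq_len(b)] <-
      fit_dice_from_counts(cnt, R * windows_per_row, weights)
    done <- done + b
  }
  ci <- unname(quantile(boot, c(0.025, 0.975), type = 7))
  list(p1_hat = p1_hat, ci = ci, n_boot = n_boot,
       boot_quantiles = quantile(boot, c(0.025, 0.25, 0.5, 0.75, 0.975)))
}

#' Bootstrap test for a difference in unitary hit probability
#'
#' Two-sample test of the dice-model `P_1` between conditions. The
#' observed statistic is `|P_1(a) - P_1(b)|`. Under the null that both
#' conditions are drawn from one pool, ROI rows are pooled and two
#' groups of the original sizes are resampled (with replacement) per
#' iteration; the p-value is the add-one-corrected fraction of null
#' statistics at least as large as observed.
#'
#' @param matrix_a,matrix_b logical hit matrices with equal trial
#'   counts.
#' @param n_boot iterations (default 10000).
#' @param seed integer seed.
#' @param max_n largest run length (default 4).
#' @param weights fit weighting (see [fit_dice()]).
#' @return List with `p_value`, `stat_observed`, `p1_a`, `p1_b`,
#'   `n_boot`.
#' @export
compare_conditions <- function(matrix_a, matrix_b, n_boot = 10000,
                               seed = 1, max_n = 4,
                               weights = "events") {
  a <- as.matrix(matrix_a); b <- as.matrix(matrix_b)
  if (!nrow(a) || !nrow(b)) stop("both matrices must be nonempty",
                                 call. = FALSE)
  if (ncol(a) != ncol(b))
    stop("conditions must have equal trial counts", call. = FALSE)
  p1a <- fit_dice(run_probabilities(a, max_n), weights = weights)$p1
  p1b <- fit_dice(run_probabilities(b, max_n), weights = weights)$p1
  obs <- abs(p1a - p1b)
  pool <- rbind(a, b)
  ca <- run_count_rows(pool, max_n)
  windows_per_row <- ncol(pool) - seq_len(max_n) + 1
  na <- nrow(a); nb <- nrow(b); np <- nrow(pool)
  set.seed(seed %% .Machine$integer.max)
  k <- 0L; done <- 0L; chunk <- 5000L
  while (done < n_boot) {
    bsz <- min(chunk, n_boot - done)
    ma <- rmultinom(bsz, na, rep(1, np))
    mb <- rmultinom(bsz, nb, rep(1, np))
    p1s_a <- fit_dice_from_counts(t(ca) %*% ma, na * windows_per_row,
                                  weights)
    p1s_b <- fit_dice_from_counts(t(ca) %*% mb, nb * windows_per_row,
                                  weights)
    k <- k + sum(abs(p1s_a - p1s_b) >= obs)
    done <- done + bsz
  }
  list(p_value = (k + 1) / (n_boot + 1), stat_observed = obs,
       p1_a = p1a, p1_b = p1b, n_boot = n_boot)
}
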