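#' First-moment lifetime from a photon decay histogram
#'
#' Fit-free lifetime estimate: the photon-weighted mean arrival time
#' (computed over bin centers) minus a rise reference time. By default
#' the reference is the center of the histogram's peak bin; a fixed
#' numeric origin (e.g. 0) can be supplied instead. The estimate is
#' invariant to uniform count scaling, and negative values are clipped
#' to 0.
#'
#' @param counts integer vector of per-bin photon counts (256 bins for
#'   the system modeled).
#' @param bin_width_ps histogram bin width, ps (default 48.86).
#' @param t_ref `"peak"` (default) or a numeric reference time in ns.
#' @return Lifetime in ns; NA for an empty histogram.
#' @export
first_moment <- function(counts, bin_width_ps = 48.86, t_ref = "peak") {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  total <- sum(counts)
  if (total == 0) return(NA_real_)
  w_ns <- bin_width_ps / 1000
  centers <- (seq_along(counts) - 0.5) * w_ns
  centroid <- sum(counts * centers) / total
  ref <- if (identical(t_ref, "peak")) centers[which.max(counts)]
         else as.numeric(t_ref)
  max(centroid - ref, 0)
}

# 2D box sum over a (2k+1)x(2k+1) neighborhood, truncated at borders,
# via an integral image.
box_sum <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- apply(m, 2, cumsum)               # cumulative down rows
  ii_core <- t(apply(cs, 1, cumsum))      # then across columns
  ii <- matrix(0, nr + 1, nc + 1)
  ii[-1, -1] <- ii_core
  r1 <- pmax(seq_len(nr) - k, 1); r2 <- pmin(seq_len(nr) + k, nr)
  c1 <- pmax(seq_len(nc) - k, 1); c2 <- pmin(seq_len(nc) + k, nc)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    out[, j] <- ii[r2 + 1, c2[j] + 1] - ii[r1, c2[j] + 1] -
                ii[r2 + 1, c1[j]] + ii[r1, c1[j]]
  }
  out
}

#' Photon and lifetime images from per-pixel decay histograms
#'
#' For each pixel, sums the decay histograms over the centered 5x5
#' neighborhood (truncated at image borders), excludes the pixel if the
#' binned histogram's peak bin holds fewer than 5 photons, and computes
#' the first-moment lifetime otherwise. Also returns the per-pixel
#' photon-count image (unbinned) and a frame QC flag from the
#' >= 1e6 photons/mm^2 criterion.
#'
#' @param counts integer array `[rows x cols x n_bins]` of per-pixel
#'   histograms.
#' @param bin_width_ps histogram bin width, ps.
#' @param bin_px spatial binning neighborhood size (odd, default 5).
#' @param min_peak_photons exclusion threshold on the binned peak
#'   (default 5).
#' @param pixel_size_um um per pixel, for the QC criterion.
#' @param t_ref rise reference passed to [first_moment()].
#' @return A `flim_frame`: list with `photons` (matrix), `lifetime`
#'   (matrix, NA where excluded), `excluded` (logical matrix),
#'   `qc_pass`, `binned_photons`.
#' @export
binned_lifetime_image <- function(counts, bin_width_ps = 48.86,
                                  bin_px = 5, min_peak_photons = 5,
                                  pixel_size_um = 2, t_ref = "peak") {
  stopifnot(length(dim(counts)) == 3, bin_px %% 2 == 1)
  if (dim(counts)[1] < bin_px || dim(counts)[2] < bin_px)
    stop("image smaller than the spatial bin", call. = FALSE)
  nr <- dim(counts)[1]; nc <- dim(counts)[2]; nb <- dim(counts)[3]
  k <- (bin_px - 1) / 2
  photons <- apply(counts, c(1, 2), sum)
  # binned histograms: box-sum each time bin
  binned <- array(0, dim = c(nr, nc, nb))
  for (b in seq_len(nb)) binned[, , b] <- box_sum(counts[, , b], k)
  peak <- apply(binned, c(1, 2), max)
  total_binned <- apply(binned, c(1, 2), sum)
  excluded <- peak < min_peak_photons
  w_ns <- bin_width_ps / 1000
  centers <- (seq_len(nb) - 0.5) * w_ns
  centroid <- apply(binned, c(1, 2), function(h) sum(h * centers)) /
    pmax(total_binned, 1)
  ref <- if (identical(t_ref, "peak"))
    matrix(centers[apply(binned, c(1, 2), which.max)], nr, nc)
  else matrix(as.numeric(t_ref), nr, nc)
  lifetime <- pmax(centroid - ref, 0)
  lifetime[excluded | total_binned == 0] <- NA_real_
  area_mm2 <- nr * nc * pixel_size_um^2 * 1e-6
  structure(list(photons = photons, lifetime = lifetime,
                 excluded = excluded | total_binned == 0,
                 qc_pass = sum(photons) / area_mm2 >= 1e6,
                 binned_photons = total_binned),
            class = "flim_frame")
}

#' Photon-weighted ROI lifetime traces with neuropil subtraction
#'
#' Per frame, the ROI lifetime is the photon-weighted mean over the
#' ROI's included (non-excluded) pixels. The neuropil contribution is
#' removed in photon-weighted intensity space at 1:1 photon-density
#' scaling: with ring photon density `rho` (photons per ring pixel) and
#' photon-weighted ring lifetime `tau_np`, the corrected ROI lifetime
#' is
#' `(sum_roi n_i tau_i - rho A_roi tau_np) / (N_roi - rho A_roi)`.
#' The subtracted neuropil photon count is capped at half the ROI
#' photons for numerical stability (when ROI and ring have equal
#' photon density the uncapped denominator vanishes); the cap leaves
#' the equal-lifetime cancellation exact. When ring and ROI share the
#' same lifetime the correction cancels exactly. Delta-lifetime is then taken relative to the mean over a
#' declared baseline window of frames.
#'
#' @param frames list of `flim_frame` objects (one per time point).
#' @param roi_masks named list of logical matrices.
#' @param rings optional named list of `neuropil_ring` objects (or
#'   logical matrices); NULL skips neuropil subtraction.
#' @param baseline_frames integer indices of the baseline window
#'   (default: first quarter of the frames).
#' @param polarity +1 or -1; stored so that increments of the signaled
#'   quantity can be plotted positive (-1 for sensors whose lifetime
#'   falls as the quantity rises).
#' @return List with `lifetime` (matrix frames x ROIs, ns),
#'   `delta_lifetime` (ns, baseline-subtracted), `polarity`,
#'   `baseline_frames`, `flags` (ROIs with all pixels excluded in some
#'   frame).
#' @export
roi_lifetime_trace <- function(frames, roi_masks, rings = NULL,
                               baseline_frames = NULL, polarity = 1) {
  n_f <- length(frames); n_r <- length(roi_masks)
  baseline_frames <- baseline_frames %||%
    seq_len(max(1, floor(n_f / 4)))
  lt <- matrix(NA_real_, n_f, n_r,
               dimnames = list(NULL, names(roi_masks)))
  flags <- setNames(rep(FALSE, n_r), names(roi_masks))
  for (f in seq_len(n_f)) {
    fr <- frames[[f]]
    stopifnot(inherits(fr, "flim_frame"))
    for (r in seq_len(n_r)) {
      mask <- roi_masks[[r]]
      ok <- mask & !fr$excluded
      if (!any(ok)) { flags[r] <- TRUE; next }
      n_i <- fr$photons[ok]
      tau_i <- fr$lifetime[ok]
      num <- sum(n_i * tau_i); den <- sum(n_i)
      if (!is.null(rings)) {
        ring <- rings[[r]]
        rmask <- if (inherits(ring, "neuropil_ring")) ring$mask else ring
        rok <- rmask & !fr$excluded
        if (any(rok)) {
          rho <- sum(fr$photons[rok]) / sum(rok)
          tau_np <- sum(fr$photons[rok] * fr$lifetime[rok]) /
            sum(fr$photons[rok])
          n_np <- min(rho * sum(ok), 0.5 * den)  # stability cap
          num <- num - n_np * tau_np
          den <- den - n_np
          if (n_np >= 0.5 * sum(fr$photons[ok])) flags[r] <- TRUE
        }
      }
      lt[f, r] <- num / den
    }
  }
  base <- colMeans(lt[baseline_frames, , drop = FALSE], na.rm = TRUE)
  dlt <- sweep(lt, 2, base, `-`)
  list(lifetime = lt, delta_lifetime = dlt, polarity = polarity,
       baseline_frames = baseline_frames, flags = flags)
}
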