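#' Magnification-corrected inter-centroid distance
#'
#' Euclidean distance between two ROI centroids (stored in image-plane
#' um) divided by the optical magnification, giving a specimen-plane
#' distance. The GRIN doublet modeled here magnifies 2.6x; slice
#' recordings use 1.0.
#'
#' @param roi_a,roi_b rows of a roi table (need `centroid_x_um`,
#'   `centroid_y_um`), or length-2 numeric centroids.
#' @param magnification optical magnification (default 2.6).
#' @return Distance in specimen um.
#' @export
pair_distance <- function(roi_a, roi_b, magnification = 2.6) {
  cen <- function(r) if (is.numeric(r)) r[1:2] else
    c(r$centroid_x_um, r$centroid_y_um)
  a <- cen(roi_a); b <- cen(roi_b)
  stopifnot(all(is.finite(a)), all(is.finite(b)), magnification > 0)
  sqrt(sum((a - b)^2)) / magnification
}

#' Trial-outcome or response similarity between two ROIs
#'
#' Three metrics over matched trials: `xnor`, the fraction of trials on
#' which both ROIs agree (both hit or both miss) -- defined for any pair
#' of sequences, including all-miss ones; `f1` (Dice coefficient),
#' `2TP/(2TP+FP+FN)` over hit labels, undefined (NA with a flag) when
#' neither sequence has a hit; `pearson`, the correlation of per-trial
#' continuous values (e.g. peak dF/F0).
#'
#' @param a,b logical hit sequences (xnor/f1) or numeric vectors
#'   (pearson), equal length.
#' @param method `"xnor"`, `"f1"`, or `"pearson"`.
#' @return Scalar similarity (NA when undefined).
#' @export
similarity <- function(a, b, method = c("xnor", "f1", "pearson")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("unequal trial counts", call. = FALSE)
  if (method == "pearson") return(stats::cor(as.numeric(a), as.numeric(b)))
  a <- as.logical(a); b <- as.logical(b)
  if (method == "xnor") return(mean(a == b))
  tp <- sum(a & b); fp <- sum(a & !b); fn <- sum(!a & b)
  if (2 * tp + fp + fn == 0) return(NA_real_)   # no hits anywhere
  2 * tp / (2 * tp + fp + fn)
}

# All eligible ROI pairs for a scope, with specimen distances.
eligible_pairs <- function(rois, magnification,
                           pair_scope = c("all", "soma-soma",
                                          "soma-neurite")) {
  pair_scope <- match.arg(pair_scope)
  idx <- utils::combn(nrow(rois), 2)
  i <- idx[1, ]; j <- idx[2, ]
  keep <- switch(pair_scope,
    "all" = rep(TRUE, length(i)),
    "soma-soma" = rois$kind[i] == "soma" & rois$kind[j] == "soma",
    "soma-neurite" =
      (rois$kind[i] == "soma" & rois$kind[j] == "neurite" &
         !is.na(rois$parent_id[j]) & rois$parent_id[j] == rois$roi_id[i]) |
      (rois$kind[j] == "soma" & rois$kind[i] == "neurite" &
         !is.na(rois$parent_id[i]) & rois$parent_id[i] == rois$roi_id[j]))
  i <- i[keep]; j <- j[keep]
  d <- sqrt((rois$centroid_x_um[i] - rois$centroid_x_um[j])^2 +
            (rois$centroid_y_um[i] - rois$centroid_y_um[j])^2) /
    magnification
  data.frame(i = i, j = j, distance_um = d)
}

# Pairwise similarity values for all pairs at once.
pairwise_similarity <- function(values, pairs, method) {
  if (method == "pearson") {
    cm <- suppressWarnings(stats::cor(t(values)))
    return(cm[cbind(pairs$i, pairs$j)])
  }
  h <- values * 1          # numeric 0/1
  n_trials <- ncol(h)
  both <- h %*% t(h)
  neither <- (1 - h) %*% t(1 - h)
  if (method == "xnor")
    return((both + neither)[cbind(pairs$i, pairs$j)] / n_trials)
  # f1: 2TP / (hits_a + hits_b)
  ha <- rowSums(h)
  denom <- outer(ha, ha, `+`)[cbind(pairs$i, pairs$j)]
  tp2 <- 2 * both[cbind(pairs$i, pairs$j)]
  ifelse(denom == 0, NA_real_, tp2 / denom)
}

#' Distance-binned similarity curve
#'
#' Assigns every eligible ROI pair to a distance bin (half-open,
#' specimen um) and averages the pairwise similarity per bin.
#'
#' @param hit_table a `hit_table` (xnor/f1) -- or, for
#'   `method = "pearson"`, also used for its `peak_amplitude` values.
#' @param rois roi table with centroids (image-plane um) and `kind`.
#' @param method similarity metric (see [similarity()]).
#' @param direction hit direction for binary metrics.
#' @param bin_width um (default 20).
#' @param pair_scope `"all"`, `"soma-soma"`, or `"soma-neurite"` (the
#'   latter restricted to a neurite and its own parent soma).
#' @param magnification optical magnification for distances.
#' @param max_distance um; bins cover [0, max_distance) (default: data
#'   range).
#' @return A `similarity_curve` data frame: `bin_lo`, `bin_hi`,
#'   `bin_center_um`, `mean_similarity` (NA in empty bins), `n_pairs`.
#'   Attribute `pair_data` carries the per-pair values for reuse by
#'   [chance_band()].
#' @export
distance_curve <- function(hit_table, rois, method = c("xnor", "f1",
                                                       "pearson"),
                           direction = c("increment", "decrement", "any"),
                           bin_width = 20,
                           pair_scope = "all",
                           magnification = 2.6,
                           max_distance = NULL) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  if (nrow(rois) < 2) stop("need at least 2 ROIs", call. = FALSE)
  rois <- rois[match(unique(hit_table$roi_id), rois$roi_id), ]
  pairs <- eligible_pairs(rois, magnification, pair_scope)
  values <- if (method == "pearson") {
    pm <- hit_matrix(hit_table, "any")  # for dimnames/order
    v <- matrix(NA_real_, nrow(pm), ncol(pm), dimnames = dimnames(pm))
    v[cbind(match(hit_table$roi_id, rownames(pm)),
            match(hit_table$trial, as.integer(colnames(pm))))] <-
      hit_table$peak_amplitude
    v
  } else hit_matrix(hit_table, direction)
  sim <- pairwise_similarity(values, pairs, method)
  max_distance <- max_distance %||% (max(pairs$distance_um) + bin_width)
  edges <- seq(0, max_distance + bin_width, by = bin_width)
  bin <- findInterval(pairs$distance_um, edges, rightmost.closed = FALSE)
  n_bins <- length(edges) - 1
  msim <- rep(NA_real_, n_bins); np <- integer(n_bins)
  for (bidx in seq_len(n_bins)) {
    in_b <- which(bin == bidx & !is.na(sim))
    np[bidx] <- length(in_b)
    if (length(in_b)) msim[bidx] <- mean(sim[in_b])
  }
  curve <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                      bin_center_um = (edges[-length(edges)] +
                                       edges[-1]) / 2,
                      mean_similarity = msim, n_pairs = np)
  attr(curve, "pair_data") <- list(pairs = pairs, values = values,
                                   method = method, edges = edges,
                                   bin = bin)
  class(curve) <- c("similarity_curve", class(curve))
  curve
}

#' Bootstrap chance band for a similarity curve
#'
#' Null distribution of the binned curve under spatial independence:
#' each ROI's trial sequence is permuted independently, destroying
#' cross-ROI coincidence while preserving every ROI's own hit count,
#' and the curve is recomputed. The band is the per-bin percentile
#' interval.
#'
#' @param curve a `similarity_curve` from [distance_curve()].
#' @param n_shuffle permutations (default 1000).
#' @param seed integer seed.
#' @param probs band quantiles (default 2.5% and 97.5%).
#' @return The curve with `chance_lo`/`chance_hi` columns added.
#' @export
chance_band <- function(curve, n_shuffle = 1000, seed = 1,
                        probs = c(0.025, 0.975)) {
  pd <- attr(curve, "pair_data")
  if (is.null(pd)) stop("curve lacks pair data", call. = FALSE)
  values <- pd$values; pairs <- pd$pairs; bin <- pd$bin
  n_bins <- nrow(curve)
  set.seed(seed %% .Machine$integer.max)
  acc <- matrix(NA_real_, n_shuffle, n_bins)
  n_trials <- ncol(values)
  for (s in seq_len(n_shuffle)) {
    perm <- values
    for (r in seq_len(nrow(values)))
      perm[r, ] <- values[r, sample.int(n_trials)]
    sim <- pairwise_similarity(perm, pairs, pd$method)
    for (bidx in seq_len(n_bins)) {
      in_b <- which(bin == bidx & !is.na(sim))
      if (length(in_b)) acc[s, bidx] <- mean(sim[in_b])
    }
  }
  curve$chance_lo <- apply(acc, 2, function(x)
    if (all(is.na(x))) NA_real_ else quantile(x, probs[1], na.rm = TRUE))
  curve$chance_hi <- apply(acc, 2, function(x)
    if (all(is.na(x))) NA_real_ else quantile(x, probs[2], na.rm = TRUE))
  curve
}

#' Spatial scale of above-chance similarity
#'
#' Scanning outward in distance, the center of the first populated bin
#' at which the curve is no longer above chance -- mean similarity at
#' or below the upper edge of the chance band -- i.e. the end of the
#' initial contiguous above-chance run. The criterion is one-sided (a
#' bin below the lower band edge is also at-or-below chance), and
#' isolated re-excursions above the band at larger distances, expected
#' by chance among many correlated bins, do not move the estimate but
#' set a flag. Censored at the largest populated bin when the curve
#' never reaches chance.
#'
#' @param curve a `similarity_curve` with chance band columns.
#' @return List with `scale_um`, `censored`, `flag_nonmonotone` (TRUE
#'   when some farther bin pokes back above the band edge).
#' @export
spatial_scale <- function(curve) {
  if (is.null(curve$chance_hi))
    stop("curve lacks a chance band; run chance_band() first",
         call. = FALSE)
  keep <- !is.na(curve$mean_similarity) & curve$n_pairs > 0 &
    !is.na(curve$chance_hi)
  cv <- curve[keep, ]
  if (!nrow(cv)) stop("no populated bins", call. = FALSE)
  at_chance <- cv$mean_similarity <= cv$chance_hi
  first <- which(at_chance)[1]
  if (is.na(first))
    return(list(scale_um = cv$bin_center_um[length(at_chance)],
                censored = TRUE, flag_nonmonotone = FALSE))
  list(scale_um = cv$bin_center_um[first], censored = FALSE,
       flag_nonmonotone = any(!at_chance[first:length(at_chance)]))
}

#' Neurite responses conditioned on the parent soma's outcome
#'
#' For each neurite ROI, averages its response separately over trials
#' on which its parent soma was a hit and trials on which it was a
#' miss. Decoupled compartments show similar neurite means in both
#' groups.
#'
#' @param tensor a `trial_tensor`.
#' @param hit_table the matching `hit_table`.
#' @param direction hit direction for the soma labels.
#' @return List with `soma_hit` and `soma_miss` mean traces (averaged
#'   over neurites and trials), `time`, and per-group trial counts.
#' @export
neurite_by_soma_outcome <- function(tensor, hit_table,
                                    direction = c("increment",
                                                  "decrement")) {
  direction <- match.arg(direction)
  rois <- tensor$rois
  hm <- hit_matrix(hit_table, direction)
  resp <- tensor_response(tensor)
  sgn <- if (direction == "decrement") -1 else 1
  neur <- which(rois$kind == "neurite" & !is.na(rois$parent_id))
  acc_h <- acc_m <- rep(0, length(tensor$time))
  n_h <- n_m <- 0L
  for (i in neur) {
    soma_row <- match(as.character(rois$parent_id[i]), rownames(hm))
    if (is.na(soma_row)) next
    for (j in seq_len(ncol(hm))) {
      x <- sgn * resp[i, j, ]
      if (hm[soma_row, j]) { acc_h <- acc_h + x; n_h <- n_h + 1L }
      else { acc_m <- acc_m + x; n_m <- n_m + 1L }
    }
  }
  list(soma_hit = if (n_h) acc_h / n_h else rep(NA_real_,
                                                length(tensor$time)),
       soma_miss = if (n_m) acc_m / n_m else rep(NA_real_,
                                                 length(tensor$time)),
       time = tensor$time, n_soma_hit = n_h, n_soma_miss = n_m)
}
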