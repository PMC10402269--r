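# Shared fixtures: small configs and sessions built in code.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_somas = 8, n_neurites_per_soma = 0, n_release_sites = 4,
         fov_size = c(200, 200)), list(...))
  do.call(generator_config, args)
}

# Isolated-unit geometry: one release site at each soma, somas far
# apart, so each ROI is an independent Bernoulli unit.
isolated_config <- function(preset = "pomc_fasted", n_somas = 60, ...) {
  make_preset(preset, n_somas = n_somas, n_neurites_per_soma = 0,
              site_placement = "per_soma", fov_size = c(3000, 3000),
              plume_fwhm = 20, ...)
}

# Ground-truth per-ROI hit matrix from a bundle's event log.
truth_matrix <- function(bundle) {
  n_rois <- nrow(bundle$rois)
  n_trials <- length(bundle$meta$stim_onsets_s)
  m <- matrix(FALSE, n_rois, n_trials,
              dimnames = list(bundle$rois$roi_id, seq_len(n_trials) - 1))
  ev <- bundle$events
  if (nrow(ev)) {
    aff <- strsplit(ev$affected_roi_ids, ";")
    for (e in seq_len(nrow(ev)))
      m[as.character(aff[[e]]), as.character(ev$trial_index[e])] <- TRUE
  }
  m
}

# Decay histogram with expected (deterministic) counts of a truncated
# exponential: a noise-free oracle input for the first-moment check.
expected_exp_histogram <- function(tau_ns, total = 1e5, n_bins = 256,
                                   bin_width_ps = 48.86) {
  w <- bin_width_ps / 1000
  edges <- (0:n_bins) * w
  span <- n_bins * w
  p <- (exp(-edges[-(n_bins + 1)] / tau_ns) - exp(-edges[-1] / tau_ns)) /
    (1 - exp(-span / tau_ns))
  p * total
}

# Closed-form mean of an exponential truncated at span T.
truncated_exp_mean <- function(tau, T) {
  tau - T * exp(-T / tau) / (1 - exp(-T / tau))
}
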