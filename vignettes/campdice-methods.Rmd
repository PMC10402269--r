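---
title: "Quantifying stochastic neuropeptide-evoked cAMP transients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stochastic neuropeptide-evoked cAMP transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campdice)
```

## The problem this package addresses

Hypothalamic feeding circuits use neuropeptides — NPY from
hunger-promoting AgRP neurons, alpha-MSH from satiety-promoting POMC
neurons — whose receptors converge on the second messenger cAMP in
downstream MC4R-expressing neurons of the paraventricular hypothalamus.
Two-photon imaging of a cAMP biosensor (cADDis, whose fluorescence
*falls* when cAMP rises) during optogenetic stimulation of peptide
axons reveals a striking statistical structure: a stimulation train
either evokes a large, all-or-none cAMP transient in a given neuron
("hit") or nothing at all ("miss"), hits occur with a fixed per-trial
probability, and a single release event impacts only a ~100 um region
of tissue. The efficacy of each peptide is hunger-state dependent: the
amplitude and persistence of transients evoked by the satiety pathway
are several-fold larger in the fed state, and vice versa for the
hunger pathway.

`campdice` implements the complete quantitative pipeline for this kind
of data — trial classification, release-probability ("dice") modeling,
persistence and amplitude metrics, spatial similarity analysis, and
fluorescence-lifetime (FLIM) estimation — together with a synthetic
session generator that embodies the statistical structure above and
carries a ground-truth event log, so every stage can be validated by
recovery tests.

## The synthetic session generator

`generate_session()` simulates one recording. Soma ROIs (with optional
attached neurite ROIs) are placed uniformly in the field of view.
Point release sites fire independently on each of 10 stimulation
trials (8 s trains, 60 s inter-trial interval) with probability
`release_prob`. A firing site adds to every ROI within its plume a
transient scaled by a Gaussian spatial weight, and the raw trace is
assembled as

    F(t) = F0 * bleach(t) * (1 + polarity * sign * response(t)) + noise

with a mono-exponential bleach envelope and i.i.d. Gaussian noise.

### The plume

One release event impacts an isotropic Gaussian plume of full width at
half maximum `plume_fwhm` (default 100 um), truncated at its
half-maximum radius. The truncation makes the event's impact region a
disc whose *diameter* equals the FWHM, a direct encoding of the ~100
um impact diameter this style of experiment reports; inside the disc
the response amplitude falls from 1 to 0.5 of the event amplitude.
The event log records, for every release, the affected ROIs (those
inside the disc) — the ground truth that classifier recovery tests
compare against.

### Transient kinetics

The temporal template is

    A * (1 - exp(-t/tau_rise)) * ((1-c) * exp(-t/tau_decay) + c)

starting at the end of the stimulation train (the analysis windows
open well after the train, so the onset convention is immaterial and
configurable). The non-persistent (low-efficacy) state uses
`tau_decay = 30` s and `c = 0`, giving transients of roughly 100 s
duration whose persistence index (below) has the closed form
`exp(-60/30) = 0.135`. The persistent (high-efficacy) state uses the
same fast decay onto a sustained plateau, `c = 0.45`. Two
considerations fix this shape rather than a slower single exponential:

1. **Calibration.** The plateau fraction is derived in closed form so
   that the ratio of persistence indices between the two states is
   exactly 5.0, the headline state contrast.
2. **Trial independence.** A slow single exponential (tau ~150 s)
   keeps *decaying* through the following trials' classification
   windows; a two-tailed rank classifier sensitive enough to detect
   plume-edge events then flags those tails as opposite-direction
   "hits" on 3–12% of trials — an order of magnitude above the <1%
   opposite-direction rate the classification must reproduce. A
   decay-to-plateau leaves later windows flat. It also makes the
   persistent state's duration right-censored at the session length,
   matching reports of ">5 min" transients measured against ~100 s
   ones.

Amplitudes are log-normal (CV 0.3, reproducing the unimodal hit
cluster on a log axis) with mean 0.2–0.25 dF/F0 in the low-efficacy
state and 1.8-fold larger in the high-efficacy state. A release event
whose site also fired on the immediately preceding trial is amplified
by `facilitation` (default 1.5), reflecting the strengthening of
back-to-back hits riding on residual peptide.

### Noise calibration

`noise_sd` (default 0.06 dF/F0 per frame at 15.5 Hz) puts single-trial
detection in the marginal regime such data actually occupies: after
0.5 Hz smoothing the noise floor is ~0.014 dF/F0, so full-plume events
(amplitude 0.2–0.45) are detected with high sensitivity, plume-edge
events (half amplitude) are detected partially, and residual tails of
preceding transients stay below the two-tailed threshold. Under these
defaults a simulated POMC-type session classifies ~11–14% of
ROI-trials as increments (the generating per-site probability is 0.15;
the detected rate is slightly lower because edge events are sometimes
missed — as in the real assay, where the printed rates are themselves
detected rates) with ~0.2% opposite-direction hits; an AgRP-type
session yields ~19–20% decrements with ~1% opposite.

### Determinism

Geometry, events, and noise are drawn from three separate seeded
substreams. Adding ROIs therefore never perturbs the event draws, and
identical `(config, seed)` pairs are bit-identical end to end.

## Preprocessing

* **Neuropil rings** (`build_neuropil_ring`): the ROI mask is dilated
  (Euclidean distance transform, so dilation by d px selects exactly
  the pixels within d px of the ROI) starting at 14 px; every ROI
  mask is removed from the dilated region; if fewer than 2500 px
  remain the dilation increments by 1 px up to a 40 px cap, past
  which the ring is returned flagged. The ring trace is subtracted
  from the ROI trace at fixed 1:1 scaling.
* **Trial alignment** (`trigger_trials`): half-open windows of
  [-20, +110) s around each onset; per-trial F0 is the mean of that
  trial's own 20 s pre-window (mean, not median, to keep the
  transform linear); trials without complete windows are dropped and
  listed. dF/F0 is stored as recorded; `tensor_response()` applies
  the sensor polarity so increments of the signaled quantity are
  always positive.
* **Photometry** (`demux_photometry`): one median per 6 ms LED-on
  pulse (robust to single-sample outliers) giving a 50 Hz trace;
  zero-phase 10 Hz Butterworth low-pass; mono-exponential bleach fit
  over the first 4 min subtracted across the recording and reused as
  the F0 for dF/F; z-scoring over the session with a degenerate-
  variance flag.

All zero-phase filtering uses a 2nd-order Butterworth applied forward
and backward over odd-reflection-padded traces; without the padding the
filter start-up transient would corrupt the pre-stimulation window at
the head of each trial.

## Classification

The unit of classification is one trial of one ROI. Each trial is
smoothed (0.5 Hz zero-phase low-pass, configurable — slow enough to
keep tens-of-seconds transients, chosen here since the assay's own
smoothing parameters are not published) and the pre-stimulation window
[-20, 0) s is compared with a 30 s post-stimulation window by a
rank-based auROC (Mann-Whitney U over n*m, midrank ties). The
post-window opens at the train offset plus 2 s for the cAMP sensor
(its transients develop over seconds) and 0 s for the NPY sensor;
both onsets are configurable since only their existence, not their
values, is documented for the assay. auROC > 0.995 labels a trial
`hit_increment`, < 0.005 `hit_decrement`, otherwise `miss`; under the
null the two-tailed hit probability is at most 1%, which the test
suite verifies on 10,000 i.i.d.-window trials. The null calibration
is stated for independent samples; smoothing introduces
autocorrelation that would inflate the tail probabilities, so the
calibration check deliberately uses unsmoothed windows.

## The dice model

With overlapping length-n windows of consecutive trials pooled across
ROIs, `P_n` is the fraction of windows that are all hits; `P_1` is
then the plain hit fraction, and a fixed per-trial probability implies
`P_n = P_1^n`, linearized as `Ln(P_n) = n Ln(P_1)`. `fit_dice()` runs
least squares through the origin over run lengths with `P_n > 0`
(exact on power-law input). The linearization amplifies noise in the
small `P_3`, `P_4`; session-level estimators (`bootstrap_ci`,
`compare_conditions`, `run_pipeline`) therefore weight each `Ln(P_n)`
by its all-hit window count, the approximate inverse variance of a
log-transformed binomial proportion. All weightings coincide on exact
power-law data; on sessions they differ by a few percent, with the
weighted fit markedly less sensitive to single missing triple-runs.

Uncertainty comes from resampling whole ROI rows with replacement
(rows preserve the serial trial order the run statistics need) and
refitting per iteration; the percentile 2.5/97.5 interval is reported.
The default is 100,000 iterations; recovery tests use 10,000, which
changes the interval endpoints by well under the interval width.
Between-condition tests pool rows, resample two groups of the original
sizes, and compare `|P1_a - P1_b|` with an add-one-corrected p-value;
its type-I error is verified to sit in [0.03, 0.07] at alpha = 0.05
over 1,000 exchangeable replicates.

## Amplitude, persistence, duration

* `peak_amplitude`: extremum of the smoothed response in [20, 40) s
  after onset, the window used for sorting single-trial displays.
* `persistence_index`: late ([80, 100) s) over early ([20, 40) s)
  area under the curve of the mean hit trace, by trapezoid. The
  late/early orientation is chosen so that larger = more persistent
  (descriptions of this ratio appear in both orders in the
  literature; this package fixes the direction and documents it).
  For a pure exponential the index is exactly `exp(-60/tau)`, and the
  trapezoidal estimate at 15.5 Hz is within 0.5% of that closed form.
* Averaging set: a hit enters the mean hit trace only if the same ROI
  shows no other near-threshold event (auROC >= 0.9 in the hit
  direction) on the following trial or the two preceding trials. The
  following trial's transient would fall inside the averaging window
  and artificially sustain the mean; preceding transients' tails
  distort the baseline. The looser neighbor criterion matters: weak
  plume-edge or tail-riding events that just miss the 0.995 hit
  threshold otherwise leak into the averaging window and bias the
  persistence index by up to ~10%.
* `duration_estimate`: time from response onset (first crossing of
  the noise floor, conventionally 2x the baseline SD) until the trace
  first falls below `max(noise_floor, peak/e)`; traces that never
  cross are right-censored at the trace span — which is the expected
  outcome for the sustained (fed POMC-like) condition.
* `repeated_hit_contrast`: paired amplitudes of back-to-back hits,
  recovering the generator's facilitation factor in tests.

## Spatial similarity

Pairwise similarity of trial outcomes versus inter-ROI distance.
Distances are inter-centroid, divided by the optical magnification
(2.6 for the GRIN doublet geometry, 1 for slice). Metrics: XNOR (the
fraction of trials on which two ROIs agree — defined for every pair,
including all-miss ones, which is why it is the primary metric), F1 /
Dice (undefined and flagged when neither ROI has a hit), and Pearson
correlation of per-trial peak dF/F0. Pairs are binned in 20 um bins
(configurable; the width is not documented for the assay).

The chance band permutes each ROI's trial sequence independently
(1,000 shuffles), which destroys cross-ROI coincidence while
preserving every ROI's hit count exactly, and takes per-bin 2.5/97.5
percentiles. The spatial scale is the center of the first populated
bin whose mean similarity is at or below the band's upper edge — the
end of the initial contiguous above-chance run. Two deliberate
choices here: the criterion is one-sided, because a bin *below* the
lower band edge is also at-or-below chance; and isolated
re-excursions above the band at larger distances only set a flag,
because with ~40 correlated bins at 95% per-bin coverage such
excursions are expected under the null and would otherwise inflate
the estimate severely (in simulation, rules requiring all farther
bins to stay inside the band misestimated the scale in ~30% of
sessions; the run-end rule is within one bin of the generative 100 um
impact diameter in ~85%).

## FLIM

Lifetimes are estimated by the first moment of the photon decay
histogram (256 bins, 48.86 ps per bin, spanning 12.51 ns as for an
80 MHz laser; published descriptions of such systems occasionally
print "fs", which is physically inconsistent with a 256-bin
nanosecond-scale decay and is read as ps here): the count-weighted
mean of bin centers minus a rise reference, by default the peak bin's
center (so a single-bin histogram reads exactly zero), or a fixed
numeric origin. The estimator is invariant to count scaling, and for
an exponential truncated at the span the fixed-origin first moment
matches the closed form `tau - T exp(-T/tau)/(1 - exp(-T/tau))`
within 1% at 1e5 photons.

Per-pixel estimates use 5x5 spatial binning (border-truncated,
implemented with an integral image and verified against a direct
neighborhood sum); a pixel is excluded when its binned histogram's
peak bin holds fewer than 5 photons. Frames below 1e6 photons/mm^2
are flagged, not dropped. ROI lifetime traces are photon-weighted
means over included pixels; the neuropil contribution is removed in
intensity-weighted space at 1:1 photon density —
`(sum n_i tau_i - rho A_roi tau_ring) / (N_roi - rho A_roi)` — with
the subtracted photon count capped at half the ROI photons. The cap
matters: at equal ROI/ring photon density the uncapped denominator
vanishes; the capped correction stays finite and still cancels
exactly when ROI and ring share a lifetime. Delta-lifetime is taken
against a declared baseline window, with the sensor polarity stored
so cAMP increases can be plotted positive.

## Problem sizes and what the tests show

Recovery tests run at deliberately chosen sizes: dice-model recovery
on 500 isolated units x 10 trials (one release site per soma, sparse
field, low noise — isolating the Bernoulli process from plume
overlap, the construction implied by "adjacent release sites");
persistence on noise-free isolated-unit sessions averaged over six
seeds per state (plume overlap adds rare weak events that are
invisible to any threshold classifier and bias single-session
indices); spatial-scale recovery on one 300-ROI session with 46
uniform sites (one per plume-impact area, so the per-ROI hit rate
matches the per-site probability of 0.15).

The generator emulates the statistical structure of the assay — not
its imaging physics. It contains no motion, no shot-noise scaling
with brightness, no slow drifts, no segmentation errors, and its
noise is white; passing recovery tests therefore demonstrate that the
analysis correctly inverts the generative model it assumes, not that
the pipeline is robust to every artifact of real recordings. Known
limitations: consecutive same-site events riding steep tails can
evade the classifier even noise-free (the facilitation default
mitigates this); opposite-direction false hits rise toward ~1% for
high-rate persistent conditions; the spatial-scale estimator
carries a seed-to-seed spread of about one 20 um bin; and because the
bleach envelope is multiplicative, sessions generated with the default
`bleach_tau = 6000` s carry a slow upward drift in response units
(~0.003 dF/F0 per 20 s) that inflates persistence indices measured on
raw sessions — the kinetics recovery tests therefore run with
bleaching disabled, as stated above, and persistence comparisons on
bleached data should contrast conditions rather than read single
indices as pure kinetic quantities.
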