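---
title: "Quantifying single-cell secretion from time-lapse immunospot signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell secretion from time-lapse immunospot signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qlcis)
library(dplyr)
```

## The measurement and its inversion problem

Live-cell imaging of secretion (qLCI-S) seats single cells in an array of
nanoliter wells (by default 996 cubic wells of 80 µm per chamber, 115 µm
pitch, four chambers) whose glass floor carries capture antibody. Secreted
cytokine is captured where it lands, stained by a fluorescent detection
antibody, and read out by TIRF microscopy frame after frame for days. The
well-floor fluorescence is therefore a *cumulative secretion signal* (CSS):
every release event keeps contributing long after it happened, filtered
through the binding and bleaching kinetics of the immunoassay.

The package's central operation inverts that accumulation. A unit
instantaneous release produces the staining-kinetics response

$$A(t) \;=\; \Big[\textstyle\sum_j w_j e^{-t/\tau_{d,j}}\Big]
             \Big[\textstyle\sum_k v_k\big(1-e^{-t/\tau_{a,k}}\big)\Big],$$

a product of one or two exponential association terms (capture and
detection-antibody binding; two terms accommodate a polyclonal detection
antibody with fast and slow binding classes) and one or two exponential
decay terms (dissociation from the capture antibody plus photobleaching).
`A(0) = 0`, and with decay disabled the association part saturates at 1.
All printed calibration variants are instances of this single product form,
which is why the package represents them with one constructor,
`ab_kinetics()`. Four calibrations obtained by microinjection standard
curves (instantaneous release of a known amount of recombinant protein) are
shipped in `builtin_calibrations()`:

| name | decay τ (w) | association τ (w) | unit |
|---|---|---|---|
| mouse-IL-5 | 3.4e4 | 7.6 (0.599), 84 (0.401) | min |
| human-IL-5 | 280 | 0.27 | h |
| human-IL-13 | 0.84 (0.71), 210 (0.29) | 1.0 | h |
| crosstalk-13to5 | 280 | 0.23 (0.23), 25 (0.77), amplitude β = 0.33 | h |

One printed parameter set pairs a two-term *decay* with α = 0.71 and a
single association term; that weighting is kept on the decay part as the
formula states, and the association-term label ambiguity elsewhere (fast
vs. slow term under α ↔ 1 − α) is resolved by always storing association
time constants in ascending order.

On the binned time grid (bin width Δt frames, `A_k = A(kΔt·interval)`),
observed CSS and per-bin release (DSS) are related by the causal
convolution

$$CSS_k = \sum_{i \le k} DSS_i \, A_{k-i+1},$$

so a bolus released in bin 0 first shows up at the end of that bin with
weight `A(Δt)`. `deconvolve_css()` solves this bin by bin:

$$DSS_k = \Big(CSS_k - \sum_{i<k} DSS_i A_{k-i+1}\Big)\big/ A_1 .$$

Negative intermediates are clamped to zero — secretion cannot be negative —
and the *clamped* value enters all subsequent history sums, so the recursion
stays self-consistent. The total clamped mass is reported on the result; on
noiseless input it is zero up to floating-point dust (order 1e-13 of the
train), and the tests budget it against the same 1e-9 relative tolerance as
the round-trip error rather than asserting an exact zero. A whole-trace
non-negative least-squares solve (`method = "nnls"`) is available as a
cross-check; the recursion remains the standard path.

Cross-reaction is handled the same way: the anti-IL-13 detection antibody
binds captured IL-5 immunocomplexes, adding
$\chi(\Delta t) = \beta e^{-\Delta t/\tau_4}\{\alpha(1-e^{-\Delta t/\tau_5})
+ (1-\alpha)(1-e^{-\Delta t/\tau_6})\}$ per unit IL-5 release. Because the
IL-5 channel is deconvolved first, its release train predicts the spurious
IL-13-channel signal, which `compensate_crosstalk()` subtracts before the
IL-13 deconvolution. The corrected CSS is floored at zero for consistency
with DSS clamping (the alternative — allowing negative corrected CSS — only
moves the clamp into the subsequent deconvolution).

## Preprocessing: what is removed before deconvolution

Wells that contain no cell are an in-situ reference for everything the
instrument does to the signal. Illumination drift is modelled as a
multiplicative factor per field-of-view quadrant × chamber × frame (and per
channel, computed independently): the mean empty-well intensity of each
stratum divided by the grand mean of all empty wells gives a coefficient,
and dividing each well's trace by its stratum coefficient removes the
drift. The operation is idempotent, and a stratum without empty wells falls
back to the chamber-level coefficient with a warning.

Baselines are subtracted per well: by default the well's own initial
intensity (static autofluorescence), but wells whose initial intensity lies
beyond Q3 + 1.5 × IQR of the population of initial intensities — infrequent
autofluorescent contaminants — instead have the per-frame mean empty-well
trace subtracted. The outlier rule is one-sided (above Q3 only):
contaminants brighten, they do not darken. The time-varying empty-mean
trace (rather than a constant) is used for outlier wells because those
wells' own initial frame is exactly what cannot be trusted.

A consequence worth knowing: subtracting the own initial frame makes every
CSS trace share that frame's noise draw as a constant offset. The robust SD
estimated from empty-well CSS values absorbs this (it is √2 times the
per-frame noise SD), but a well whose initial frame was a ≳2.5σ outlier has
its entire trace shifted relative to the detection limit, and its called
onset can land more than one frame from the truth. This is a property of
the baseline rule itself, not of the implementation; the synthetic-data
studies below therefore score onset recovery as a rate (fraction of
detected wells within one frame) rather than a worst case.

For image stacks, `align_stack()` registers frames by exhaustive
integer-shift search (default ±10 px) maximizing Pearson correlation on the
overlap — sub-pixel registration is deliberately not attempted — with
out-of-frame pixels marked invalid rather than zero-filled, and frames whose
best correlation is below a confidence floor left unshifted and flagged.
`denoise_and_bin()` subtracts the initial frame, applies a 5-frame rolling
median per pixel (window shrinking symmetrically at the edges, so no signal
is fabricated at the boundaries), and bins 5 × 5 pixel blocks by *mean*, not
sum, so intensities remain on the calibration scale.

## Calling and classification

The noise scale is estimated as `robust_sd()` = 1.4826 × MAD of empty-well
intensities — consistent for Gaussian noise, immune to contaminated wells.
A zero MAD is returned as a degenerate result that threshold construction
refuses. Two thresholds derive from it: the detection limit 3σ̂ and the
hyperactive limit 50σ̂ (the value that matches a k-means split of positive
wells; `kmeans_activity_check()` reports that concordance, but the 50σ̂ rule
is authoritative).

Positivity exploits the continuity of a cumulative signal: a trace is
positive when it stays above the detection limit for at least 2 consecutive
frames, and once confirmed, dips of up to 3 frames below threshold do not
end the episode. Two semantics were genuinely open and are fixed as
follows: the gap allowance may be used repeatedly within one episode, and
an episode must *begin* with ≥ 2 consecutive supra-threshold frames — an
isolated single frame before a gap never seeds an episode. The state
machine is verified exhaustively against an independent rle-segment oracle
over every supra/sub pattern up to length 12.

Each well is then silent (not positive), hyperactive (positive with max CSS
≥ 50σ̂) or slightly active; a well is active if positive in *either*
channel, and its class comes from the channel with the largest max-CSS/σ̂
ratio. Onsets are reported on the CSS frame grid, not the coarser
deconvolution bin grid. `activation_curve()` turns onsets into a cumulative
activation function with censoring bookkeeping (via `survival::survfit`),
and `compare_groups()` wraps Mann-Whitney / log-rank tests with
Benjamini-Hochberg control across the pairwise family.

## Localization

Per-pixel deconvolution yields DSS images whose spot is modelled as a
single elliptical Gaussian plus constant offset, fitted by
Levenberg-Marquardt (`fit_dss_gaussian()`). Localization is only meaningful
when a spot is clearly present, so images whose peak is below `min_peak`
(naturally 3σ̂ of the empty-well DSS noise floor) return a below-threshold
verdict instead of a fabricated centre; non-convergence and out-of-bounds
centres are likewise flagged, never silently accepted. Multi-source wells
are flagged by residual rather than fitted with multiple peaks.
`displacement_series()` joins per-frame fits (not time-averaged ones) to
the tracked cell centroid — supplied masks or `mask_centroids()`; cell
segmentation itself is outside the package — and summarizes distances by
median and quartiles.

## Optics checks

`critical_angle(n_t, n_i) = asin(n_t/n_i)` and the objective aperture limit
`asin(NA/n_i)`, reported in degrees to one decimal. With the printed glass
index 1.52: an amorphous-fluoropolymer layer (n = 1.34) gives 61.8°, the
aperture limit of an NA 1.49 objective is 78.6°, and PDMS directly on glass
gives 67.1° — the PDMS index 1.40 is the standard material value (it is not
printed in the source of the other constants). `check_optics()` assembles
these into a per-dish validation table.

## The synthetic experiment generator

`make_dish_layout()`, `population_spec()`, `simulate_population()` and
`render_observations()` forward-model an entire experiment so that every
analysis stage can be tested against known ground truth:

* **Layout** — deterministic near-square grids, 996 wells/chamber at 115 µm
  pitch by default, quadrant assignment by position.
* **Population** — three secretory phenotypes. Defaults: ~25% of wells
  empty; of the occupied wells 33% silent, 50% slightly active, 17%
  hyperactive (roughly two thirds active, the scale seen in such assays);
  onsets log-normal (median 4 h, σ_log 0.5) truncated to 1-12 h after
  stimulation; slightly active cells cease release after a uniform 10-30 h;
  hyperactive cells sustain it to the 72 h horizon.
* **Release trains** — a burst at onset carrying half of the class scale,
  the remainder spread over the active window. The burst models the step
  onset of secretion and is what makes onsets sharp at a 1 h cadence; the
  class plateau scales (0×, 10×, 100× the empty-well robust SD for
  silent/slight/hyperactive) tie the truth directly to the 3σ̂ and 50σ̂
  thresholds used downstream.
* **Observation** — release convolved with the channel kinetics, optional
  IL-13 cross-signal, a static per-well baseline (with optional
  autofluorescent outlier wells), multiplicative drift per
  quadrant × chamber × frame (default 0.7-1.4×), additive Gaussian noise.
  All randomness is fixed by the single integer seed in the spec.

What the generator does **not** emulate: diffusion of secreted protein
within a well (spot shape is phenomenological), cell division and death,
focus drift, non-Gaussian camera noise, saturation, or spatial correlation
of the illumination field within a stratum. Passing tests therefore
demonstrate that the analysis correctly inverts its own stated forward
model at realistic noise levels — not that real microscope data meet those
assumptions.

## Numerical choices and problem sizes

* Nonlinear fits (`fit_kinetics()`, `fit_dss_gaussian()`) run
  Levenberg-Marquardt on log-transformed positive parameters with
  logistic-transformed weights; the kinetics fit uses 8 log-spaced
  multi-starts over the observed time span (the calibration source gives no
  fitting details) and keeps the lowest-RSS converged start. Association
  faster than decay is encouraged by the starts, and fitted association
  constants are canonicalized ascending.
* `smooth_dss()` applies a moving median directly to the per-bin release
  train; the Δt binning already provides the temporal integration, and a
  median on the *re-integrated* trace would preserve steps and thus fail to
  reject single-bin impulses.
* Rolling medians and moving medians shrink their window symmetrically at
  trace edges instead of padding.
* Ties and degenerate inputs: zero-MAD thresholds are refused; all-tied
  Mann-Whitney data warns and returns p = 1; featureless frames register
  with zero shift and a low-confidence flag; flat standard curves are a fit
  error, not a silent zero.
* Validation problem sizes (chosen to exercise the estimators well away
  from small-sample artifacts while staying desk-scale): 500 random trains
  of length 2-200 for the deconvolution round trip; 100 replicates × 200
  points at 1% noise for kinetics recovery; a 2,000-well two-chamber
  population for end-to-end class/onset recovery; 1,000 replicates at
  SNR 10 for localization; 10⁵ draws for the robust-SD consistency check.

## Known limitations

The recursion amplifies per-bin noise by 1/A(Δt) and has no regularization
beyond clamping and post-hoc smoothing; very slow kinetics relative to the
bin width are rejected outright (`A(Δt)` at the numeric floor). Calibration
decay constants are trusted as-is: kernels are evaluated in the physical
time units stored on every object, so changing the imaging cadence never
rescales a photobleaching-containing decay constant even though the
bleaching component is, physically, exposure-driven. Quantities are
relative signal units throughout; converting DSS to molecules requires an
absolute calibration the package does not model.
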