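---
title: "Methods: signal model, quantification rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal model, quantification rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberpnn)
```

This vignette documents what the package computes, the assumptions behind
each stage, why the defaults are what they are, and what a passing test
does and does not establish. Every number quoted here is either a package
default or a quantity the test suite itself computes.

## 1. The ΔF/F model

A two-channel fiber-photometry recording interleaves a 470 nm
calcium-dependent frame with a 415 nm isosbestic frame at 40 FPS, giving
20 Hz per channel. At the isosbestic wavelength GCaMP fluorescence is
calcium-independent, so the 415 stream carries the non-neural components —
photobleaching and motion/fiber-bending artifacts — that contaminate the
signal channel.

The pipeline (`process_dff()`) proceeds in three steps.

**Debleaching model.** The 415 stream is fit by nonlinear least squares to
a biexponential decay, `F(t) = a₁e^(−t/τ₁) + a₂e^(−t/τ₂) + c`. The two
time constants capture the empirically distinct fast and slow bleaching
pools of a fluorophore/autofluorescence mixture. For fixed (τ₁, τ₂) the
model is linear in (a₁, a₂, c), so the fit profiles the linear part exactly
and searches only the two log-time-constants (Nelder–Mead from four
starts). The single-exponential special case is always evaluated too; if
the biexponential search cannot beat it, the single-exponential fit is
returned and flagged in provenance, so the reported SSE never exceeds the
nested model's. An all-constant input returns `a₁ = a₂ = 0, c = mean(F)`.

**Reference scaling.** The reference vector is mapped onto the signal
channel by ordinary least squares: `F̂ = slope·ref + intercept`. OLS is the
conventional reading of "linearly scale"; a robust alternative was
considered and rejected as unnecessary for the artifact levels modelled
here.

**Choice of reference — the central design decision.** Two references are
offered:

* `reference = "isosbestic"` (default): the raw 415 stream. Because motion
  artifacts appear additively in both channels, subtracting the scaled raw
  isosbestic stream cancels them along with the bleach trend. The cost is
  that the isosbestic channel's shot noise enters the trace (noise SD grows
  by roughly √(1 + slope²) relative to the signal channel alone).
* `reference = "fitted"`: the fitted bleach curve only. This is pure
  debleaching — it adds no reference noise but leaves motion artifacts in
  the trace. It is the right choice for recordings without movement (e.g.
  head-fixed, or simulated sessions with artifacts disabled).

The default is `"isosbestic"` because artifact rejection is the stated
purpose of recording the 415 channel at all; a smooth fitted curve cannot
cancel an artifact it does not contain. The package's artifact-rejection
test measures residual artifact-band power (excess power in windows around
known artifact times, relative to the rest of the trace, after removing a
1 s running median) and requires ≥ 80% reduction against a naive
`(F − mean)/mean` trace; the isosbestic route achieves 81–94% across
simulated sessions, limited mainly by the OLS slope mapping the two
channels' different bleach amplitudes (slope ≈ 1.25 for the default
simulation) while artifacts enter both channels with gain 1 — the residual
artifact fraction is `|1 − slope·g/α|`-shaped and cannot reach zero unless
the channels bleach identically.

One subtlety of OLS scaling worth knowing: the regression sees the calcium
transients in the signal channel, so the scaled reference is inflated by
the mean transient uplift (the transient duty cycle times amplitude). For
sparse transients this is well below 1% of baseline, but it appears as a
small uniform negative offset in ΔF/F; the test suite measures transient
amplitude above the local pre-event baseline for this reason.

**Baseline correction.** For test sessions, the offset
`|mean(hc) − min(test)|` is added to every sample, where `mean(hc)` is the
home-cage ΔF/F averaged over the *middle 3 minutes* of the 5-minute
baseline recording (the edges are excluded because handling stress
contaminates them). The absolute-value form means the correction is always
an upward shift; whenever `min(test) ≤ mean(hc)` the corrected minimum
equals the home-cage mean exactly. The shift preserves variance and all
peak structure; the AUC's positive-part convention (below) is what makes
this correction matter.

## 2. Behaviour alignment and epoch filtering

Behaviour tracks (freezing/moving at the tracking software's own sampling
rate, clock-zeroed at the synchronizing TTL pulse) are aligned to the
photometry grid by minimum absolute timestamp difference, ties to the
earlier behaviour sample. Tie comparisons carry a 1 ns slack so that exact
midpoints — which occur systematically when the two clock rates are
commensurate (10 Hz vs 20 Hz) — are not decided by floating-point
representation error.

Maximal constant-state runs become epochs; a run of *n* samples at frame
period Δt spans `[t_first, t_first + nΔt)`. Runs shorter than the minimum
bout criterion are **dropped, not merged**: an excluded short bout leaves a
gap, because exclusion ("not included in the analysis") is not the same as
reassignment to a neighbouring state. The default minimum is 2 s and a run
of exactly 2 s is retained (the exclusion rule is "shorter than"). The
threshold is configurable because freezing itself is often *scored* with a
1 s criterion; the analysis-time 2 s criterion is a separate, stricter
filter.

## 3. Trace metrics

* **AUC** is the summed area between the x-axis and the trace: positive
  samples contribute `value × Δt`, negative excursions contribute zero.
  The baseline correction exists precisely to lift test traces above the
  axis, which supports the positive-part reading; a trapezoid option is
  provided for the whole-session value. Per-state AUC divides by the summed
  duration of that state's retained epochs (yielding ΔF/F units), and a
  state with no retained epochs is reported as missing (`NA`) rather than
  zero. When epochs tile the session, per-state values recombine exactly to
  the session total (partition additivity, tested to 1e-9).
* **Peak detection** thresholds at `median + 2·SD` of the whole session's
  ΔF/F and takes local maxima (strictly greater than both neighbours) above
  it. Accepted peaks must be ≥ `min_peak_gap_s` apart; among conflicting
  candidates the larger wins. The default gap is 1.0 s: at the default
  threshold a 5% transient with GCaMP7f-like decay (τ ≈ 0.6 s) stays above
  threshold for roughly 0.9 s, and a shorter gap (e.g. 0.25 s) lets noise
  on the decay flank register as spurious second peaks — in simulation this
  inflated counts by ~60%. With the 1 s gap, injected event counts are
  recovered within ±10% (median over sessions) at the package's default
  noise. The gap is configurable and 0 disables it.
* **Peak height** is the absolute ΔF/F at the maximum, not prominence;
  heights therefore include any baseline-correction offset, which is
  constant within a session and cancels in between-state comparisons.
  **Peak frequency** divides the count of peaks falling inside a state's
  epochs (half-open intervals) by that state's summed duration. Peaks in
  excluded short bouts count toward the session but toward no state.

## 4. PNN quantification

High-magnification z-stacks of single WFA-labelled nets are
maximum-intensity projected over the **top half** of the stack (planes
1..⌈Z/2⌉), avoiding out-of-focus signal from the far hemisphere of the
net. Binarization uses the IsoData iterative-intermeans algorithm — the
method behind FIJI's "Default" threshold — computed from intensities
*inside the traced ROI* so that large dark background regions cannot drag
the threshold down; Otsu is available as an alternative. A uniform ROI is
an error, not an empty mask.

**Surface contiguity** is the fraction of WFA-positive pixels belonging to
the largest connected component, with 8-connectivity by default (ring arcs
that touch diagonally are one structure; 4-connectivity is available). An
intact net scores 1.0; fragmentation into disconnected arcs lowers the
score toward the largest surviving arc's share. Density is simply counted
nets over traced area (shoelace polygon area × pixel size² → mm⁻²); net
identification itself is manual, as in the source workflow — the package
quantifies, it does not segment.

## 5. Estimation statistics

Cohen's d uses the pooled standard deviation and no small-sample
correction by default (Hedges' correction is a flag); at n = 14 per group
the uncorrected estimator carries a known upward bias of about +0.02 on a
true d of 0.8, which the coverage test documents. The BCa interval
resamples each group independently with replacement, computes the
bias-correction z₀ from the fraction of resampled d values below the
observed d (exact ties counted half), and the acceleration from the
jackknife skewness over leave-one-out deletions across both groups.
Resamples with zero pooled variance are dropped and counted; more than 50%
degenerate is an error, and BCa refuses groups smaller than 3 (no
jackknife). Multi-comparison analyses run each pair independently — this
is estimation, not testing, so there is no pooling and no multiplicity
adjustment — with per-label seeds derived from the master seed, making
results invariant to comparison order.

## 6. The synthetic world

The generators state a world once and the tests measure recovery in it:

* **Photometry** (`simulate_session()`): 300 s at 40 FPS interleaved.
  Bleach: a₁ = 20 (τ = 40 s), a₂ = 30 (τ = 500 s), offset 100 units for
  the 470 channel; the 415 channel uses the same shape scaled by 0.8
  (channels bleach similarly, not identically). Transients: Poisson events
  (0.1 Hz default, or a fixed count), difference-of-exponentials kernel
  with rise 50 ms and decay 600 ms (GCaMP7f-like), peak amplitude 5% ΔF/F,
  multiplicative on the bleach curve. Artifacts: raised-cosine bumps of
  0.4 s and ±10 units at 0.05 Hz, added to both channels with equal
  amplitude — smooth, because a real head-movement artifact does not step
  discontinuously between two frames 25 ms apart. Noise: white, SD 1 unit
  per frame (≈ 0.2 × the transient amplitude in ΔF/F terms). The source
  study reports no noise levels or amplitudes; these are package choices
  at physiologically plausible values, documented here, not claims about
  any particular dataset.
* **Behaviour** (`simulate_behavior()`): alternating freezing/moving bouts
  with exponential durations (mean 8 s), sampled at 10 Hz. Ground-truth
  bouts are defined as the bout structure the sampled track encodes —
  which is what any tracking export contains — so recovery can be exact;
  boundaries between the behaviour and photometry grids agree to within
  half a photometry frame (25 ms), and the epoch-filter test asserts
  exactly that.
* **PNN images** (`simulate_pnn_image()`): bright rings (radius 3 µm, width
  0.6 µm at 0.1 µm/px) with a stated fraction of circumference removed
  across 3 arc gaps; depth-faded planes at 0.37 µm z-steps. True contiguity
  is computed on the noise-free mask, and the pipeline reproduces it
  exactly at the default SNR.
* **Two groups** (`simulate_two_groups()`): Normal(0,1) vs Normal(d,1), so
  the nominal d is the population effect size.

What a green test establishes: the implementation recovers known ground
truth under this world's assumptions. What it does not establish: that the
biexponential is the right bleach model for a given rig, that artifacts in
a given experiment are channel-symmetric, or that the noise level matches
a given photoreceiver — all of which should be checked per dataset.

## 7. Numerical choices and degenerate inputs

* Bleach-fit time constants are searched in log space over
  `[span/2000, 20·span]`; amplitudes may be negative (rising channels fit
  without error), and the monotonicity guarantee applies only when both
  amplitudes are nonnegative.
* `compute_dff()` refuses non-positive scaled references (division
  blow-up), reporting the first offending index.
* Epoch durations are counted as `n_samples × Δt` and compared against the
  bout criterion with 1e-9 slack, so grid-exact 2.0 s bouts are retained
  regardless of binary representation.
* Empty peak sets, states without epochs, and empty masks are `NA`/error
  by design — missing is distinct from zero throughout.
* All generator randomness flows through one seed per call and the caller's
  RNG state is restored afterwards; pipeline stage seeds are derived from
  the master seed by a label hash, so adding a stage never perturbs another
  stage's draws.

## 8. Known limitations

* No aperiodic detrending alternatives (airPLS, low-pass) and no z-scored
  ΔF/F variant; the biexponential + linear scaling route is the only one
  implemented.
* The OLS scaling inflates the reference by the transient duty cycle
  (section 1); for very dense transients a baseline-restricted regression
  would be needed.
* Image handling is deliberately minimal: plain-text stacks, single
  channel, no registration, no automated net detection.
* The CSV dialects cover the common export shapes (nm literals or 1/2 LED
  flags; Time/Freezing behaviour columns) but not proprietary binary
  formats.
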