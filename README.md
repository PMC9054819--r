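# fiberpnn

Tools for quantifying hippocampal population activity and perineuronal-net
(PNN) integrity in studies of memory retrieval — the kind of experiment in
which mice expressing GCaMP7f in CA1 are recorded by fiber photometry during
a contextual fear memory test, behaviour is scored as freezing vs. movement
by automated tracking, and WFA-stained histology quantifies how intact the
extracellular matrix around CA1 neurons remains.

The package covers four analysis stages plus a ground-truthed simulator:

1. **ΔF/F processing.** Two-channel recordings interleave a 470 nm
   calcium-dependent frame with a 415 nm isosbestic frame (40 FPS → 20 Hz
   per channel). The isosbestic stream is fit to a biexponential bleach
   curve `F(t) = a₁e^(−t/τ₁) + a₂e^(−t/τ₂) + c`, a reference (raw 415
   stream by default, or its fitted curve) is mapped onto the signal channel
   by ordinary least squares, and

   ΔF/F(t) = (F₄₇₀(t) − F̂(t)) / F̂(t).

   Test traces are then baseline-corrected by adding the offset
   `|mean(hc) − min(test)|`, where `mean(hc)` is the mean ΔF/F over the
   middle 3 min of a 5-min home-cage recording, so that a trace that dipped
   below the x-axis is lifted back to the home-cage baseline.
2. **Behaviour-gated metrics.** Behaviour samples are aligned to the
   photometry grid by minimum timestamp difference (TTL-synchronized
   clocks); bouts shorter than 2 s are excluded; per behaviour state the
   package computes duration-normalized AUC, peak frequency (peaks/s) and
   mean peak height, with peaks defined as local maxima above
   `median + 2·SD` of the session's ΔF/F.
3. **PNN quantification.** Image stacks are maximum-intensity projected over
   the top half of each net, binarized with IsoData ("Default")
   thresholding inside the traced ROI, and summarized by *surface
   contiguity* — the fraction of WFA-positive pixels in the largest
   8-connected component — plus density (cells/mm²).
4. **Estimation statistics.** Cohen's d (pooled SD) with 5000-resample
   bootstrap and 95% bias-corrected-and-accelerated (BCa) confidence
   intervals, independently per comparison for multi-region analyses.

Because studies of this kind rarely deposit raw recordings, the
`simulate_*` generators produce every input format with known ground truth
(transient times and amplitudes, bleach parameters, shared motion
artifacts, bout structure, ring fragmentation, true effect sizes), and the
test suite verifies that the pipeline recovers that truth.

## Worked example

```r
library(fiberpnn)

sim <- simulate_session(photom_sim_config(duration_s = 300, n_events = 30, seed = 42))
hc  <- simulate_session(photom_sim_config(duration_s = 300, event_rate_hz = 0.05, seed = 43))
beh <- simulate_behavior(300, mean_bout_s = 8, seed = 44)

pair  <- deinterleave(sim$session)
trace <- baseline_correct(process_dff(pair),
                          process_dff(deinterleave(hc$session)))
trace
#> dff_trace: 6000 samples over 300.0 s (offset +0.0496)

eps <- extract_epochs(align_behavior(beh$track, trace$time_s), min_bout_s = 2)
str(trace_metrics(trace, eps)[1:4])
#> List of 4
#>  $ auc_total               : num 14.9
#>  $ auc_per_state           : Named num [1:2] 0.0501 0.0496
#>   ..- attr(*, "names")= chr [1:2] "freezing" "moving"
#>  $ peak_frequency_per_state: Named num [1:2] 0.161 0.196
#>   ..- attr(*, "names")= chr [1:2] "freezing" "moving"
#>  $ mean_peak_height        : num 0.097
```

The trace was lifted by the baseline offset (+0.0496), so peak heights —
absolute ΔF/F at each maximum — sit near 0.10 for 5% transients riding on
that offset. The per-state AUC is in ΔF/F units (area divided by summed
state duration). The session yields 55 detected peaks for 30 injected
transients: this session also contains simulated motion artifacts whose
residuals, plus the noise floor, cross the data-driven threshold — the
behaviour-state *contrast* in peak frequency is the quantity of interest,
not the raw count.

```r
pn   <- simulate_pnn_image(fragmentation = 0.3, seed = 7)
mask <- binarize_default(project_top_half(pn$stack), roi = pn$truth$rois[[1]])
contiguity(mask)$fraction
#> [1] 0.9614035  # equals pn$truth$true_contiguity exactly

g <- simulate_two_groups(14, 14, true_d = 0.8, seed = 9)
bootstrap_effect(g$g1, g$g2, seed = 10)
#> Cohen's d = 1.016, BCa 95% CI [0.069, 1.756] (5000 resamples)
```

## Command line

```sh
./exec/fiberpnn run --config inst/extdata/pipeline-config.json --seed 7 --out out/
./exec/fiberpnn simulate --kind pnn --seed 3 --out fixtures/
./exec/fiberpnn effects --data values.tsv --resamples 5000 --ci 0.95 --seed 7
```

`run` executes simulate → ΔF/F → epochs → metrics → effects and writes a
`manifest.json` with parameters, derived seeds and an MD5 checksum per
output; reruns with the same seed are bit-identical.

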