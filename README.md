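# mesochoice

Simulation and analysis toolkit for studying how perceptual **choice**
signals — together with stimulus, movement and sustained-attention
signals — are distributed across the areas of mouse posterior cortex in
widefield calcium imaging. It is aimed at systems neuroscientists who
analyze mesoscale imaging from decision-making tasks and want a tested,
self-contained pipeline they can exercise end to end on synthetic sessions
with known ground truth.

The package covers:

* a **synthetic-session generator**: per-trial dF/F tensors over a
  procedurally drawn 10-area atlas (V1, PM, AM, A, SSt, RL, SSb, AL, L,
  RS), with planted low-dimensional signals (stimulus-evoked, movement-
  and saccade-locked, sustained attention, and a weak choice signal with
  random-sign loadings distributed across all areas), plus a matching
  behavioral trial table (wheel movements, saccades, pupil-based attention
  tertiles, psychometric left/right choices over 13 difficulty levels);
* **preprocessing**: per-trial dF/F normalization, zero-phase band-pass
  (0.1–8 Hz) with overlapping spatial binning, wheel/saccade event
  detection, the stimulus-evoked pupil-change metric, and dual-wavelength
  hemodynamic correction by regression of the low-passed
  calcium-independent channel;
* **seeded localized NMF**: SVD compression followed by a semi-NMF whose
  non-negative spatial maps pay an exponential-decay localization penalty
  (`1 - D`) outside their seeding area, with a greedy rank line search to a
  target explained variance and a 75% localization threshold;
* **state axes and d′**: for each task variable, balanced trial groups
  under the study's inclusion rules, the per-time discrimination axis
  S(t) = normalize[(⟨A(t)⟩ − ⟨B(t)⟩)/σ_AB(t)] with pooled SD
  σ_AB = √(½(σ_A² + σ_B²)), held-out d′ curves by five-fold
  cross-validation (axes fit on 20% of trials), axis stability
  autocorrelograms, area-restricted axes, and Gram–Schmidt
  orthogonalized d′;
* **representational geometry**: pairwise axis angles folded to [0°, 90°],
  a bootstrap surrogate null for the angle between independent axes,
  average-linkage clustering, the Spatial-Distribution Index
  SDI(%) = (d′_global / max_i d′_i − 1)·100, five-area-group d′
  coordinates, two-segment piecewise-linear fits of d′ ramps, and the
  pixel-wise d′ negative control;
* a **recurrent decision model**: a 50-unit ReLU Elman network (3 inputs:
  left stimulus, right stimulus, binary attention; 25 frames; batch-norm;
  3-class softmax head) trained with Adam on choices simulated from the
  lapse-logistic psychometric curve
  P_left(θ) = σ(αθ)(1 − λ) + λ/2 (λ = 0.2, α = 2/90 or 5/90 per degree
  for low/high attention), with the same state-axis machinery applied to
  its hidden units.

## Worked example

```r
library(mesochoice)

atlas <- make_area_atlas(48, 48, seed = 1)
sim   <- simulate_session(atlas, n_trials = 400, seed = 1)
dec   <- loca_nmf(sim$session, rank_per_area = 2, svd_ev = 0.9)
dec
#> decomposition: 20 components over 10 areas, EV = 0.079, min loc = 0.82

for (v in c("stimulus", "wheel", "saccade", "attention", "choice")) {
  pair <- build_group_pair(sim$trials, v, fs = 30, pre_stim = 1,
                           n_frames = 90, seed = 2)
  print(dprime_curve(dec, pair, seed = 3,
                     baseline_time = if (v == "attention") 0 else NULL))
}
#> dprime_curve 'stimulus':  31 frames, peak |d'| = 3.46 at t = 0.00 s (n = 400/group)
#> dprime_curve 'wheel':     46 frames, peak |d'| = 0.84 at t = 0.13 s (n = 17/group)
#> dprime_curve 'saccade':   46 frames, peak |d'| = 0.67 at t = -0.13 s (n = 31/group)
#> dprime_curve 'attention': 61 frames, peak |d'| = 1.45 at t = 1.27 s (n = 134/group)
#> dprime_curve 'choice':    46 frames, peak |d'| = 0.79 at t = 0.43 s (n = 143/group)
```

The stimulus axis separates strongly right after onset; movement and
saccade axes peak around their events; the attention axis (onset value
imposed at zero) builds up across the trial; the choice axis reaches
d′ ≈ 0.8 around movement time. The choice ramp and its spatial spread:

```r
pair <- build_group_pair(sim$trials, "choice", 30, 1, 90, seed = 2)
cur  <- dprime_curve(dec, pair, seed = 3)
piecewise_fit(cur)
#> piecewise_fit: slopes 0.135 -> 1.024 d'/s, knot -0.209 s (R2 = 0.87)

area_dp <- vapply(atlas$area_names, function(a)
  max(abs(area_axis(dec, pair, a, seed = 4)$curve$dprime)), numeric(1))
sdi(max(abs(cur$dprime)), area_dp)
#> [1] 20.9
```

The choice d′ ramps slowly before movement onset and ~7× faster after the
knot at −0.21 s; no single area reaches the global d′ (best area 0.65),
and the positive SDI (≈21%) quantifies the gain from pooling all ten
areas — the planted choice signal is genuinely distributed. A pixel-wise
d′ map on the same session (`pixelwise_dprime`) stays near the noise
floor, the negative control showing the signal is invisible without
spatial integration.

`run_pipeline(default_config(...))` chains all stages (simulate →
preprocess → decompose → axes → geometry → optional RNN) and returns one
report; `write_report()` serializes it to JSON.

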