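---
title: "Models and methods behind mesochoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mesochoice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `mesochoice`, the
assumptions behind them, the tunable parameters and their defaults, and
the design choices made where the methodology was genuinely open. It
states no empirical result beyond what the package's tests and the
acceptance script themselves compute.

## The scientific setting

Head-fixed mice perform a two-alternative forced-choice (2AFC) orientation
discrimination: two oriented gratings appear left and right of the
midline, and the animal reports which is closer to a target orientation by
turning a wheel. Each trial has a 1 s pre-stimulus baseline, a 1.5 s
open-loop period in which wheel turns do not yet move the stimulus, and a
closed-loop period until the response. Difficulty is the signed
orientation difference θ between the two stimuli; a session spans 13
levels uniform on [−90°, +90°]. Simultaneously, widefield calcium imaging
covers ~10 visual, parietal, somatosensory and retrosplenial areas of
posterior cortex at 30 frames/s, and pupil video provides a
trial-by-trial arousal/attention proxy.

The analytical question is *where* the choice signal lives: is it
concentrated in one area, or weakly and redundantly distributed across
many? The package's machinery — localized NMF to get area-assigned
components, state axes to get cross-validated discriminability (d′), and
geometry statistics to compare axes — exists to answer that question, and
the synthetic-data generator exists so every stage can be validated
against planted ground truth.

## The synthetic-session generator

### What it emulates

Widefield dF/F data are spatially smooth and effectively low-rank: each
area's signal is dominated by a few coactivation patterns. The generator
therefore builds, per area, a small number of non-negative spatial
*modes* (default 2: a broad bump plus a random sub-bump; a "flat"
indicator variant exists for analyses that need homogeneous per-pixel
amplitudes). Ongoing activity is each mode times a smoothed Gaussian
temporal trace (`bg_sd`, default 0.02 dF/F), plus iid per-pixel noise
(`noise_sd`, default 0.02) and an optional slow shared fluctuation
(`global_amplitude`, default 0.002) that mimics global co-fluctuations
(vascular/arousal artifacts).

Every planted task signal is a unit-norm mixture of modes times a
temporal kernel times a per-trial condition factor:

* **stimulus** — V1 modes, step kernel during the open loop;
* **wheel / saccade** — parietal+somatosensory (resp. V1/RL) modes,
  raised-cosine transients locked to the event times written into the
  trial table;
* **attention** — all areas, a sustained kernel rising over 0.3 s after
  stimulus onset and holding, scaled by the trial's latent pupil state
  (the metric it emulates is the stimulus-evoked pupil change, which is
  zero in the pre-stimulus baseline by definition);
* **choice** — random-sign loadings on 60% of the modes of *all ten*
  areas, a ramp starting 0.5 s before the movement and saturating 0.3 s
  after it, signed by the trial's left/right choice.

Amplitudes are *projected* dF/F along the unit spatial pattern, so
downstream d′ scales directly with them. The defaults (stimulus 0.25,
wheel 0.15, attention 0.08, saccade 0.06, choice 0.05 ≈ stimulus/5) were
calibrated once so that the cross-validated d′ of the weak variables lands
in the 0.5–1.5 range at a 400-trial session — the regime in which the
distribution question is interesting — while per-pixel amplitudes stay in
the realistic few-percent dF/F range. Two factors of ≈2 enter that
calibration and are worth knowing about: the diagonally normalized state
axis is suboptimal when components are correlated (see below), and axes
fit on 20% of trials shrink held-out d′ at desk-scale trial counts.

Behavior is generated consistently with the kernels: lognormal movement
latencies (median 0.8 s), movement direction deterministic given the
choice (choices are *measured* from the first movement direction), sparse
Poisson saccades, a latent Gaussian pupil state whose tertiles define the
high/mid/low attention labels, and left/right choices drawn from the
lapse-logistic psychometric curve

$$P_{\text{left}}(\theta) = \frac{1}{1+e^{-\alpha\theta}}(1-\lambda) + \frac{\lambda}{2}$$

with λ = 0.2 and slope α = 2/90 (low attention) or 5/90 (high attention)
per degree. At θ = 0 the rewarded side is a fair virtual coin (the
behavioral task leaves 0° undefined; this is configurable by reading the
`correct` column rather than the generator). Under the 13-level discrete
design these parameters give exact expected accuracies of 68.3% (low) and
79.6% (high); under a continuous uniform difficulty distribution the same
parameters give 67.3% and 79.0%, matching the design's nominal 67%/80%
average performance targets.

### What it does not emulate

No realistic hemodynamics (the correction module is tested against a
parametric shared artifact), no eye-video simulation (saccades are event
lists), no inter-areal lag structure, no slow nonstationarity across a
session, and no Allen-atlas geometry (the atlas is a jittered Voronoi
partition — alignment is out of scope and only disjointness and
contiguity matter). Passing tests therefore demonstrate correctness of
the *analysis machinery* under the stated generative assumptions, not
performance on real recordings.

## Preprocessing

* **dF/F** — per trial, the scalar baseline F0 is the grand mean of the
  trial's raw tensor over pixels and frames; output is (I − F0)/F0.
* **Band-pass** — 0.1–8 Hz, applied as a zero-phase Butterworth-magnitude
  response in the frequency domain (equivalent in magnitude to
  forward–backward IIR filtering). Zero phase matters: d′ *timing* claims
  (slope-change times relative to movement onset) must not be biased by
  filter delay.
* **Binning** — overlapping mean pooling (130 µm bins, 50% overlap),
  mostly-outside-window bins dropped, edge bins truncated; the bin-level
  atlas takes each bin's majority area label. 50 fps data are resampled
  to 30 fps after low-passing.
* **Wheel events** — velocity zero-crossings followed by an excursion
  beyond a fixed threshold (default 20, in trace units: the printed
  threshold's unit is ambiguous, so it is configurable).
* **Saccades** — the published adaptive elliptic velocity thresholding
  lives in proprietary tracking code; we use a velocity-magnitude
  threshold at k·MAD (k = 6 default). The rejection filters are
  implemented exactly as stated: candidates lasting ≤ 60 ms or smaller
  than 1.5° are discarded.
* **Pupil metric** — pA = max pupil area over the open loop (0, 1.5 s]
  minus the mean over the second before onset, z-scored across the
  session's trials.
* **Hemodynamic correction** — per pixel, both channels are detrended to
  ΔF/F via a linear fit F(t) ~ at + b; the calcium-independent (violet)
  channel is low-passed at 5 Hz (6th-order Butterworth, zero-phase — the
  IIR family is unstated, Butterworth assumed and recorded here) and
  regressed onto the blue channel; corrected = blue − (c·violet_lp + d),
  then low-passed at 8 Hz. A constant violet channel skips the regression
  with a warning (c = 0).

## Localized NMF

The tensor (trials concatenated) is SVD-compressed to 99% of its sum of
squares (`svd_ev`; an explicit `svd_rank` cap exists for noise-dominated
synthetic data whose structured part is known to be low-dimensional).
Each of the 10 areas contributes a seeding mask with distance field D = 1
inside the area and exp(−dist/decay_length) outside; the localization
penalty is 1 − D. `decay_length` defaults to 15% of the mean equivalent
area diameter, approximately the correlation length of the generator's
smooth modes.

The factorization is a semi-NMF — spatial maps A ≥ 0, temporal components
C unconstrained (dF/F is signed) — fit by alternating least squares on C
and penalized HALS on A, with all products carried in the compressed
space. A component's penalty weight starts at zero and is raised
geometrically whenever less than 75% (`loc_threshold`) of its spatial
energy lies within its seed's D > 0.5 support; because the penalty
vanishes inside the seed region, this always drives components toward
their areas. The rank line search is greedy: starting from one component
per region, components are added one at a time to the region with the
largest residual sum of squares until the explained-variance target is
met or a per-area cap is reached (then the best fit is returned with a
warning and `converged = FALSE`). This greedy scheme is a documented
simplification of the full line-search schedule of the original
localized-NMF solver; initialization is deterministic (squared seed
shapes), so decompositions are bit-reproducible.

Explained variance follows the per-pixel variance convention: variance of
the partial reconstruction over concatenated time, summed over pixels,
divided by the summed per-pixel variance of the original. Note that an EV
*target* is meaningful on data whose variance is dominated by structure
(real widefield data, or noiseless planted fixtures); on synthetic
sessions dominated by iid pixel noise no localized factorization of
sensible rank can reach 99%, so the pipeline default fixes
`rank_per_area = 2`, the generative rank.

## State axes and discriminability

For a variable's two balanced trial groups A and B, the per-time axis is

$$S(t) = \left\| \frac{\langle A(t)\rangle - \langle B(t)\rangle}{\sigma_{AB}(t)} \right\|, \qquad
\sigma_{AB}(t) = \sqrt{\tfrac{1}{2}(\sigma_A^2(t) + \sigma_B^2(t))}$$

per component, normalized to unit length (the ‖·‖ notation is read as
unit-norm normalization of the ratio vector). Components with zero pooled
SD are zeroed with a warning; an all-zero vector is an error. Projections
P_i(t) = S(t)·C_i(t) are plain dot products with no mean-centering in
time. Held-out d′ divides the difference of mean projections by their
pooled SD; cross-validation uses 5 folds whose *training* sets are
disjoint 20% blocks, matching the study's unusual 20/80 split. Because
the axis normalizes each component independently, it ignores noise
*correlations* between components; with overlapping within-area
components this costs roughly a factor of two in d′ relative to the
optimal linear readout. We keep the method as defined — the package
reproduces the method, not an improvement of it.

Time-independent (window) axes average the per-component ratio over the
window *before* renormalizing (per-component-then-average; the
alternative order is not distinguishable from the method description, and
this one keeps each component's ratio interpretable). Axis stability uses
a backward three-frame smoothing window and cosine similarity between all
time pairs; the reference time t* for time-independent sensory, movement
and attention axes is the center of the longest contiguous run whose mean
off-diagonal stability exceeds 0.8 (the "largest stability cluster"
criterion is unstated; 0.8 is configurable).

Group rules (inclusion, alignment, balancing by subsampling the larger
group to the smaller's size) follow the study's definitions, with two
adaptations for short synthetic trials: the no-movement/no-saccade
horizon (5 s) truncates to the trial length, and random alignment frames
for the no-event control groups are drawn uniformly in (0.5 s, horizon]
once per trial under the pair's seed. For the stimulus variable the
"no-stimulus" group is the same trials with the alignment shifted 0.5 s
earlier (window covering the final second of the randomized inter-trial
interval), which is the one deliberate exception to the no-overlap rule
between groups. The sustained-attention d′ curve has its stimulus-onset
value subtracted ("imposed zero discriminability at onset") — an
interpretation of the method description, flagged as such; it is exactly
correct for signals absent in the baseline, and conservative otherwise.

## Geometry statistics

Angles between axes use the absolute cosine, folding to [0°, 90°] (axes
are directionless). The independence null resamples an axis's *own*
weights with replacement (2000 surrogates), renormalizes, and takes the
2.5/97.5 percentiles of the angle to the original — the bootstrap as
stated, not a rotation null; the two differ when the weight distribution
has nonzero mean, which is why the null is computed from the data rather
than assumed. SDI follows the printed formula
(d′_global/max d′_i − 1)·100. Its descriptive upper bound of (N−1)·100%
for N equally and independently contributing areas is documented but not
asserted: under independent Gaussian noise, pooled d′ scales as √N, which
implies (√N−1)·100% instead; the formula itself is implemented exactly as
printed and the bound treated as rhetorical. The five-group d′ space uses
dorsal (PM, AM), ventral (L), parietal (A, AL, RL), somatosensory (SSt,
SSb) and retrosplenial (RS) unions, excluding V1.

Piecewise fits are continuous two-segment least squares with one free
knot: for a candidate knot the segment fit is closed-form, and the knot
is located by a coarse grid followed by golden-section refinement. The
fit window runs from −1 s before movement onset to the earliest time the
curve reaches 95% of its post-movement maximum. Flat curves (R² < 0.1)
are returned with a `degenerate` flag since their knot is unconstrained.

The pixel-wise d′ control computes d′ per pixel and time with no spatial
integration. Its role is the negative control for distribution claims: a
signal planted at ~0.1 d′ per pixel across hundreds of pixels is
invisible in the pixel map (maxima at the noise floor) while the
component-space axis, which pools spatially, exceeds d′ = 1 on identical
data. The acceptance test for this contrast uses 4000 trials of a
32×32-pixel session with one flat mode per area and equal-magnitude
random-sign area loadings — sizes chosen so that both sides of the
contrast have comfortable statistical margins on one CPU in about a
minute.

## The recurrent decision model

A single Elman recurrent layer (50 ReLU units) receives three channels
over 25 frames: left and right stimulus (zero for the first 10 frames,
then constant at angle/90, with N(0, 0.1) noise at every frame — the
printed noise "amplitude" is interpreted as an SD) and a noiseless binary
attention level present from the first frame. The hidden sequence passes
through batch normalization (placement is stated only as "a batch
normalization layer"; we normalize the recurrent output sequence over
batch and time per unit) into a dense 3-class softmax head (left, right,
no-choice). The loss is the categorical cross-entropy at the
stimulus-presentation frame (target no-choice, which anchors the output
before evidence arrives) plus at the final frame (target the simulated
choice). Training uses Adam (25 epochs, batch 640) on choices drawn from
the psychometric generator; 6400 trials per difficulty level is the
study-scale set, and 640 per level per attention state is the desk-scale
default used by the tests and the acceptance run. After training, the
inference batch-norm statistics are frozen on the full training set
(short schedules leave the exponential running average biased). The
recurrent matrix uses the standard orthogonal initialization for
recurrent layers; gradients are norm-clipped at 5. The learning rate
(unstated in the protocol, so a package choice) follows a cosine decay
from 2e-3 to 1e-4 over the epochs: at desk-scale training-set sizes a
constant rate leaves the final hidden-representation geometry —
e.g. the angles between per-difficulty choice axes — noticeably variable
across training seeds, while the decayed schedule lets the network settle
into a consistent solution at the same epoch and batch budget. The whole
model, loss and optimizer are implemented in base R matrix operations and
the parameter count (2953) is asserted in closed form.

Because training targets are stochastic labels, the cross-entropy
optimum is the conditional choice probability: a trained network's
softmax output reproduces the full lapse-logistic curve, including the
lapse plateaus, even though its argmax response is nearly deterministic.
`rnn_trace` therefore exposes both readings of "the continuous output
determines the choice": the argmax (default; used for axis analyses,
where sampled labels would only add estimation noise) and sampling from
the softmax (which reproduces lapse-like stochastic responding).
Hidden-unit analyses reuse the axes module verbatim with frames as the
clock. Per-difficulty choice axes are computed on the *nonzero*
difficulty levels: at θ = 0 the response carries no stimulus information
(and, for sampled choices, is independent of the network state), so no
choice axis is defined there — mirroring the behavioral task, whose
hardest condition is a small but nonzero orientation difference.

## Numerical choices and degenerate inputs

Unit normalization errors below an L2 norm of 1e−12; zero pooled SDs are
zeroed with warnings rather than propagating NaN; empty trial groups
raise errors naming the failed rule; the NMF line search warns and
returns its best fit when the EV target is unreachable at the rank cap;
piecewise fits flag flat curves; a constant violet channel skips the
hemodynamic regression with c = 0. All stochastic operations take
explicit integer seeds and restore the caller's RNG state, so sessions,
decompositions (which are deterministic given inputs), reports and
trained networks are reproducible bit-for-bit given (config, seed).

## Problem sizes used by the test suite

Unit tests run on 40×40-pixel atlases with 8–240 trials; the oracle
equivalence of the d′ pipeline uses 20 seeds of 3000-trial Gaussian
component clouds; the pixel-vs-axis contrast uses one 4000-trial session;
the network tests use a 6-epoch smoke schedule plus one full 25-epoch
desk-scale training in the acceptance suite. These sizes were chosen as
the smallest at which each claim's statistical margins are comfortable.

## Known limitations

The generator's noise is white in time and space apart from the planted
structure, so real-data nuisances (hemodynamic residuals, motion,
vignetting, slow drift) are only covered by the dedicated correction
tests; the greedy rank line search can over-allocate components to
high-variance regions on strongly heteroscedastic data; the diagonal
normalization of S(t) is suboptimal under correlated components (kept by
design, see above); and the RNN analyses depend on a well-calibrated
trained network — severely under-trained networks have biased choices at
low difficulties and their per-difficulty axes are estimation-noise
dominated.
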