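---
title: "Neuro-fuzzy feature selection for steering-based drowsiness detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuro-fuzzy feature selection for steering-based drowsiness detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steerwake)
```

## The problem

Drowsy drivers steer differently from alert ones. Awake lane keeping is a
stream of frequent small corrections around the lane centre; as vigilance
drops, the wheel is left to drift slowly and is then yanked back in sparse,
large corrective jerks. steerwake detects this signature from two channels —
steering-wheel angle (degrees, 60 Hz) and steering velocity (deg/s, obtained
by first differencing when not recorded) — annotated per sample with the
Karolinska Sleepiness Scale (KSS, 1–9). KSS 1–6 define the awake class,
8–9 the drowsy class, and the transitional 7 is discarded so the two classes
stay well separated.

The core contribution is the *feature selector*: a hybrid of filter and
wrapper selection in which four filter statistics per feature are fused by a
Takagi–Sugeno fuzzy system into a single importance degree, and the fuzzy
system's parameters are themselves trained — by particle swarm optimization
(PSO) — against the validation accuracy of the downstream classifier.

## Processing model

**Windowing and detrending.** The signals are cut into 3-s windows
(180 samples at 60 Hz) with 50% overlap (90 samples), starting at sample 0
with 0-based half-open indexing `[start, start + W)`; trailing samples that
do not fill a window are discarded. Each channel is detrended by subtracting
its own within-window mean. On a curved track the window mean carries the
road-geometry component of the steering angle, so mean removal isolates the
driver's corrective activity. Detrending is strictly per analysis window —
the same window the features see — not via a reconstructed continuous
signal. A window's label is the binarized KSS at its centre sample; the
centre was chosen because labels are assigned per driving period and the
centre minimizes mislabeling at period transitions. Both choices were open
design decisions.

**Features.** Each window yields 36 features, 18 per channel
(`I01a..I18a` for angle, `I01v..I18v` for velocity): range, standard
deviation, energy, zero-crossing rate (ZCR), the three quartiles, Katz
fractal dimension, skewness, kurtosis, sample entropy, Shannon entropy, and
— from the one-sided Hann-tapered periodogram — spectral variance, spectral
entropy, spectral flux, spectral centroid, dominant frequency and mean PSD.
These one-line descriptions admit many concrete definitions; the package
fixes the most common conventions in this literature and treats them as part
of its contract:

* sample entropy: `m = 2`, `r = 0.2·SD`, Chebyshev distance, self-matches
  excluded; when no template pairs resolve (`A = 0` or `B = 0`, including
  constant windows where `r = 0`) the maximum resolvable value
  `-ln(2/((W-m-1)(W-m)))` is returned, preserving the regularity ordering
  without infinities;
* Shannon entropy: 16 equal-width amplitude bins, log base 2, `0·log 0 := 0`;
* kurtosis is non-excess (`m4/m2²`); skewness is `m3/m2^{3/2}`;
* spectral flux: squared difference of the L1-normalised magnitude spectrum
  against the previous window of the same recording, 0 for the first window;
* dominant frequency excludes the DC bin (windows are mean-removed, so DC is
  numerically ~0 but not exactly);
* quartiles use linear interpolation.

Features are min-max normalised to [0, 1] with bounds fitted on the training
split only; out-of-range validation values are clipped. A constant training
feature is flagged and maps to 0.5, keeping the fuzzifier input defined —
such features carry near-zero filter indexes and are never selected anyway.

**Filter indexes.** For each feature four statistics against the binary
label are computed: the Fisher score `(μ₁−μ₀)²/(σ₁²+σ₀²)`, the Pearson
(point-biserial) correlation, the Welch t statistic
`|μ₁−μ₀|/√(σ₁²/n₁+σ₀²/n₀)`, and plug-in mutual information over a 10-bin
equal-width discretisation (bits). Degenerate perfect separators (zero
within-class variance with distinct means) receive a large cap (10⁶) so they
rescale to 1. Each index vector is then min-max rescaled across the 36
features to [0, 1] — the membership functions live on the unit domain, so
some normalisation is forced; min-max across features is our choice, and a
constant index vector maps to all-0.5.

**Fuzzy fusion.** Each of the four scaled indexes carries three Gaussian
membership functions Low/Medium/High, giving the full 3⁴ = 81-rule base.
Rule *l* reads "if Fisher is A₁ and correlation is A₂ and t is A₃ and MI is
A₄ then ID = αₗ" with singleton consequents αₗ ∈ {0, 0.5, 1}. Firing
strengths use the product t-norm and the output is the firing-strength
weighted average — the canonical zero-order Takagi–Sugeno evaluation, which
needs no defuzzification step and is smooth in the parameters (the min
t-norm alternative is not PSO-friendly). Gaussians are strictly positive, so
the weighted average is always defined and lies in [0, 1]. Features with
ID *strictly* above the threshold (default 0.5) are selected.

Untrained defaults place the three Gaussians at centres 0/0.5/1 with common
width 0.2125, which makes neighbouring functions cross near membership 0.5
on the unit domain; the exact published initial widths are not available, so
the initialiser is config-exposed. Consequents are initialised by an
antecedent-majority heuristic (≥3 High antecedents → α = 1, ≥3 Low → 0,
otherwise 0.5); how the 81 consequents were assigned in the original design
is unstated, so they are included in the training search rather than fixed.

**PSO training.** The search position is the flattened parameter vector of
length 105: 12 centres in [0, 1], 12 widths in [0.05, 1], and 81 consequents
relaxed to [0, 1]. Decoding sorts each input's centre triple (restoring
L ≤ M ≤ H) and snaps each relaxed consequent to the nearest of {0, 0.5, 1},
ties upward. The objective is the wrapper error on a stratified 70/30
validation split: select features on the training part, fit the SVM on the
selected columns, and score the mean of ½(ŷ−y)² over validation samples —
half the misclassification rate for binary labels; an empty selection costs
a penalty of 1. The swarm follows the standard global-best update
`v ← Wv + C₁R₁(pbest−x) + C₂R₂(gbest−x)` with per-coordinate uniform random
factors, velocities clamped to ±20% of each box width and positions clamped
to the box. Defaults are population 50, C₁ = C₂ = 2, constant inertia 0.95;
iteration budget, stall-based stopping (20 stalls below 10⁻⁶), clamping and
the split protocol are all config-exposed since no published values exist
for them. Particle 1 is warm-started at the untrained defaults, so the
trained objective can never exceed the untrained one. Filter indexes of the
training split do not depend on the fuzzy parameters and are precomputed
once; classifier fits are cached per selected subset, which makes training
cheap because many particles select identical subsets.

A caution on the swarm coefficients: constant inertia 0.95 with C₁ = C₂ = 2
lies outside the classical stability region (C₁+C₂ > 2(1+W)), so the swarm
explores aggressively and relies on clamping and the pbest/gbest memory
rather than on contraction. That is harmless for the selector — the
objective is a step function of the selected subset, plateau-dominated, and
the warm start already sits near the optimum — but it refines poorly on
smooth landscapes. The package's sphere-function sanity harness therefore
runs the same update rules at convergent settings (inertia 0.7,
C₁ = C₂ = 1.5), where 50 particles reach 10⁻³ on the 10-D sphere well within
100 iterations.

**Classification and evaluation.** The wrapper and final classifier is a
soft-margin RBF SVM (C = 1, bandwidth 1/(d·var), both config-exposed; the
published description names only a binary kernel SVM). Features arrive on a
common [0, 1] scale, so no further standardisation is applied. Evaluation
takes drowsy as the positive class: confusion counts, accuracy
`(TP+TN)/(TP+FP+TN+FN)·100`, and ROC/AUC by sweeping the decision-score
threshold with trapezoid integration (equal to the normalised Mann–Whitney
U, which the tests assert).

## The synthetic generator

No public steering corpus with per-sample KSS annotation exists, so
`generate_trace()` plants the behavioural structure the detector targets.
The angle is a sum of three parts: a sinusoidal track-curvature component
(default 20° amplitude, 30 s period — a gently winding course), a
regime-dependent correction process, and Gaussian measurement noise
(0.1°). In the awake regime (KSS ≤ 7) corrections arrive as a Poisson
process (default 4/s) with small normal amplitudes (0.5°) and relax
exponentially (τ = 0.5 s), producing frequent zero crossings about the track
line. In the drowsy regime (KSS ≥ 8) the wheel drifts linearly (2 deg/s,
random sign) and Poisson-timed jerks (0.25/s, ~8°) snap it back across the
track line — the sawtooth-like low-ZCR/high-amplitude signature. KSS is a
monotone step profile, by default an even ramp through all nine levels;
per-sample assignment is the finest-grain equivalent of per-period labels.
These defaults were chosen once as plausible magnitudes for simulator
driving and are not tuned.

What the generator does *not* emulate: vehicle dynamics, road-surface
torque feedback, driver individuality, non-monotone vigilance fluctuations,
or any correlation structure between drowsiness and track position. Tests
passing on this substrate demonstrate that the pipeline recovers planted
structure of the kind reported for real drowsy steering — not that the
published accuracy figures transfer, which would require the original
simulator data.

`generate_feature_bench()` sidesteps the signal chain entirely: it plants
`n_informative` columns shifted by `effect_size` standard deviations in the
drowsy class among label-independent noise columns, for selector-only
experiments with known ground truth.

## Numerical and degenerate-input choices

* All-zero (constant) windows: range/SD/energy/ZCR/ShEn are 0, sample
  entropy returns its cap, spectral features are defined as 0.
* ZCR uses the strict product test `x_k·x_{k+1} < 0`; a sample landing
  exactly on zero contributes no crossing.
* Equal-width binning uses `findInterval` with the right edge closed.
* ROC points are emitted once per distinct score (tied scores collapse).
* Seeds: every stochastic entry point takes an explicit seed and restores
  the caller's RNG state; the pipeline fans one master seed out to stage
  seeds via fixed offsets, so reruns are bit-identical.

## Problem sizes used in the test-suite experiments

Selector-recovery experiments run 36 features with 5 informative at effect
size 2 and n = 2000 windows over 20 seeds, training with 8 particles for up
to 8 iterations: the warm start already selects high-ID features, so the
swarm's job is subset refinement and these small budgets are ample (the
gbest trace typically flattens within 2–3 iterations). The end-to-end demo
simulates 300 s of driving (≈199 windows). The sphere harness runs the
published population (50) and a 100-iteration budget in 10 dimensions.

## A worked example

```{r example, eval = FALSE}
library(steerwake)

bench <- generate_feature_bench(n_samples = 2000, n_features = 36,
                                n_informative = 5, effect_size = 2,
                                seed = 4)
bench$informative
#> [1]  5 27 31 34 36

trained <- optimize_selector(bench$x, bench$y,
                             pso_config(n_particles = 10, max_iter = 10,
                                        stall_iter = 5, seed = 7))
which(trained$selection$selected)
#> [1]  5 27 31 34 36

cols <- which(trained$selection$selected)
sp <- trained$split
fit <- train_classifier(bench$x[sp$train, cols], bench$y[sp$train])
evaluate_classifier(fit, bench$x[sp$val, cols], bench$y[sp$val])
#> Evaluation (drowsy = positive)
#>   TP 296  FP 2  TN 298  FN 4
#>   accuracy 99.000%  AUC 0.9995
```

## Known limitations

* Exact numeric parity with published feature values is impossible: the
  source descriptions are one line per feature and every estimator detail
  above is this package's own fixed convention.
* The fuzzy selector's advantage over single-index baselines is modest on
  the synthetic bench, where one good index already suffices; the
  acceptance check asserts the ordering (fuzzy ≥ best baseline, median),
  not a margin.
* The plug-in MI estimator is positively biased at small n (≈ (bins−1)/(2n
  ln 2)); with n ≥ 1000 windows this is negligible relative to planted
  effects.
* The SVM is refit per candidate subset during training; for feature
  matrices far larger than the tested sizes, subset caching mitigates but
  does not remove the wrapper cost.
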