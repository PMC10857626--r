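---
title: "Methods: the harpipe activity-recognition pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the harpipe activity-recognition pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harpipe)
```

This vignette is the package's account of its science: the models and
procedures each stage implements, the assumptions behind them, the
tunable parameters and why their defaults are what they are, what the
synthetic generator does and does not emulate, and the numerical and
design choices made where the method left room.

## Problem setting

Wearable devices log multichannel streams — tri-axial accelerometer,
gyroscope and magnetometer, sometimes audio — at tens of Hz, with an
activity label per sample. The task is to classify short spans of the
stream into locomotion activities (walking, running, climbing,
standing, ...) and localization context. The pipeline follows the
classic hand-crafted-features-plus-sequence-model design: denoise,
segment into overlapping windows, extract per-window features, select
and rebalance them, then classify short sequences of windows with an
LSTM.

## Denoising

Raw streams are low-pass filtered with a Chebyshev Type I design,
whose analog prototype magnitude is
$|H(\omega)| = (1 + \varepsilon^2 T_n^2(\omega/\omega_0))^{-1/2}$ with
$\varepsilon = \sqrt{10^{rp/10} - 1}$. The passband ripple is the one
stated design constant, `rp = 0.5` dB. The order and cutoff are free
parameters: the defaults, order 4 and cutoff at 0.2 of Nyquist (5 Hz
at 50 Hz sampling), keep all plausible gait fundamentals and their
first harmonics (≤ 7 Hz for a 3.5 Hz run) in the passband while
removing wideband sensor hiss. Both are configurable
(`filter.order`, `filter.cutoff_hz`).

The digital realization (`signal::cheby1`, bilinear transform) is
applied **forward and backward** (`denoise()`), squaring the magnitude
response and cancelling phase. A single-pass IIR filter would delay
and skew peaks, which would bias the step detector's peak timings;
zero-phase filtering avoids that at the cost of deviating from a
literal single-pass reading of the transfer function. Edges use
odd-reflection padding of three filter orders with steady-state
initial conditions, so a constant channel passes through exactly and
boundary transients are suppressed.

## Windowing

Windows are 100 samples with a step of 50 (50 % overlap) — two seconds
and one second at 50 Hz. Windows are half-open `[start, start + X)`
with 0-based starts; trailing partial windows are discarded, no
padding. Each window's label is the **majority vote** over its
samples, with ties broken lexicographically: the tie rule is arbitrary
but deterministic and dataset-independent, and mixed-activity
transition windows are kept rather than dropped so the window-count
arithmetic `floor((N − X)/step) + 1` stays exact.

The Hamming taper `w(x) = 0.54 − 0.46\cos(2\pi x/(X−1))` is applied
where it belongs — inside the spectrogram — and *not* to segments used
for temporal features: tapering attenuates window-edge samples by up
to 0.08×, which would distort step peaks, warping distances and
moments. `segment(taper = TRUE)` exists for spectral consumers; the
window set stores raw segments by default.

## Locomotion features

All per-window features operate on the acceleration magnitude
$\sqrt{x^2 + y^2 + z^2}$ unless noted, which removes orientation
dependence.

**LPCC.** Linear-prediction coefficients solve the Yule–Walker system
$R a = r$ built from the *biased* autocovariance estimator (its
Toeplitz matrix is positive semi-definite by construction), via
Levinson–Durbin. Cepstra follow the standard recursion
$c_1 = a_1$, $c_j = a_j + \sum_{t=1}^{j-1}(t/j)\,c_t a_{j-t}$ for
$j \le p$, continued with the same sum truncated to the last $p$ terms
for $j > p$. Defaults $p = d = 12$ (`lpc.order`, `lpc.n_cepstra`): a
conventional order for cepstral modeling of quasi-periodic signals,
small enough to be stable on 100-sample windows. Constant windows are
rejected (singular system) and the affected row is dropped with a
logged count.

**DTW reference distances.** Each class's reference pattern is the
element-wise mean of its training windows; each window's feature is
its dynamic-time-warping distance to every reference. The distance is
the classic dynamic program over the grid with squared local cost
$(P_i - R_j)^2$, moves down/right/diagonal, anchored at both ends, and
a terminal square root. Windows and references are z-normalized first
(`dtw.normalize`), so the distances measure *shape* and stay decoupled
from the amplitude information already carried by other features.
References come from the **training split only** — building them from
all data would leak test shape information into the features.

**SSCE.** The scalar magnitude is delay-embedded (dimension `m = 5`,
delay τ = 1); the per-dimension variances of the embedded cloud,
normalized to a probability vector $p$, give the entropy
$-\sum p_i \ln p_i \in [0, \ln m]$. The embedding dimension is the
stated design constant; the delay is not stated anywhere, and τ = 1 is
the natural unit at these window lengths (larger delays would leave
fewer than $2m$ embedded points per window). The statistic is
invariant to rescaling the input, which the tests assert.

**Phase angle.** The printed single-argument arctangent of $y/x$ loses
quadrants; the implementation uses the two-argument `atan2(y, x)`
(degrees, $(-180, 180]$). Because arithmetic means of angles are
ill-defined across the wrap, each window is summarized by the
*circular* mean and circular standard deviation
($\sqrt{-2\ln \bar R}$).

**Moments.** Skewness uses the adjusted Fisher–Pearson sample form;
kurtosis the unbiased-style sample *excess* form (zero for a normal
population). Both are cross-checked in the tests against an
independent implementation (`e1071`, type 2) to 1e-10.

**Spectrogram bands (audio).** When an audio channel is present, the
short-time Fourier transform with Hamming-tapered frames yields
$S(t,f) = |F(t,f)|^2$; each configured band contributes the mean over
frames of $\log(10^{-12} + \text{band power})$. The floor keeps silent
windows finite. Off by default — whether such features entered the
original classifier or served only visualization is unknowable, so
they are optional.

## Localization features

**Step detection.** Peaks of the acceleration magnitude must exceed
$T = 1.1 \times \text{mean}(M)$ and be separated by at least
$D = 0.3$ s. The threshold is stated only as "a proportion of the
signal's amplitude": making it *relative to the mean* makes the count
invariant to uniform scaling and robust to the constant 1 g gravity
offset; 1.1 sits comfortably between the noise floor of a stationary
signal and the crest of a walking oscillation. $D = 0.3$ s caps
cadence at ≈ 3.3 steps/s, above fast running. When two candidate
peaks conflict, the taller one wins (greedy, tallest-first) — a
deterministic resolution consistent with cadence gating. Both are
configurable (`steps.t_frac`, `steps.d_seconds`).

**Heading.** $H = \mathrm{atan2}(a_y, a_x) \cdot 180/\pi \bmod 360$,
from the horizontal magnetometer axes only; no tilt compensation.
Per window the pipeline reports circular mean, circular sd, and the
angular range (360° minus the largest gap between sorted angles).
Step counts and headings are computed **per window**, not per
activity bout: classification is per window, so features must be too.

## Feature selection and rebalancing

**RFE** is a fixed loop: with $M$ features and a target of $k$,
exactly $M - k$ iterations each refit the importance oracle on the
survivors and remove the single least-important feature (ties broken
by name, so column order cannot change the outcome). The default
oracle is a seeded random-forest impurity ranking (`ranger`); any
`(features, labels) → named importance` function can substitute. The
per-iteration "model performance" is recorded as stratified 3-fold
accuracy but never used for early stopping. RFE is **opt-in**
(`rfe.enabled`): the default feature bank already omits the families a
selection pass would reject (plain means, percentiles, energies), and
no principled default for $k$ exists, so the pipeline keeps all
features unless told otherwise.

**SMOTE** draws a minority sample $x_i$ uniformly, one of its
$k_{nn} = 5$ nearest same-class neighbors $x_{nn}$ (Euclidean metric
on z-scored features, so no feature dominates by scale), and emits
$x_i + u (x_{nn} - x_i)$, $u \sim U(0,1)$, until every class reaches
its target (default: the majority count). Originals are preserved
verbatim and synthetics appended, so the output is bit-reproducible
under a seed. SMOTE runs on the **training split only**, after the
split — oversampling before splitting would place interpolants of
test points into the training set.

In the assembled pipeline SMOTE operates in *flattened sequence
space*: each training sequence of $L$ window-vectors is flattened to a
single $L \times F$ vector, interpolated, and reshaped. Window-level
synthetic rows would have no temporal ordering to sequence over;
flattening keeps both the interpolation contract and the LSTM's
temporal axis coherent.

## The LSTM classifier

The classifier consumes sequences of $L = 5$ consecutive window
feature vectors (stride 1, never crossing recording boundaries),
labeled by the last window. Nothing in the method fixes the temporal
axis over extracted features; $L = 5$ spans three seconds of signal at
the default windowing, enough to smooth single-window noise without
straddling many bout transitions.

The network is 1 LSTM layer of 64 hidden units (stacked layers are
supported) with a dense softmax head. The loss is mean softmax
cross-entropy plus $\lambda \sum w^2$ over all weight matrices
(biases excluded), $\lambda = 10^{-4}$; optimization is Adam
(lr $10^{-3}$, $\beta = (0.9, 0.999)$), batch 64, a **fixed 50
epochs** with no early stopping. Features are z-scaled with
parameters fitted on the training set only; zero-variance features
are dropped with a warning. Initialization is uniform
$\pm 1/\sqrt{\text{fan-in}}$ with forget-gate biases at 1. The
forward/backward passes are plain R matrix operations; the backward
pass is verified against central finite differences in the unit tests
(single and stacked layers), which is the strongest correctness check
available for hand-written backpropagation. Given (seed, config,
data) a training run is bit-reproducible.

## Evaluation

Confusion counts are row-normalized; "mean per-class accuracy" is the
mean of the normalized diagonal over classes with support, which is
identically macro recall (the tests assert the identity), and overall
accuracy is the trace over the total. Both are always reported: the
two aggregates genuinely differ under class imbalance and published
tables do not always say which one they print. Per-class
precision/recall/F1 define 0/0 as 0 with a warning; zero-support
classes are excluded from macro means. One-vs-rest ROC sweeps the
unique scores as thresholds and integrates by trapezoid, which equals
the normalized Mann–Whitney pair statistic — asserted exhaustively
against a brute-force pair oracle in the tests.

## The synthetic generator

`generate_recording()` emulates the statistical structure the pipeline
assumes: per-activity quasi-periodic acceleration (distinct
fundamental frequency and amplitude per class, harmonics decaying as
$1/h$, random phase per bout), a constant 1 g gravity offset on the
z-axis, additive Gaussian wideband noise, a magnetometer that is a
unit horizontal field rotated by a per-class heading behavior (fixed,
random-walk, or sweep), and per-bout labels. The default bank —
standing (static), climbing (1 Hz), walking (2 Hz), running (3.5 Hz)
— keeps all fundamentals inside the default filter passband so
denoising cannot erase the class signal. `generate_imbalanced_table()`
produces Gaussian class clusters with exact, heavily skewed counts
(majority:minority ratios like the ~15:1 skew of real localization
corpora) for selection and oversampling studies, and
`generate_ar_series()` provides AR ground truth for
linear-prediction recovery.

What the generator does **not** emulate: real gait is not a sum of
harmonics (no impacts, no stride-to-stride variability), sensors have
no bias drift or clipping, headings have no magnetic disturbances,
bout transitions are instantaneous, and classes are far better
separated than field data. Passing tests therefore demonstrate that
the *pipeline machinery* is correct and recovers known structure —
not that field-data accuracies would match.

## Problem sizes and numerical choices

The default end-to-end scenario is 5 cycles × 4 classes × 20 s at
50 Hz (400 s, ≈ 400 windows, ≈ 395 sequences, 80/20 split) — large
enough that held-out macro F1 ≥ 0.90 is a meaningful recovery bar,
small enough to run in seconds. Linear-prediction recovery uses
N = 10 000 samples and 20 seeds; DTW and AUC oracles enumerate
exhaustively at lengths ≤ 6 and ≤ 12 respectively, where enumeration
is exact.

Other numerical choices: the Chebyshev polynomial is evaluated by its
three-term recurrence (valid on the whole real line); near-singular
Yule–Walker systems are refused rather than regularized; SSCE treats
$0\ln 0 = 0$ and filters zero-variance dimensions; `atan2(0, 0)` is
defined as 0 with a warning; probability softmaxes subtract the row
maximum; ranking ties and predicted-class ties resolve
lexicographically / to the first class.

## Configuration surface

`run_pipeline()` takes a nested list or a YAML file (YAML is the
R-ecosystem convention for such configs) mirroring
`default_config()`: `filter.*`, `window.*`, `features.*`, `steps.*`,
`rfe.*`, `smote.*`, `model.*`, `split.*`, `synth.*`, plus one global
`seed` that fans out to per-stage seeds by fixed offsets (+1 split,
+2 SMOTE, +3 model, +4 RFE), so each stage is reproducible in
isolation. Unknown keys are rejected. The CLI
(`inst/cli/harpipe.R`) exposes `synth` and `run`; the per-stage
functions with CSV I/O are the composable interface for everything
in between.

## Known limitations

- No timestamp alignment or resampling: channels are assumed
  synchronous and equi-sampled.
- Heading has no tilt compensation; it is only meaningful for a
  roughly horizontal device.
- The LSTM is CPU-oriented; it is not intended for corpus-scale
  training.
- GPS features, Mel-frequency cepstra, learned features, and
  borderline-SMOTE variants are out of scope.
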