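# harpipe

Human activity recognition (HAR) from wearable inertial sensors. The
package implements a complete recognition pipeline for **locomotion**
activities (walking, running, climbing, standing, ...) and
**localization** context (heading, step counts for pedestrian dead
reckoning) from multichannel sensor logs — tri-axial accelerometer,
gyroscope, magnetometer, optional audio — and ships a seeded synthetic
multi-sensor generator so every stage runs and is testable without any
external dataset.

It is aimed at researchers in digital-health signal processing who want
a transparent, fully scriptable reference pipeline in R: every stage is
an exported function with CSV input/output, and the whole chain is
reproducible from one seed.

## The pipeline

1. **Denoising.** Each channel is low-pass filtered with a Chebyshev
   Type I design, magnitude response
   `|H(ω)| = 1 / sqrt(1 + ε² T_n²(ω/ω₀))` with ripple factor
   `ε = sqrt(10^(rp/10) − 1)` (default ripple `rp = 0.5` dB, order 4,
   cutoff 0.2·Nyquist), applied forward–backward so it is zero-phase
   and step-peak timings are preserved.
2. **Windowing.** Overlapping segments of 100 samples with a step of 50
   (50 % overlap); the Hamming taper
   `w(x) = 0.54 − 0.46 cos(2πx/(X−1))` is available for spectral
   consumers. Each window takes the majority label of its samples.
3. **Locomotion features** per window: linear-prediction cepstral
   coefficients (Yule–Walker LPC via Levinson–Durbin, then the cepstral
   recursion), dynamic-time-warping distances to per-class reference
   patterns, state-space correlation entropy of the delay-embedded
   (m = 5) acceleration magnitude, circular statistics of the
   quadrant-aware phase angle `atan2(y, x)`, skewness and kurtosis, and
   optional spectrogram band summaries for audio.
4. **Localization features**: step counts from thresholded peak
   detection on `M = sqrt(bx² + by² + bz²)`, inter-step interval, and
   circular mean/sd/range of the magnetometer heading
   `H = atan2(a_y, a_x)·180/π mod 360`.
5. **Selection & balancing.** Recursive feature elimination (a fixed
   `M − k` loop over a refitted importance ranker) and SMOTE
   oversampling (`x_i + u·(x_nn − x_i)`, `u ~ U(0,1)`, k-NN = 5) on the
   training split only.
6. **Classifier.** An LSTM over sequences of 5 consecutive window
   feature vectors, trained 50 epochs with Adam on softmax
   cross-entropy plus an L2 weight penalty; implemented in base R
   matrix operations with a finite-difference-verified backward pass.
7. **Evaluation.** Row-normalized confusion matrices, per-class
   precision/recall/F1 with macro means, and one-vs-rest ROC/AUC
   (threshold sweep ≡ normalized Mann–Whitney statistic).

## Worked example

```r
library(harpipe)
res <- run_pipeline(list(seed = 1))   # seeded synthetic 4-class scenario
print(res$report)
```

```
<evaluation_report> 4 classes | 79 samples
          pred
true       climbing running standing walking
  climbing        1     0.0        0     0.0
  running         0     0.9        0     0.1
  standing        0     0.0        1     0.0
  walking         0     0.0        0     1.0
Mean Accuracy = 97.50% | Overall = 97.47% | macro F1 = 0.974
```

The scenario cycles four activity classes (static, 1 Hz, 2 Hz and
3.5 Hz gait signatures) through the full chain; the report is computed
on the held-out 20 % of sequences. The normalized confusion rows show,
per true class, the fraction routed to each predicted class; "Mean
Accuracy" is the mean of the diagonal (macro recall), "Overall" the
trace over the total. `res$report$per_class` holds per-class
precision/recall/F1, and `res$report$auc` the one-vs-rest AUCs.

Individual stages are ordinary functions if you want to compose them
yourself — `design_chebyshev1()`, `denoise()`, `segment()`,
`extract_locomotion_features()`, `extract_localization_features()`,
`rfe()`, `smote()`, `train_lstm()`, `evaluation_report()` — and
`inst/cli/harpipe.R` provides `synth` and `run` shell subcommands over
the same functions.

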