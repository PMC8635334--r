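---
title: "Unsupervised ECG feature learning with a 1-D convolutional VAE: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised ECG feature learning with a 1-D convolutional VAE: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Rule-based ECG feature extraction (ST deviations, PR/RR/QT intervals, ...)
requires every clinically relevant waveform shape to be named in advance.
`ecgvae` takes the opposite route: it learns a fixed-length feature vector
for single-lead (lead II) ECG strips *without labels*, by training a
one-dimensional convolutional variational autoencoder (CVAE) to compress
and reconstruct 8.192-second waveform windows. The latent posterior means
become a 60-dimensional feature vector; the reconstruction error becomes a
scalar *anomality score*. Downstream, the package evaluates those features
four ways: anomaly detection with grid threshold selection, 2-D embedding
of the feature cloud, latent-space exploration by coordinate perturbation,
and two transfer-learning protocols for rhythm classification.

Because the package must be testable without access to clinical waveform
databases, it ships a synthetic generator producing labelled, z-normalizable
lead-II-like records with separable rhythm classes. Everything downstream of
the generator is agnostic to where the waveforms came from.

## The synthetic generator

One beat is a sum of five Gaussians (the P, Q, R, S, T deflections):
amplitude $a_w$, center $c_w$ expressed as a fraction of the RR interval,
width $\sigma_w$ in seconds. Defaults give a dominant R wave (1.2 units)
with realistic smaller deflections; after z-normalization records span
roughly $-2$ to $6$, matching the amplitude range the method assumes for
normalized ECG. RR intervals are drawn from a truncated normal with mean
$60/\mathrm{HR}$ and coefficient of variation `rr_cv`, floored at 0.25 s so
beats never overlap.

Rhythm classes differ by rate, RR variability and P-wave presence:

| class | heart rate (bpm) | `rr_cv` | P wave | extras |
|---|---|---|---|---|
| `SR` | 60–100 | 0.05 | yes | — |
| `SB` | 40–55 | 0.05 | yes | — |
| `ST_TACHY` | 105–150 | 0.05 | yes | — |
| `AFIB_LIKE` | 70–110 | 0.25 | no | 4–9 Hz fibrillatory baseline |
| `SVT_LIKE` | 160–200 | 0.02 | no | — |

Artifacts are additive sub-0.5 Hz sinusoids (baseline wander, exercising
the high-pass stage), seeded Gaussian broadband noise, and flatline
segments. Per-record seeds are derived from a master seed by a counter
hash, so datasets are reproducible element-wise.

What the generator does *not* emulate: genuine AF dynamics (the RR process
is i.i.d. truncated-normal, not a point process with autocorrelation),
morphology change under rate (fixed template scaled to the RR interval),
ventricular arrhythmias, electrode motion artifacts with realistic spectra,
and inter-patient morphology variability beyond heart-rate jitter. Tests
passing on this generator therefore demonstrate that the pipeline's
machinery works and that its statistics behave as designed — not that the
learned features would transfer to any particular clinical dataset.

One generator-related subtlety: because wave centers are RR fractions, the
R-peak latency shifts slightly with each beat's RR interval, which smooths
the *detected* peak-to-peak series relative to the underlying RR draws.
Property tests about RR irregularity therefore use long (60 s) strips so
the per-pair event probability integrates over enough beats.

## Preprocessing

The chain is: zero-phase Butterworth high-pass (order 2, cutoff 0.5 Hz) at
the native rate, linear-interpolation resampling to 250 Hz, z-score
normalization, segmentation into non-overlapping 2,048-sample windows
(8.192 s), and finally a per-window re-standardization so each emitted
window has mean 0 and population SD exactly 1.

Numerical choices:

* the filter is applied forward–backward (`signal::filtfilt`) so ECG
  morphology is not phase-skewed; the input is point-reflected (odd
  padding) by $3 \cdot f_s / f_c$ samples before filtering because the
  filter's transient at a 0.5 Hz cutoff lasts seconds and would otherwise
  leak wander back into short records;
* sample $i$ (0-based) sits at time $i/f_s$; resampling evaluates the
  linear interpolant on the target grid and carries the last value forward
  when a target time exceeds the source span; no separate anti-alias stage
  is used for 2:1 down-sampling since the generator's content and filtered
  real ECG are band-limited well below 125 Hz;
* z-normalization uses the population SD with a $10^{-8}$ degeneracy
  guard (flat records raise a classed error carrying the record id);
* windows are non-overlapping and the trailing remainder is discarded.

## The CVAE

The encoder is nine residual blocks of 1-D convolutions (kernel 19 in
blocks 1–6, 9 afterwards), each block one strided convolution plus an
identity or strided 1×1 projection skip, followed by two dense heads
producing the latent mean $\mu \in \mathbb{R}^{60}$ and half-log-variance.
The decoder mirrors the encoder with transposed convolutions and ends with
a length-preserving 3-point average pooling; its final layer is linear.
Residual skips are an encoder feature only — the decoder's hyperparameters
mirror the encoder's, and reconstruction quality does not require skips
there. Channel widths default to a doubling schedule capped at 128 and are
fully configurable; strides default to 2 per block (2048 → 4).

Convolution geometry: for kernel $k$ and stride $s$, total padding
$k - s$ split floor/ceil keeps encoder lengths at exactly $L/s$ and
decoder lengths at $L \cdot s$; a configuration whose strides do not
divide the input length is rejected at build time naming the offending
block.

Training minimizes the negative ELBO
$$\mathcal{L} = \tfrac1n\sum_i \|x_i - \hat x_i\|_2^2 +
  \tfrac1n\sum_i \sum_d \tfrac12\left(\mu_{id}^2 + \sigma_{id}^2 - 1 -
  2\ln\sigma_{id}\right),$$
i.e. a per-window sum of squared errors (a sum-of-absolute-errors variant
sits behind `recon_loss = "sae"`) plus the closed-form KL divergence of the
diagonal Gaussian posterior from the standard normal prior, both averaged
over the batch with KL weight 1. Sampling uses the reparameterization
$z = \mu + \sigma \odot \varepsilon$. The optimizer is Adam (default
learning rate $10^{-3}$, batch 32); all stochasticity (shuffling,
$\varepsilon$, initialization) is derived from named seeds. Early stopping:
after each epoch the validation total is computed; training stops when the
running best has not strictly improved for `patience` (default 5)
consecutive epochs, and the best epoch's parameters are returned.
"Improvement" is strict (no tolerance band). `elbo_loss()` draws one noise
vector per call shared across the batch, making evaluated components
invariant under duplicating rows; training steps use independent per-row
noise.

The entire network — im2col convolutions, transposed convolutions,
projection skips, dense layers, pooling, Adam — is implemented in base R
on BLAS matrix products, with every backward pass verified against central
finite differences in the test suite.

## Anomaly detection

The anomality score of a window is the per-point mean reconstruction error
$\|x - \mathrm{dec}(\mu)\|_2^2 / 2048$, decoded at the latent *mean* so
scoring is deterministic. Scoring at the mean and dividing by the window
length are deliberate: the score then lives on the same per-point scale as
published thresholds for this method (a 0.05 grid, selections near 0.45,
noise beyond 1.3).

Threshold selection scans a grid from
$\lfloor \min s / 0.05\rfloor \cdot 0.05$ to
$\lceil \max s / 0.05\rceil \cdot 0.05$, classifying *abnormal iff score
> threshold* (strict). The selected threshold maximizes the weighted F1
(class-proportion weights over the two classes); ties break first on
abnormal-class precision, then on the larger threshold. The precision and
largest-threshold tie-breaks both favor fewer false alarms — in intensive
care, alarm fatigue argues for precision over recall. AUROC is computed
threshold-free from ranks (Mann–Whitney form, midranks for ties); Welch's
unequal-variance $t$-test compares score distributions.

The RR-irregularity statistic — the fraction of beats 50% longer or
shorter than the previous beat — needs an R-peak detector. Peaks are local
maxima above `median + max(2*MAD, 0.4*(max - median))` with a 0.25 s
refractory period keeping the larger of two close candidates. The
peak-referenced term in the threshold is load-bearing: a pure MAD
threshold sits below the T wave on clean strips, and for slow rhythms the
T wave falls outside any reasonable refractory window and would double the
detected rate.

## Latent space uses

Features are the encoder means (rows of `extract_features()`). Latent
exploration decodes $\mu$, $\mu - 2e_k$ and $\mu + 2e_k$ per coordinate
($\pm 2$ prior SDs). Which coordinate carries which clinical change is a
property of one training run, not a contract.

For 2-D embedding no t-SNE or LLE implementation exists among the
package's allowed dependencies, so both are implemented here: exact
$O(n^2)$ t-SNE (perplexity-calibrated Gaussian affinities by bisection,
early exaggeration ×4 for 100 iterations, momentum gradient descent with
gain adaptation, 500 iterations, seeded initialization) and standard LLE
(k-nearest-neighbor Gram systems with trace-scaled regularization, bottom
eigenvectors of $(I-W)^\top(I-W)$). Defaults: perplexity 30 (reduced
automatically for small n), 10 LLE neighbors. Exact duplicates embed as
mutual nearest neighbors rather than numerically identical points — t-SNE
at finite perplexity holds an equilibrium gap.

## Transfer learning

*Feature reuse*: a gradient-boosted tree classifier (xgboost, library
defaults, 60 rounds, recorded in the report) maps latent features —
optionally plus the anomality score as feature $d{+}1$ — to rhythm labels.
Validation repeats five seeded 80/20 re-splits and reports each metric as
mean ± SD. The protocol named "bootstrap" in this literature is ambiguous;
independent re-splits are the reading most consistent with mean ± SD
reporting, and a with-replacement bootstrap (out-of-bag validation) is
available behind `bootstrap = TRUE`.

*Weight reuse*: a supervised classifier shares the encoder topology, takes
the mean-branch output as the input to a dense softmax head, and is
trained with cross-entropy at a fixed learning rate ($10^{-4}$) for a
fixed epoch budget (150 in the reference protocol; scaled runs use fewer).
`init = "pretrained"` copies encoder weights from a trained CVAE
checkpoint (head always fresh); `init = "random"` re-draws everything. The
encoder is fine-tuned, not frozen — the weights serve as initialization
only. Convergence is compared by the first epoch reaching 90% of the
curve's own final weighted F1, plus peak values and final-5-epoch SDs.

A note on what the scaled synthetic study shows for weight reuse: the
pretrained initialization ends at a higher and more stable weighted F1
than random initialization on most seeds, but the *relative*
time-to-90%-of-own-final measure can favor random initialization. The
four synthetic rhythm classes are largely separable by heart rate — easy
enough for a randomly initialized encoder to learn quickly and plateau at
a lower value, which a measure taken relative to each curve's own final
value rewards; the pretrained encoder keeps improving through the budget,
pushing 90% of its larger final later. Both the epochs-to-90% medians and
the final-F1 medians are computed and reported by the acceptance script
so the two facets can be read together.

Classification metrics are one-vs-rest per class: precision
$TP/(TP+FP)$, recall $TP/(TP+FN)$, $F1 = 2PR/(P+R)$, weighted F1
$\sum_i w_i F1_i$ with $w_i$ the class proportion among true labels;
classes never predicted get precision 0 by convention.

## Problem sizes used in tests and the acceptance script

The shipped experiments are scaled to a single CPU: the reduced CVAE has
latent 16, four blocks (channels 8/16/24/32, strides 4/4/4/2) and trains
on ~500 synthetic normal-rhythm windows for at most 30 epochs (batch 8,
patience 5), which takes a couple of minutes and reaches a per-point
reconstruction error of roughly 0.3–0.6 on held-out normals. Anomaly
separation is evaluated on 100 held-out normals, 100 AFIB-like and 50
artifact windows; feature reuse on four rhythm classes × 200 records;
weight reuse on the same set for 15 epochs × 5 seeds per initialization.
These sizes are the package's chosen scaled-down study, selected once to
make each stage's expected behavior measurable with comfortable margins.

## Known limitations

* The architecture is a faithful-shape reconstruction of the published
  design, not a weight-compatible clone: the original layer table
  (channel widths, normalization layers, activations) is not public, so
  those choices are re-derived defaults.
* Whether the published reconstruction error is squared or absolute is
  not stated; both are implemented and the default is squared error,
  consistent with the published per-point arithmetic.
* Training on CPU in R is practical for the reduced study but not for
  hundreds of thousands of windows; the implementation is vectorized but
  single-threaded apart from BLAS.
* The generator's rhythm classes are separable by construction; absolute
  metric values on synthetic data say nothing about clinical performance,
  only orderings and mechanisms are meaningful.
* WFDB ingestion is not provided; records enter as CSV/serialized
  bundles, or programmatically as `ecg_record` objects.
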