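---
title: "Electrode attribution for CNN-based EEG emotion classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrode attribution for CNN-based EEG emotion classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegcam)
```

This vignette is the package's methods account: the model and its
assumptions, the parameters that matter, what the synthetic generator does
and does not emulate, the numerical conventions that were genuinely open,
and the known limitations. Every number quoted here is computed by the test
suite or by `scripts/acceptance.R`; nothing is asserted that the shipped
code does not reproduce.

## Data model and preprocessing

A trial is a `channels x samples` matrix at 128 Hz whose first
`n_baseline` samples (default 384, i.e. 3 s) were recorded before the
stimulus, plus arousal and valence self-ratings on a continuous 1–9 scale.
The supported layout is that of the preprocessed DEAP release: 32 EEG
channels, 8064 samples, 40 trials per subject.

Baseline correction follows the segment-template scheme: the baseline is
cut into `N = B / L` consecutive `C x L` segments (for the default
`B = 384`, `L = 128`, `N = 3`), averaged element-wise into a template `M`,
and `M` is subtracted from each `C x L` slot of the stimulus. Two
conventions are deliberate:

* A baseline length that is not divisible by `L` is an **error**, not a
  truncation — the remainder's treatment is undefined in the scheme this
  implements, and silently dropping samples would bias the template.
* Windows are non-overlapping and in temporal order; the arithmetic
  (7680 / 128 = 60 windows per trial) pins this down, and every window
  inherits the whole trial's label. There is deliberately no filtering,
  re-referencing or artifact rejection here: the preprocessed DEAP release
  already applies a 4–45 Hz band-pass, and this pipeline adds only the
  baseline correction.

Labels use 5 as the threshold with *low ≤ 5 < high*, evaluated on the
float rating, for the two binary tasks and the four quadrants. Keeping the
middle ratings (4 and 5) in the low class preserves sample size and class
balance; `label_trial()` guarantees that the quadrant label always refines
the two binary labels.

## The network

`network_spec()` encodes the architecture: six same-padded 5 × 5
convolutions over the `128 x 32` time-by-electrode window, (2,1)
max-pooling after conv3 and conv6 (temporal axis 128 → 64 → 32, electrode
axis untouched), filters 32-32-64-64-64-128, flatten length
32·32·128 = 131,072, a 512-unit fully connected layer, and `N` logits.
The 5 × 5 kernel couples ≈ 40 ms of time with two neighbouring electrodes
per layer; pooling only along time preserves electrode identity, which the
attribution stage depends on.

Six regularization devices are all implemented and on by default:

1. structured dropout (whole feature maps drop together; retention 0.5)
   after conv1, conv3, conv4, conv6 and fc1;
2. batch normalization after conv2, conv4, conv5 and fc1 (running
   statistics tracked for inference);
3. L2 weight decay: the loss is softmax cross-entropy plus
   `l2_coeff * sum(W^2)` over convolution, projection and dense weights
   (default `1e-4`);
4. learning-rate halving every 50 epochs from `lr0 = 1e-3`, under Adam;
5. residual links conv1→conv3 and conv4→conv6; because the filter counts
   differ (32→64, 64→128), the skip path carries a learned 1 × 1
   projection, and the sum lands on the target convolution's pre-activation
   (after its batch norm where present, before its ReLU);
6. 10-fold cross-validated evaluation.

Where the architecture description leaves an ordering open we use
`conv → batch norm → ReLU → dropout` (the common convention), and the
residual addition sits before the target's ReLU. The loss is softmax
cross-entropy — the attribution stage differentiates the *logit*, which
presumes a linear pre-softmax output, and training minimizes the matching
likelihood. Epoch count, L2 strength, weight initialization
(fan-in-scaled Gaussian) and the absence of early stopping are free
configuration, not claims about the reference protocol.

All of this is implemented directly in the package (R with
RcppArmadillo convolution/pooling kernels); training is deterministic
under a fixed seed, and inference (dropout off, batch norm on running
statistics) is batch-size invariant — both are property-tested.

## Grad-CAM and the contribution scores

For class `c`, the gradient of the logit `y_c` (never the softmax
probability) is taken with respect to the activations `A^k` of the **final
convolutional layer** — conv6's post-ReLU output, *before* the second
pooling, so `H = 64`, `W = 32`, `K = 128`; pooling layers are not
convolutional layers. The gradients are globally average-pooled into
per-map weights `alpha_k = (1/Z) Σ_ij ∂y_c/∂A^k_ij` with `Z = H·W`, the
maps are combined as `ReLU(Σ_k alpha_k A^k)`, and the result is upsampled
bilinearly to the 128 × 32 input grid.

Numerical conventions:

* **Bilinear grid.** Half-pixel centers without corner alignment: output
  row `i` samples source coordinate `(i + 0.5)·H_in/H_out − 0.5`, clamped.
  The test suite pins this against an independently coded scalar oracle;
  constants stay constant and non-negativity is preserved.
* **Gradient correctness.** `class_gradients()` is checked against central
  finite differences through the real head (pooling, flatten, batch norm,
  ReLU, dense) at 1e-3 relative tolerance. Coordinates whose pooling
  partner lies within 1e-2 are excluded from the check: at a pooling tie
  the map is non-differentiable and one-sided derivatives genuinely
  disagree — that is a property of max-pooling, not an implementation
  error.
* **CAM limit.** For a network whose head is global average pooling plus a
  linear layer, Grad-CAM must reduce to CAM (`ReLU(Σ_k w_kc A^k)`) up to
  the positive factor `1/Z`; the suite verifies this to 1e-6 after scalar
  normalization, using the same forward/backward engine.

Per-window heatmaps are reduced to per-electrode means over time,
averaged over samples (per class, or pooled over the task), and min-max
normalized to \[0, 1\]. Min-max is applied **per vector** (each class or
task on its own 0–1 axis) since the scores are only ever compared within a
vector; it is invariant under positive affine transforms, so the arbitrary
scale of Grad-CAM maps (e.g. rescaling a class's head weights) cannot move
a score. A constant raw vector has no spread to normalize: it maps to all
zeros and is flagged `degenerate` rather than raising.

Selection keeps channels with score **strictly above** the threshold —
0.5 by default, 0.6 for the binary arousal task where the high-contribution
cluster is tighter; both are plain arguments. Stability is assessed by
drawing sample subsets without replacement under a recorded seed,
recomputing the normalized vector and the selected set per subset, and
reporting the Pearson correlation against the full-data vector (the
full-size row is 1 by construction). Whether heatmaps are computed for the
true or the predicted class is a flag (`class = "true"` is the default, as
the per-class averages require it).

## The synthetic generator

`generate_trial()` emulates the DEAP layout exactly: 32 × 8064 at 128 Hz,
384 baseline samples, ratings drawn uniformly from {1..5} for "low" and
{6..9} for "high" so the threshold rule reproduces the intended quadrant
deterministically. Signal model per trial:

* i.i.d. Gaussian noise (`noise_sd`, default 1) everywhere;
* a per-channel DC offset (`baseline_offset_sd`, default 1) shared by
  baseline and stimulus — this is what makes baseline subtraction
  demonstrably useful, and the template provably removes it;
* on the planted channels only, and only in the stimulus segment, a
  10 Hz sinusoid whose amplitude encodes the arousal level and a 20 Hz
  sinusoid encoding the valence level (amplitudes
  `0.5 · effect_size · noise_sd` for low, `1.5 · effect_size · noise_sd`
  for high), with random phases per trial and channel. Band-limited
  oscillatory power is the canonical EEG feature, it gives the 5 × 5
  kernels a learnable temporal pattern, and with `effect_size = 0` the
  classes are exactly exchangeable.

The defaults (`effect_size = 2`, planted channels 20 and 22 = F4 and FC6,
200 training windows per class, 30 epochs) are the package's fixed study
conditions for the end-to-end recovery check. A single master seed fans
out to per-trial substreams, so datasets are bit-identical regardless of
generation order — property-tested.

Before the CNN ever sees these data, the effect model is validated by an
independent route: linear discriminant analysis on trial-level 10/20 Hz
band power of the planted channels reaches > 90% quadrant accuracy at
`effect_size = 2`, is at chance on baseline-only features, and its
accuracy is non-decreasing in the effect size (checked at three effect
sizes and three seeds in the 0–0.05 range, where the 60 s power estimate
is not yet saturated).

What the generator does **not** emulate: volume-conducted scalp
topographies (each channel is independent), artifacts (blinks, EMG),
non-stationarity within a trial, the 8 peripheral DEAP channels, and
inter-subject variability. Passing the recovery test therefore shows the
*pipeline* recovers a known band-power effect; it does not show that real
DEAP attributions are neurophysiologically correct.

## Evaluation protocol, leakage, and the null control

Cross-validation pools windows across trials by default — the protocol
that produces the familiar 93–95% DEAP figures. Pooling means windows of
one trial appear on both sides of a split, and a trial is identifiable
from its windows (at minimum through the shared baseline-template
residual: every window of a trial has the same template subtracted), so
pooled accuracy is partly trial memorization. The package makes this
measurable rather than hiding it: the synthetic benchmark reports both
held-out-window accuracy (95.5% at seed 1) and accuracy on windows of
*freshly generated* trials (53.1%) — both far above the 25% chance level,
but the gap is the pooled protocol's optimism. `kfold_split()` therefore
also offers `group_by = "trial"` (and `"subject"`), which keeps whole
recordings on one side of the split; grouped folds are dealt
round-robin per class so they stay class-balanced.

The null control exploits this: with `effect_size = 0` there is no class
information by construction, and trial-grouped cross-validation of the
scaled network sits at chance (within ±5 points of 25%, tested). Under
pooled folds the same data can score *above* chance purely through
template-residual memorization — which is why the null is run under the
grouped protocol: it isolates pipeline leakage (which must be zero) from
protocol leakage (which is real, documented, and quantified by the
transfer gap above).

## Desk-scale problem sizes

The canonical architecture (131,072 → 512 alone is 67 M weights) is
impractical to train repeatedly in a test suite, so the end-to-end checks
use a scaled copy of the same topology — every layer, both poolings, both
residual projections, all six regularizers — with filters 2-2-4-4-4-8 and
a 32-unit fc1. Study sizes: 200 training windows per class (quadrant
task), 30 epochs, batch 120, three seeds for the recovery check; an
independent 1200-window evaluation set for attribution and for
subset-stability at sizes 100/500/1000; 24 trials, 2 epochs, 3 grouped
folds for the null. Architecture-shape checks (`layer_shapes()`,
`build_network()`, a forward pass) always run at canonical size. The
acceptance script repeats the benchmark at one seed and writes every
quantity it computes as JSON.

## Known limitations

* Grad-CAM here is spatial/temporal on a 1 s window; it says nothing about
  longer-range temporal dynamics, and no guided/second-order variants are
  provided.
* The contribution score is a min-max-scaled mean of rectified evidence
  for the (true-class) heatmaps; it is a relative ranking, not a
  calibrated effect size, and carries no significance test.
* Pooled-window accuracy should be read with the leakage caveat above;
  subject-independent evaluation is out of scope.
* The montage is configuration (a packaged CSV with the documented DEAP
  channel ordering); if your recording uses a different ordering, supply
  your own CSV — electrode-name outputs are only as correct as that file.
* Training is CPU-bound R/C++ and sized for tens of thousands of window
  passes, not for full-scale DEAP training; the full-scale protocol is a
  documented workflow (`read_deap_subject()` + `cross_validate()` with the
  canonical spec), not an automated test.
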