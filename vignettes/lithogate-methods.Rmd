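---
title: "Methods: simulation, segmentation and statistics behind lithogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, segmentation and statistics behind lithogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Extracorporeal shockwave lithotripsy (ESWL) fragments kidney stones with
focused shockwaves fired from outside the body under inline ultrasound
guidance. The lithotripter fires at a constant pulse rate (typically 90
pulses/min) whether or not the stone actually occupies the focal zone (FZ),
the small region where the acoustic energy concentrates. Respiration moves
the kidney several millimetres per breath, so a large fraction of
shockwaves are *mishits*: they deposit energy in healthy tissue and do not
touch the stone. Operator-controlled hit rates of roughly 40--60% are
typical.

`lithogate` implements the full analysis pipeline for *gated* ESWL: a
convolutional segmentation network finds the stone in each ultrasound
frame, a geometric rule decides whether the stone is sufficiently inside
the focal zone to justify firing, and a statistical layer quantifies both
the operator baseline (per-patient hit rates with bootstrap confidence
intervals, a pooling test) and the classifier (confusion-matrix metrics,
treatment-efficiency estimates). Because real treatment videos are private
patient data, the package ships a synthetic ultrasound generator that
reproduces the features of the task that matter and provides exact ground
truth for every downstream stage.

## Synthetic ultrasound sequences

### Anatomy and speckle

Each frame is composed in three layers: a dark surround, a brighter
elliptical kidney, and a bright elliptical stone echo with an
acoustic-shadow column beneath it (stones are strong reflectors, so the
tissue below them is shadowed; rendering the shadow gives the network a
realistic confusable dark feature adjacent to the bright echo). The smooth
anatomy image is multiplied by gamma-distributed speckle with mean 1 and
shape `speckle_shape` (default 8, i.e. about 35% coefficient of
variation), a standard first-order emulation of fully developed B-mode
speckle. This is deliberately not an RF-level acoustic simulation: the aim
is a segmentation problem with the right structure (bright small target,
textured organ context, intensity noise), not physical fidelity.

Defaults (all in pixels on a 64x64 grid unless stated): stone semi-axes
(4, 3), kidney semi-axes (26, 22), stone echo 230, kidney parenchyma 90,
surround 30 (8-bit gray levels), shadow attenuation factor 0.45, frame
rate 15 frames/s.

### Respiratory motion

The stone centre follows a one-dimensional periodic path mapped onto a
line in the image plane (default cranio-caudal):

$$ s(t) = A \, \sin^{2p}\!\left(\frac{\pi t}{T}\right), $$

with amplitude $A$ (`motion_amplitude`, pixels), breathing period $T$
(`respiratory_period`, default 4 s) and dwell exponent $p \ge 1$
(`dwell_exponent`, default 4). The even power flattens the minima: near
end-expiration the stone is almost standing still -- the clinically
exploitable dwell -- followed by a fast transit to the inspiration
extreme. $p = 1$ recovers a plain raised-cosine; larger $p$ concentrates
more of the cycle at end-expiration. The trajectory is a pure function of
the configuration (no noise), so frame labels are exactly reproducible.

The fraction of the cycle spent within a displacement $d$ of
end-expiration has the closed form
$\frac{2}{\pi}\arcsin\!\big((d/A)^{1/(2p)}\big)$, which the cohort
simulator inverts to hit a target hit rate.

### Focal zone and ground truth

The focal zone is an axis-aligned ellipse (piezoelectric focal zones are
ellipsoidal; a rectangle is available for exact-arithmetic tests) with
configurable centre and semi-axes, by default centred on the stone's
end-expiration position. Each rendered frame carries exact masks and an
exact overlap: the fraction of stone pixels inside the zone by pixel
counting. The frame label is `in_focus` iff that overlap is at least 0.5,
so generator labels and the decision rule agree *by construction* -- this
identity is asserted exactly in the tests and is what makes the
ground-truth oracle path of the pipeline a meaningful internal control.

### Cohorts with controlled heterogeneity

`simulate_cohort()` gives each patient a target hit rate (evenly spread
over 20--90% at `jitter = 1`, randomly permuted across patients so that
patient id does not correlate with rate) and solves for the motion
amplitude in closed form. Because the dwell concentrates time at
end-expiration, rates below about 60% are unreachable by amplitude alone
within the image; such patients instead get their focal zone placed at the
inspiration end of the path -- a poorly targeted patient -- where the
in-focus fraction is $1 - \frac{2}{\pi}\arcsin\!\big((1 -
d/A)^{1/(2p)}\big)$ and the amplitude again has a closed-form solution.
Stone semi-axes are additionally perturbed by up to ±25% per patient.
Realised rates track their targets to within a few percentage points
(quantisation of frames and pixels accounts for the residual), which is
what the pooling test needs: strong jitter produces a chi-square that
rejects homogeneity, zero jitter produces identical rates and a chi-square
of zero.

### What the generator does not emulate

Probe retraction during firing, depth-dependent attenuation and focus,
stone fragmentation over the treatment course, out-of-plane (3-D) motion,
and annotator subjectivity (interobserver variability can be emulated
separately by `corrupt_labels()`, which flips labels at a configurable
mismatch rate). Consequently, passing end-to-end tests demonstrate that
the pipeline's machinery is correct and that the network can learn this
class of task from ~60 masks -- not that the trained weights would
transfer to clinical images.

## Annotation scheme

Treatment videos are long and mostly redundant, so per-frame labels are
derived from *transition points*: an annotation records only the 0-based
frame at which the label changes, and every frame carries the label of the
latest transition at or before it (`expand_intervals()`;
`compress_labels()` is its exact inverse, and the round-trip identity is
property-tested). Human narration of frame positions is 1-based ("the
tenth frame"); all indices in files and code are 0-based, converted only
in prose. `sample_window()` draws the annotated window uniformly from a
longer video.

## Segmentation network

`build_unet()` constructs a compact U-Net: double 3x3 convolution blocks
(ReLU) separated by 2x2 maximum pooling on the contracting path, a
bottleneck block, and nearest-neighbour upsampling with symmetric skip
concatenations on the expanding path, ending in a 1x1 convolution. The
two output channels (stone, kidney) are independent sigmoids rather than
softmax classes because the stone lies *inside* the kidney -- the kidney
channel supplies spatial context, not a competing class.

No deep-learning framework is involved: convolutions are lowered to BLAS
matrix products via im2col, and the backward pass is hand-derived
(verified against finite differences in the test suite, with biases moved
off zero because zero-initialised biases put dead-ReLU pre-activations
exactly on the kink where one-sided derivatives differ).

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| depth | 3 pooling stages | 64 -> 8 px bottleneck; enough receptive field to see the whole stone and its shadow |
| base_channels | 8 | the architecture, not capacity, is the object of study; trains on one CPU in minutes |
| input_size | 64 px | matches the generator default; resizing (bilinear images, nearest-neighbour masks) handles other sizes |
| loss | sigmoid BCE, stone channel weighted 8x | the stone occupies <1% of pixels; unweighted BCE can leave the stone channel globally under-confident (below the 0.5 threshold everywhere), which surfaces as spurious "no detection" on whole patients |
| optimizer | Adam, lr 1e-3, batch 8 | robust default for small CNNs |
| patience | 5 epochs, max 30 | validation loss plateaus well before 30 epochs on the synthetic task |

Training (`train_unet()`) records train/validation loss per epoch, stops
after `patience` non-improving validation epochs, and always returns the
weights from the epoch with minimum validation loss -- early stopping at
the lowest point of the validation curve. A single integer seed controls
initialisation and shuffling; no augmentation is applied.

Small networks occasionally draw an initialisation from which Adam never
leaves a high-loss plateau (validation loss stuck around 0.45 where
converged runs reach ~0.02); `run_full_synthetic()` therefore retrains a
fold from a fresh seeded initialisation (up to 3 attempts) whenever the
best validation loss stays above 0.15, keeping the best fit -- the usual
random-restart treatment of failed optimization.

`make_cv_splits()` builds the patient-based rotation: each fold holds out
one patient for validation and the next for testing, training on the
rest, so with 11 patients there are 11 folds and every patient serves as
validation exactly once and as test exactly once. No frame of a fold's
test patient ever enters its training or validation.

## Firing decision

`classify_frame()` applies the overlap rule verbatim: *in focus* iff at
least 50% (`>=`, the boundary counts) of the predicted stone pixels lie
inside the focal zone. Disconnected mask components are treated as one
stone (union) -- the predicted stone is a single object, and a
per-component rule would change the denominator arbitrarily. Masks with
fewer than 5 pixels count as *no detection* rather than a decision; the
floor suppresses speckle-level false detections, and the criterion the
original analysis used for "unable to find a stone" is not stated, so 5
pixels is a declared package default. No-detection frames are resolved by
an explicit policy: `exclude` (drop and count them -- the primary
analysis) or `as_out_of_focus` (an undetected stone is not fired upon);
`alternative_policy_report()` recomputes the whole metric panel under the
latter.

## Evaluation

`classifier_metrics()` computes the standard panel from the confusion
matrix at full precision (rounding happens only in printing: one decimal
in percent, four for kappa). Cohen's kappa uses the marginal expected
agreement; the no-information rate is the larger marginal prevalence. If
the lithotripter fires exactly on in-focus decisions, the achieved hit
rate *is* the PPV -- this identity is tested by direct simulation of the
firing stream.

`treatment_efficiency()` derives: relative treatment time = annotated
in-focus frames / true positives (how much longer gated treatment takes to
deliver the same number of true hits); mishit ratio = relative treatment
time x false positives / annotated out-of-focus frames; and hits per
minute for continuous vs gated firing at the configured pulse rate. One
wording in the source methods text attributes the mishit numerator to
"true negatives", but the worked arithmetic (and the physical meaning --
mishits are shots fired while the stone is out of focus) uses the
false-positive count; the implementation follows the arithmetic and says
so in its `note` field.

## Hit-rate statistics

`bca_bootstrap()` implements the bias-corrected and accelerated interval
directly: bias correction $z_0 = \Phi^{-1}(\#\{t^* < t_0\}/B)$ (ties
counted half), acceleration from the jackknife skewness, adjusted
percentiles read off the bootstrap distribution with type-6 quantiles.
The independent cross-check in the tests is `boot::boot.ci(type =
"bca")`. Constant data collapse the interval to the constant rather than
erroring, so degenerate synthetic runs still produce reports.

Two levels, two defaults:

* **Frame level** (`patient_hit_rate_ci()`, 5000 resamples): resamples a
  patient's 0/1 frame labels and bootstraps the mean; the reported
  per-patient value is the *median of the bootstrap distribution* of that
  proportion -- the "median hit rate".
* **Patient level** (`cohort_hit_rate_ci()`, 3000 resamples): resamples
  the vector of per-patient rates and bootstraps its **mean**. The mean
  (not the median) of the eight per-patient median hit rates is the cohort
  summary that reproduces both the published point value and its
  confidence interval; with the median as cohort statistic the interval is
  several points narrower and shifted. The `statistic` argument exposes
  both. 3000 resamples is justified by `convergence_trace()`: the tracked
  95th percentile of the bootstrap distribution changes by well under 1%
  per grid step beyond 2000--3000 resamples.

`pooling_chi2()` decides the summary level. Under homogeneity every
patient shares the pooled rate $\hat p = \sum n_{focus} / \sum n_{total}$,
the expected hit count is $E_i = n_{total,i}\,\hat p$, and
$\chi^2 = \sum_i (O_i - E_i)^2 / E_i$ over the *hit-count cells only*
with $k - 1$ degrees of freedom. The hit-cells-only construction is an
inference: it is the only construction that matches the published manual
statistic (a hits-plus-misses construction roughly doubles it); it is
stated prominently here and in the function documentation. Rejection
(p < 0.05) sends the cohort summary to the patient level.

`normality_diagnostics()` standardises the adjusted Fisher--Pearson
skewness and excess kurtosis (the convention SPSS prints, e1071 type 2) by
their small-sample standard errors, alongside a Shapiro--Wilk test.

## Numerical choices and degenerate inputs

* Maxpool ties break to the first block element in a fixed scan order;
  inference is exactly deterministic.
* The overlap threshold uses `>=` so an exact 0.5 overlap fires.
* Zero-denominator metrics are reported as `NA`, not errors; an all-zero
  confusion matrix is an error.
* `tp = 0` makes the efficiency ratios undefined: reported as `NA` with a
  warning.
* All randomness (speckle, cohort jitter, shuffling, initialisation,
  resampling) descends from explicit integer seeds; per-frame speckle uses
  `seed + frame_index` so single frames are reproducible in isolation.

## Problem sizes

The packaged analyses and tests use: an 11-patient synthetic cohort with
150 frames (10 s at 15 frames/s) per patient; 5 delineated mask frames per
patient (55 masks, mirroring the sparse ~57-mask annotation budget the
design emulates); one fold of the 11-fold rotation for the end-to-end
demonstration (`folds = seq_len(11)` runs the full rotation); 5000
frame-level and 3000 patient-level bootstrap resamples; 500 replications
for the coverage property. These sizes are the package's own choices: they
are the smallest at which each claim being demonstrated is actually
exercised -- the architecture and pipeline, not model capacity or
wall-clock scale, are the objects under test.

## Known limitations

The synthetic task is much easier than clinical ultrasound (the trained
network routinely reaches near-perfect PPV on held-out synthetic
patients); the comparison of interest is therefore *qualitative* -- gated
PPV exceeding cohort prevalence -- not the absolute metric values. The
BCa implementation makes no claim of binary identity with any particular
statistics package, only agreement within bootstrap noise. The pooling
statistic's cell construction is inferred as documented above. Focal-zone
geometry on real devices, and the mapping from on-screen crosshairs to the
physical zone, are configurable but unknown.
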