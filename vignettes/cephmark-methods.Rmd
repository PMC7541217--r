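---
title: "Bayesian coarse-to-fine landmark detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian coarse-to-fine landmark detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cephmark locates cephalometric landmarks on lateral skull radiographs and,
unlike a plain point detector, attaches a 95% confidence ellipse to every
estimate. This vignette explains the model, the knobs that matter, what the
synthetic generator does and does not emulate, and the design choices made
where the protocol left room.

## The detection model

Landmarks are detected one at a time, independently, by a pair of binary
patch classifiers per landmark:

1. **Low-resolution screening (LRS).** The image is downsampled by a factor
   of 3 (block mean) and square patches are sampled on a regular lattice
   with a 3 mm stride. A CNN trained for landmark $k$ classifies each patch
   centre as *true* (landmark neighbourhood) or *false*. The proposed
   region-of-interest (ROI) centre is the arithmetic mean of the $n_T$
   positions classified true,
   $(\hat x_k^L, \hat y_k^L) = \frac{1}{n_T}\sum_i \vec p_i^{\,t}$.
   If $n_T = 0$, the grid point with the largest true-class probability is
   used instead and the prediction is flagged as a fallback.

2. **High-resolution screening (HRS).** A square ROI (40 mm side at full
   scale; 99% of true landmark positions fall within such a window around a
   reasonable centre) is placed at the LRS centre. Every ROI pixel is
   classified at native resolution by a Bayesian CNN: $T = 17$ forward
   passes with dropout left active give, per pixel $i$, the mean $\mu_i$
   and standard deviation $\sigma_i$ of the true-class softmax output —
   Monte-Carlo dropout's approximation to the posterior predictive mean and
   uncertainty.

3. **Score weighting.** Pixels likely to be the landmark combine a high
   $\mu_i$ with a low $\sigma_i$. Both enter one score,
   $$\mathrm{score}_i = \left(e^{10\mu_i} - 1\right)\,
     \tanh\!\left(\frac{\sqrt{\sum_{j=1}^N \sigma_j^2}}{s_\sigma\,\sigma_i}\right),$$
   where $N$ is the ROI candidate count and $s_\sigma > 0$ a scale. The
   final estimate is the *score centre*, the score-weighted centroid
   $(\hat x_k^H, \hat y_k^H) = \sum_i \mathrm{score}_i\,\vec p_{h_i} \big/
   \sum_i \mathrm{score}_i$.

All geometry is metric (mm); pixels appear only at I/O and sampling
boundaries. The pixel spacing defaults to 0.1 mm/px.

### The confidence ellipse

The reference protocol displays 95% ellipses but does not spell out their
construction. cephmark treats the normalised scores as a spatial probability
surface — the same reading that makes the score centre a centre of mass —
and builds the ellipse from the score-weighted covariance $\Sigma$ of the
candidate positions about the score centre: the boundary is
$\{x : (x-c)^\top \Sigma^{-1} (x-c) = q\}$ with $q = \chi^2_2(0.95) = 5.991$.
Axes and orientation come from the eigendecomposition of $\Sigma$. For an
isotropic Gaussian score field of spread $s$ both semi-axes equal
$s\sqrt{5.991}$ and the ellipse contains 95% of the score mass; this is
asserted in the test suite. A covariance with a null direction (all mass on
a point or a line) yields a degenerate ellipse with the corresponding
semi-axis 0 and a flag. This construction is an interpretation, recorded as
such, and is confined to `confidence_ellipse()`.

### Uncertainty estimator

$\sigma_i$ is the sample (n−1) standard deviation of the true-class softmax
across the $T$ dropout passes, defined as 0 at $T = 1$. Richer
decompositions (aleatoric/epistemic splits) exist; the moment estimator is
the simplest one consistent with "mean and uncertainty of the softmax
output", and the estimator sits behind `predict_bayesian()` so it can be
swapped without touching the scoring.

### Degenerate inputs and tie-breaks

* $\sigma_i = 0$ (all passes agree) is floored at `sigma_floor = 1e-12` so
  the tanh term attains its supremum 1 — the continuous limit of the
  formula.
* If every score is 0 (e.g. all $\sigma_j = 0$, which zeroes the tanh for
  every pixel), the pipeline falls back to the maximum-$\mu$ pixel with a
  degenerate ellipse and a flag.
* A deterministic classification tie (true-class probability exactly 0.5)
  resolves to the false class.
* $s_\sigma$ is not pinned by the reference protocol; it defaults to 1.0
  and is exposed in `score_config()`. Because it enters all pixels through
  the same $\tanh(\cdot/s_\sigma \sigma_i)$, moderate changes re-weight but
  do not move well-peaked score fields much.

## The classifier and its training contract

Each classifier stacks *convolutional clusters* — batch normalisation,
convolution, rectifier, 2×2 max pooling (stride 2, floor), dropout, in that
order — then two fully connected layers, the first as wide as the flattened
map, the second with one neuron per class. The full-scale stack uses 4
clusters with kernel sides 10/7/5/1 and depths 32/64/128/256, dropout 0.2.
Convolutions are SAME-padded: the stated stack must survive four pooling
halvings on a 31-px patch, which rules out valid (shrinking) convolutions;
`build_model()` checks the shape arithmetic and names the first cluster at
which a too-small patch would collapse. Batch normalisation uses batch
statistics during training and its trained running statistics at prediction
time, so dropout is the only stochastic element of a Monte-Carlo pass.

Training minimises softmax cross entropy plus an L2 weight-decay penalty
(0.001) with Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$, learning rate 0.05 at
full scale), from a fan-balanced (Glorot) uniform initialisation, in batches
of 128 patches for up to 200,000 steps at full scale. Everything —
initialisation, batch order, dropout masks — derives from explicit integer
seeds, so training and prediction are bit-reproducible. The backend is
written in C++ (im2col convolutions on BLAS); no deep-learning framework is
required.

Training patches are generated by cropping around the ground-truth landmark
(the mean of the two annotators' points): per image, `n_true` = NT centres
drawn area-uniformly within the stage's true region and `n_false` = NF from
its false region — LRS: a disc of 18 mm and its complement; HRS: a disc of
0.9 mm and the 2.1–40 mm annulus, leaving the ambiguous (0.9, 2.1) mm ring
out of training entirely. At the full-scale defaults (NT = 200, NF = 500) a
150-image training set yields exactly 105,000 patches, and the 19-landmark,
2-stage registry holds 38 independent models.

## Evaluation

* Landmark error (LE): Euclidean distance in mm per image; tables report
  the mean and the sample (n−1) SD across images.
* SDR at radius $z$: $100 \cdot \#\{i : \|m_i - a_i\| < z\}/n$ — strictly
  below $z$, following the set-builder definition (an error of exactly
  2 mm does not count as a success at 2 mm).
* Aggregate rows are unweighted means over the 19 landmark rows; rounding
  happens only at presentation.
* `error_sdr_correlation()` is the sample Pearson coefficient between the
  per-landmark mean LE and SDR(2 mm) columns.

The package ships the published per-landmark reference table
(`reported_performance()`); feeding it through `aggregate_report()`
reproduces the published average row to within the rounding of 2-d.p.
inputs, and the published −0.689 correlation.

## Orthodontic parameters

`compute_parameters()` derives ANB, SNA, SNB (vertex angles at Nasion),
ODI and APDI (sums of line angles), FHI (Sella–Gonion over Nasion–Menton),
FMA (Sella–Nasion vs Gonion–Gnathion) and MW (incisal-incision distance).
Line-angle components default to the unsigned convention (minimal angle
between undirected lines, [0°, 90°]) with a signed mode available, because
clinical conventions sign some components; the mode is recorded on the
result. MW is Euclidean by default with a signed-horizontal variant for
threshold tables that use negative classes. Numeric class thresholds are a
configuration input — the reference tables print class labels but no
cutoffs — and the packaged `classification_thresholds.csv` is a template of
conventional ranges, not a validated clinical standard.

### Recovering counts from printed percentages

Published confusion matrices often print only row percentages (2 d.p.,
half-up). `recover_counts_from_percentages()` finds integer counts that
reproduce a row, but per-row minimal totals are ambiguous: a row printed as
5.04/0.00/94.96 is consistent with 119 cases (6/0/113) as well as the true
139. Since all parameters of one study share a single test set,
`recover_confusion_joint()` intersects the feasible grand totals across
tables and recovers counts under the smallest common total; on the shipped
reference rows this pins the grand total at 249 and reproduces the
published diagonal accuracies exactly. One MW row (89.76) is numerically
inconsistent with every total up to 250 — its consistent reconstruction
(44 of 49) prints as 89.80 — so a `pct_tol` option admits such
typographic slips explicitly rather than silently.

## The synthetic generator

`generate_case()` draws frames (default 500×500 px at 0.1 mm/px) with one
analytic structure per landmark — radial bumps, rings, oriented blobs and
four-lobe crosses with distinct amplitudes (235 down to 60 over background
20, pixel noise SD 5) and distinct scales (σ from 0.35 to 0.6 mm) — so the
true landmark coordinate is exact by construction and sub-pixel checks are
meaningful. Two simulated annotators jitter the truth with independent
isotropic Gaussian noise; the default per-axis SDs (0.70 and 1.43 mm,
a careful and a less consistent observer) make the expected inter-annotator
distance $\sqrt{\pi/2}\,\sqrt{s_A^2 + s_B^2} = 2.0$ mm, the scale reported
for manual tracing. Isotropy is the minimal assumption given that only
scalar variabilities are reported.

What the generator does **not** emulate is anatomical context: a real
radiograph is textured everywhere, and a 9.1 mm patch 15 mm from Sella
still looks like "the Sella region". Synthetic structures are isolated
blobs on noise, so a coarse-stage patch that does not contain a structure
carries no information. The desk profile therefore adapts the coarse-stage
geometry rather than the method:

* `lrs_true_radius_mm = 0.9` — every true patch contains its structure's
  centre, keeping the true class homogeneous (with a 1 mm grid stride the
  nearest lattice point is at most 0.71 mm from the landmark, so at least
  one grid point always lies in the true disc);
* `lrs_patch_side_mm = 2.1` at native resolution
  (`lrs_downsample_factor = 1`) — the window is wide enough to contain a
  whole structure, whose sub-millimetre shape is what distinguishes
  neighbours and would not survive 3× block-mean downsampling;
* `roi_side_mm = 20` — a 40 mm ROI would span nearly the whole 50 mm
  synthetic frame, defeating the coarse-to-fine split;
* `hrs_pixel_stride_px = 2`, NT = 60 / NF = 300 per image, a reduced
  3-cluster architecture (depths 4/8/16, 3×3 kernels), 2,000 Adam steps at
  learning rate 0.005 in batches of 32;
* `n_hard_false = 60` hard negatives per image, drawn from the true regions
  of the *other* landmarks and labelled false. On real radiographs the
  false class is densely textured, so uniform sampling sees plenty of
  landmark-like negatives; on synthetic frames other structures occupy
  about 1% of the false region, and without explicit hard negatives a
  classifier can reach 99% training accuracy as a mere "bright structure"
  detector that fires on every landmark. With them, each coarse model
  responds to its own structure only, which is what the end-to-end
  recovery in the acceptance suite exercises.

Consequently, passing desk-scale tests demonstrates that the pipeline's
mechanics — sampling geometry, training contract, Monte-Carlo inference,
score weighting, ellipse calibration, metrics — are correct and that the
two-stage scheme recovers well-separated, locally distinctive structures to
sub-millimetre accuracy. It does not demonstrate full-scale radiographic
accuracy, which depends on real anatomy, the 400-image clinical dataset and
orders of magnitude more training.

Problem sizes used by the test suite and the acceptance script: 8 training
and 3 held-out frames with 5 landmarks for the end-to-end benchmark
(`desk_benchmark()`), 150 reduced frames for the patch-count check, and a
few hundred optimisation steps for unit-level classifier checks.

## Known limitations

* Landmarks are detected independently; no spatial-relationship model
  constrains implausible configurations.
* The uncertainty is the Monte-Carlo spread of one scalar output; it does
  not separate data noise from model uncertainty.
* The score scale $s_\sigma$ and the ellipse construction are documented
  interpretations where the reference protocol is silent.
* The desk profile's coarse stage relies on photometrically distinct
  structures; with near-identical structures the LRS stage needs contextual
  texture that the generator deliberately does not fake.
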