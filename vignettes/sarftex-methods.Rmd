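---
title: "Multi-scale co-occurrence texture features with self-attention random forests"
author: "SARFtex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale co-occurrence texture features with self-attention random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SARFtex)
```

## The problem

Histopathology and mammography classification from hand-crafted texture
features remains attractive where training data are too scarce for deep
networks and where interpretability matters clinically. SARFtex
implements a complete pipeline of that kind: multi-scale gray-level
co-occurrence (PGLCM) features, a shallow self-attention network (SAN)
that learns per-feature importance weights, and a random forest
classifier trained on attention-reweighted features (the SARF
composite), with out-of-bag permutation importance and a full
confusion-matrix/ROC evaluation suite.

## Feature extraction: PGLCM

Each image is reduced to a Gaussian pyramid: level 0 is the input, each
further level is smoothed with a separable Gaussian (sigma = 2/3, the
conventional choice for a downscale factor of two; borders are
edge-clamped so constant images stay constant) and decimated to
`ceiling(previous/2)`. Three levels are the default — on a 460-pixel
image the coarsest level still has >100 pixels per side, while a fourth
level adds little texture information on the 64-pixel test images used
throughout the test-suite.

Every level is quantized to 16 gray levels (uniform binning of
`[0, max]`; 16 keeps a 16x16 co-occurrence matrix well populated even
for 32x32 images while preserving the dynamic range of 8-bit input) and
a gray-level co-occurrence matrix (GLCM) is accumulated for each
(distance, angle) pair. The offset convention is: 0° = (0, +d)
(horizontal neighbor), 45° = (−d, +d), 90° = (−d, 0), 135° = (−d, −d);
matrices are symmetric (both pair orders counted) and normalized.
Defaults are distances {1, 2, 4} and all four angles.

Four Haralick statistics summarize each GLCM: contrast
$\sum_{ij} p_{ij}(i-j)^2$, correlation
$\sum_{ij} p_{ij}(i-\mu_x)(j-\mu_y)/(\sigma_x\sigma_y)$, energy
$\sum_{ij} p_{ij}^2$ (the angular second moment — conventions differ;
the square root is *not* taken), and homogeneity
$\sum_{ij} p_{ij}/(1+(i-j)^2)$. When a marginal variance is zero (a
constant image) correlation is defined as 1: a constant image is
perfectly self-correlated, and the convention keeps features finite.

The multi-scale fusion axis is the pyramid: for each (distance, angle,
statistic) the statistic is computed on every level's GLCM and the
across-level mean and standard deviation are emitted, named
`"i=<d>, <angle>° <mean|std> <stat>"` (so `"i=1, 0° std contrast"` is
the across-level standard deviation of contrast at distance 1,
direction 0°). With one pyramid level the standard deviation is defined
as 0. The vector length is `2 * 4 * |distances| * |angles|` (64 for
defaults restricted to two distances; 96 for the default three).
Aggregating across levels (rather than across angles) was a genuinely
open choice; the level axis is the one the pyramid construction adds,
so it is the one fused.

## The self-attention network

The SAN is a shallow network whose first layer multiplies the input
elementwise by a softmax attention distribution over the features:

$$\Omega(X) = \tfrac1k \bigoplus_k \left[X \otimes
  \mathrm{softmax}(W_{att}^k X + b_{att}^k)\right]$$

followed by a dense layer with SELU activation
($\lambda x$ for $x>0$, $\lambda\alpha(e^x-1)$ otherwise; defaults are
the standard self-normalizing constants $\lambda = 1.0507$,
$\alpha = 1.67326$), dropout (20%, training only), a sigmoid dense
layer and a softmax classification head. Training minimizes categorical
cross-entropy with Adam (learning rate 0.001) over 20 epochs of
shuffled minibatches of 16 — the published training setting. One
attention head is the default; the head count is configurable. All
gradients are derived analytically and verified against central finite
differences in the test suite; initialization, shuffling and dropout
are driven by a single seed, so training is bit-reproducible.

**Input scaling.** Attention-layer inputs are min-max scaled to
`[0, 1]` (stored in the model, replayed at prediction). Two reasons.
First, raw Haralick features span orders of magnitude (contrast can be
in the hundreds while energy is below 1), which saturates the attention
softmax. Second, and less obviously: the global importance readout
below uses the *diagonal* of the attention weight matrix, and the
diagonal only accumulates gradient where a feature's value correlates
with the benefit of attending to it. With zero-centered scaling the
informative features of a balanced two-class problem take symmetric
positive/negative values and that correlation cancels to first order —
the importance signal then migrates entirely into the attention bias,
which the readout cannot see. Keeping inputs non-negative preserves the
correlation and makes the diagonal an effective importance register.

**Global attention.** After training, the per-feature importance
distribution is
$R_G = \tfrac1k \bigoplus_k \mathrm{softmax}(\mathrm{diag}(W_{att}^k))$,
non-negative and summing to one.

**Residual fusion.** The classifier input is
$F_j' = F_j + F_j \cdot |F| R_{G,j}$: attention is rescaled by the
feature count so that *uniform* attention exactly doubles every feature
— a no-op for a threshold-based tree ensemble — and any deviation from
uniformity shifts relative feature scales monotonically in $R_G$. The
raw-weight alternative ($F + F \odot R_G$) is available via
`fuseFeatures(..., rescale = FALSE)`; the rescaled form was chosen
because it makes "no attention learned" classifier-neutral, which is
both interpretable and testable (the package asserts
prediction-identity between uniform-attention SARF and a plain forest).

## The forest and its diagnostics

The ensemble is bagged depth-bounded CART trees (Gini splitting,
$\sqrt{|F|}$ candidate features per split) fitted with the `ranger`
package, single-threaded and seeded, with per-tree in-bag counts
retained. Defaults: 200 trees of depth at most 20, the published
before-tuning setting. Prediction is majority vote; vote fractions are
exposed as probabilities and ties break to the lexicographically first
class label.

Out-of-bag permutation importance: for every tree $k$ with out-of-bag
set $B_k$ and feature $x_j$,

$$J(x_j) = \frac{1}{T}\sum_k \frac{1}{|B_k|}\left(
 \sum_{i\in B_k} I(h_k^{\bar{x_j}}(i)\ne y_i) - I(h_k(i)\ne y_i)\right),$$

with the permutation of $x_j$ drawn within $B_k$ under a master seed.
Negative values — permutation accidentally helping — are reported
unclipped; clipping would bias small importances upward. A feature
that is constant has an identity permutation and importance exactly 0.
Trees with empty out-of-bag sets are skipped with a warning.

Grid search over (depth, tree count) uses stratified k-fold
cross-validated accuracy (5 folds by default; every fold must contain
every class), step 1 over the configured ranges, with ties resolved to
the smallest depth and then the smallest tree count so the result is
deterministic and invariant to grid ordering.

## Evaluation suite

From an n-class confusion matrix (rows = truth): overall accuracy
`100 * trace/total`; one-vs-rest sensitivity TP/(TP+FN), specificity
TN/(TN+FP), positive prediction rate TP/(TP+FP) and negative prediction
rate TN/(TN+FN) per class. Zero denominators yield a flagged `NA`,
never a silent 0 or 100. Percentages are kept at full precision
internally; published tables round to two decimals, so the worked
examples are checked to ±0.01 percentage points.

ROC curves sweep the unique score values (ties grouped into single
steps) and integrate trapezoidally; the suite verifies the exact
equivalence to the Mann–Whitney pairwise concordance statistic (ties
counted ½). Multiclass AUC uses micro-averaging only: one-hot labels
and all class scores pooled into a single binary problem.

The three published confusion matrices bundled by
`referenceConfusionMatrices()` (BreaKHis binary and eight-subtype,
MIAS three-class) drive the worked-example tests; every metric printed
alongside those tables is recomputed by this module.

## Synthetic data: what it emulates and what it does not

The texture generator produces oriented sinusoidal gratings, smoothed
Gaussian random fields and checkerboards (64x64 by default, additive
Gaussian noise, seeded and byte-reproducible). Gratings were chosen
because their co-occurrence behavior is analytically predictable:
contrast at the offset parallel to the intensity gradient is high and
at the perpendicular offset low, so orientation differences must appear
in the angle-specific features — which the tests assert. The tabular
generator draws informative features from class-shifted normals
(adjacent class means one `effectSize` apart, in sd units) and noise
features from class-independent standard normals, returning the
ground-truth informative set.

None of this emulates real histopathology: no H&E staining variation,
no nuclear morphology, no magnification effects, no patient-level
correlation. Passing the synthetic benchmarks demonstrates that the
mechanics — feature extraction, attention recovery, importance ranking,
the pipeline plumbing — behave as specified, not that the published
benchmark accuracies transfer to clinical data.

Problem sizes used by the packaged checks were chosen to keep each
property informative at desk scale: the end-to-end benchmark uses two
grating classes of 100 images at 64x64 with a stratified 70/30 split;
attention recovery uses 10 runs of 500 samples with 3 informative of 20
features at effect size 3; importance ordering uses 10 runs of ~100
samples and 30–40 trees.

## Numerical and degenerate-input choices

* Softmax subtracts the row maximum (shift-invariant, overflow-proof).
* The pyramid errors when a requested level would fall below 2x2,
  naming the failing level; GLCM computation errors when the offset
  admits no pixel pair.
* Quantization is `floor(v * levels / (max+1))`, order-preserving,
  identity at 256 levels for 8-bit input.
* Only lossless quarter-turn rotations and axis mirrors are offered as
  geometric augmentations (arbitrary angles would interpolate);
  photometric enhancement factors default to 1.2, and factor 1 is the
  exact identity for all four kinds.
* Class balancing samples source images uniformly with replacement
  under a required seed and never discards originals.
* The training split is stratified per class (the published protocol
  divides "in the same proportion"); a patient-wise split is not
  implemented because the synthetic fixtures have no patient structure
  — with real archives where images share patients, an image-wise
  split optimistically biases held-out estimates.

## Known limitations

* The SAN is a single attention block, not a transformer stack;
  attention is over features, never over samples.
* Eq.-style macro-averaged multiclass ROC is deliberately absent;
  micro-averaging is the implemented (and published) choice.
* The exact augmented-sample counts of the published experiments are
  not reproducible (per-image multiplicities were not stated);
  balancing targets are configurable instead.
* Published benchmark accuracies on BreaKHis/MIAS require those
  archives and are out of scope; the bundled confusion matrices cover
  the arithmetic, not the datasets.
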