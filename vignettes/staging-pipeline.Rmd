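---
title: "Methods: interest-point descriptors and cross-validated staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interest-point descriptors and cross-validated staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adstage)
```

This vignette is the package's own account of its method: the models and
procedures it implements, the parameters that matter, the numerical choices
made where a convention was genuinely open, and what the synthetic phantom
experiments do and do not demonstrate.

## Problem setting

Structural MRI of dementia shows a characteristic progression: ventricles
enlarge, the cortical ribbon thins, and sulci widen as atrophy advances
from cognitively normal (CN) through mild cognitive impairment (MCI) to
Alzheimer's disease (AD). `adstage` stages single 2D slices along this
continuum using handcrafted local features rather than end-to-end deep
learning: local structure is located with a corner detector, summarized by
oriented-gradient histograms, pooled per image, and classified. Every
intermediate object — points, patches, histograms, feature tables, fold
assignments — is an inspectable value with a stable contract.

All grids in the package are 1-based `(row, col)` with rows increasing
downward; this convention is used everywhere, including the CSV interfaces.

## Preprocessing

Input slices are min–max stretched to [0, 1] ("histogram stretching"): a
strictly monotone map, so pixel ordering is preserved and the operation is
idempotent. A percentile-anchored variant (1st/99th, clipped) is available
for data with hot pixels; the default is the plain stretch because the
phantom generator and most research MR exports have no extreme outliers.

Smoothing uses a discrete 5×5 Gaussian with σ = 1 pixel, evaluated on the
centred integer lattice from
$G(x,y) = \frac{1}{2\pi\sigma^2} e^{-(x^2+y^2)/(2\sigma^2)}$
and renormalized to sum to one, so constant (DC) regions are preserved
exactly. Convolution pads by **border replication**: a deliberate choice —
zero padding would fabricate a dark halo whose artificial gradients the
corner detector downstream would happily report as structure.

Morphological cleanup removes islands: the slice is thresholded with Otsu's
method, the binary mask is opened with a 3×3 box element, connected
components smaller than `min_object_px` (default 64 px) are dropped, and
the image is zeroed outside the surviving mask. Intensities inside
surviving objects are untouched. Otsu is our choice of threshold; the goal
(suppress small objects and thin lines while preserving large structures)
constrains the design, not the specific threshold rule.

Volumes arrive as NIfTI (`.nii`/`.nii.gz`, read with `RNifti`); they are
optionally resampled to uniform voxel size by trilinear interpolation
(written in-package; exact on affine intensity fields, verified against an
analytic ramp) and sliced. Because no convention for slice selection is
universal, the default policy takes **9 centred slices along the third
axis**; explicit index lists are accepted. Skull stripping and template
registration are out of scope: masking plus resampling is a stand-in, and
results on real data will depend on upstream anatomy-aware preprocessing.

## Interest points

Gradients are unscaled central differences,
$g_x(r,c) = I(r,c+1) - I(r,c-1)$ and $g_y(r,c) = I(r-1,c) - I(r+1,c)$
(the sign makes $g_y$ point "up" the image), replicate-padded at borders.
The structure tensor sums $g_x^2$, $g_x g_y$, $g_y^2$ over a 5×5
**rectangular** window (a Gaussian window is available), and the corner
score is $R = \det(M) - k\,\mathrm{trace}(M)^2$.

Parameters the detector exposes, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `k` | 0.04 | response constant; the classic Harris choice, in (0, 0.25) |
| `window_size` | 5 px | structure-tensor summation window |
| `rel_threshold` | 0.01 | keep maxima ≥ this fraction of max(R) |
| `nms_radius` | 5 px | Euclidean non-maximum suppression radius |
| `max_points` | 200 | per-slice budget, by descending response |
| `border` | 8 px | margin so a 16×16 patch fits |

Thresholding is **relative** to the per-slice maximum response because
absolute R scales with the fourth power of image contrast; a fixed absolute
threshold would couple detection density to normalization. Non-maximum
suppression (strict 3×3 local maxima, then greedy radius suppression with
ties broken by image position for determinism) is necessary to avoid
clusters of near-duplicate detections along the same corner. Points too
close to the border are **dropped, not padded**: padding would fabricate
gradient structure inside descriptors. Useful invariants, all tested: R is
exactly invariant to additive intensity shifts, scales as the fourth power
under intensity scaling, and detection sets commute with 90° rotations to
within one pixel.

## Patch descriptors

Around each point a 16×16 patch is cut and divided into 4×4 cells of 4×4
pixels. Each pixel votes its gradient magnitude
$\mu = \sqrt{g_x^2 + g_y^2}$ into 8 orientation bins of 45° covering the
**signed** range [0, 2π) — the quadrant-aware angle of $(g_x, g_y)$; an
unsigned [0, π) mode exists behind a flag. Votes are split linearly between
the two bins whose centres bracket the angle (circular soft binning):
with bin width $w = 2\pi/8$ and fractional position $p = \theta/w - 0.5$,
the bins $\lfloor p\rfloor$ and $\lfloor p\rfloor + 1$ (mod 8) receive
$(1 - \mathrm{frac})\,\mu$ and $\mathrm{frac}\,\mu$. This soft assignment
removes aliasing at bin boundaries and conserves vote mass exactly: each
cell's bins sum to its total gradient magnitude, a property the test suite
asserts to 1e-9.

The 16 cell histograms concatenate (cells row-major, bins innermost) to the
128-dimensional descriptor (4 × 4 × 8). Normalization follows standard
block practice: the 4×4 cell grid is tiled by four non-overlapping 2×2-cell
blocks; each block's 32 values are divided by $\sqrt{\lVert v\rVert^2 +
\epsilon^2}$ ($\epsilon$ = 1e-6), clipped at 0.2 to bound the influence of
any single dominant gradient, and renormalized. Non-overlapping tiling (not
the sliding arrangement that would give 9 blocks and 288 values) is what
keeps the printed 128-dimensional layout; it also makes the descriptor
exactly equivariant under 90° patch rotations (cells remap, bins shift by
two positions), which the tests verify with clipping disabled.

The binarized orientation-shift code compares two cells' histograms under
all cyclic shifts: $b_{c_1,c_2}(k,\varepsilon) = 1$ iff $v_{c_1}(k) \ge
v_{c_2}((k+\varepsilon) \bmod 8)$, ties giving 1 exactly as the ≥ reads.
Cell pairing is the 4-neighbourhood of the cell grid — 12 horizontal + 12
vertical = 24 pairs, each an 8×8 bit matrix. The code is an optional
feature channel (off by default): when enabled, the per-pair bit counts (24
values, scaled to [0, 1]) are appended to the pooled feature vector. We
left it off by default because the comparison operator makes it a
similarity analysis between regions, and its contribution to the
classifiers is a separate empirical question from the descriptor proper.

**Pooling.** Slices yield variable point counts, classifiers need fixed
width. The default pools patch descriptors by element-wise mean *and*
element-wise max (128 + 128 = 256 values, matching the MLP input width);
mean-only (128) is selectable. Both are permutation-invariant in the
patches. A slice with no detections yields a zero vector and a warning
rather than an error, so a degenerate image cannot abort a study.

## Classifier heads

All heads standardize features to zero mean and unit variance using
**training-fold statistics only**; the standardizer is part of the stored
model and the test suite checks that test rows cannot influence it.

* **SVM** — one-vs-rest ensemble of binary soft-margin SVMs (libsvm through
  `e1071`; re-implementing the QP solver is explicitly not this package's
  business). Default kernel RBF with $C = 1$ and
  $\gamma = 1/(p \cdot \overline{\mathrm{Var}})$ on the standardized
  matrix (≈ 1/256); linear, polynomial and sigmoid kernels are
  configurable. One-vs-rest (not libsvm's native one-vs-one) is used
  because the ensemble-of-N-binary-classifiers construction is the
  multiclass scheme this pipeline specifies; prediction takes the class
  with the largest binary decision value.
* **KNN** — k = 1 by default, Euclidean distance, implemented directly
  because the tie rule is pinned: majority vote among the k nearest, ties
  resolved by the label of the single nearest neighbour. Agreement with
  `class::knn` (k = 1) and an exhaustive-distance oracle is tested.
* **DNN** — a multilayer perceptron written in base matrix algebra:
  256 inputs → 9 hidden ReLU layers → 3-way softmax. Hidden widths are not
  constrained beyond the count, so the package uses a constant 128 units
  per layer — the simplest reproducible choice, configurable. Training:
  Adam (lr 0.01, β₁ 0.9, β₂ 0.999), batch size 32, at most 50 epochs,
  inverted dropout 0.3 between hidden layers, L2 weight decay 0.001 on
  weights (not biases), and early stopping that halts after 10 consecutive
  epochs without improvement of the loss on a stratified 80:20 inner
  validation split, restoring the best-validation weights. Initialization
  is He-scaled and seeded; in single-threaded BLAS the whole fit is
  reproducible bit for bit, which the determinism tests rely on.

Augmentation (seeded rotation, flips, shifts, scaling, cropping, Gaussian
noise) is implemented and tested but **off by default**: the cleanest
reading of the protocol is that the classifier comparison runs on
unaugmented features, and the cross-validation harness enforces that
augmented samples derive only from training-fold images — a leak raises an
error, it is not merely discouraged.

## Evaluation protocol

Stratified 5-fold cross-validation: within each class a seeded random order
is dealt round-robin, so per-class fold counts differ by at most one and
every sample is tested exactly once (asserted at run time). Per fold, the
other four folds train the head (the MLP carving its inner 80:20 validation
split from them); metrics come from the per-fold confusion matrix with the
fixed class order CN, MCI, AD.

Per class $c$, one-vs-rest counts give accuracy $(TP+TN)/(TP+TN+FP+FN)$,
precision $TP/(TP+FP)$, recall $TP/(TP+FN)$, specificity $TN/(TN+FP)$ and
F1 $2TP/(2TP+FP+FN)$; macro averages are unweighted means, and multiclass
accuracy is trace/total. Precision and specificity are deliberately
distinct functions — formula collisions between the two are a recurring
copy-editing accident in the applied literature, so both are implemented
and tested against a label-level oracle. Zero denominators report 0 with a
`flagged` column, never NaN. Headline accuracy is reported both as the
**unweighted fold mean** (the default summary) and **pooled** over the
summed confusion matrix; with equal fold sizes the two coincide, and both
are emitted so either convention can be compared against.

ROC curves are one-vs-rest threshold sweeps over each class's score column
(decision values for SVM, vote fractions for KNN, softmax probabilities for
the MLP) with trapezoidal AUC, cross-checked against `pROC` in the tests.

## The phantom generator

The synthetic classes emulate the gross geometry the staging problem turns
on, at known effect sizes: a bright skull ring, a CSF gap, a mid-grey
cortical ring, a white-matter annulus, dark central ventricles, seeded dark
notches on the cortical ring ("sulcal widening"), and additive Gaussian
noise, clipped to [0, 1]. Defaults — frozen once as the package's study
conditions:

| class | ventricle scale | cortical thickness | notches |
|---|---|---|---|
| CN | 0.14 | 11 px | 0 |
| MCI | 0.23 | 8 px | 6 |
| AD | 0.32 | 5 px | 12 |

with image side 96 px, noise σ 0.03, and per-image jitter (ventricle ±
0.015 SD, thickness ± 1 px, notches ± 1) so classes are distributions, not
constants. The effect sizes were chosen so that the full pipeline at 150
images per class clears 0.90 fold-mean accuracy on the MLP head and 0.85 on
SVM and 1-NN — a property of the **harness**, documented so the acceptance
run is interpretable; it is not a claim about brains. Raising `noise_sigma`
toward 0.3 with small structural deltas drives all heads toward chance,
which is how the suite checks that the protocol does not leak labels.

What passing these tests shows: the geometry, code paths, seeding and
protocol are correct, and the feature chain separates classes that differ
the way the phantoms differ. What it does not show: performance on clinical
MRI, where intensity inhomogeneity, anatomy-dependent texture, scanner
effects and registration error dominate — none of which the phantoms model.

## Numerical choices and degenerate inputs

* Convolution borders: replicate padding everywhere (smoothing, gradients,
  tensor windows), keeping edge gradients finite.
* Detection ties: candidate ordering breaks response ties by (row, col) so
  NMS is deterministic.
* Binarization ties: ≥ , so ties give 1.
* Constant slices: normalization warns and returns zeros; detection warns
  and returns an empty point set; pooling of zero patches warns and
  returns a zero vector. Nothing in the chain converts a degenerate image
  into an exception mid-study.
* Seeds: one global seed; each stage derives its own stream via
  `derive_seed(seed, stage_name)` (kept below 2³¹), so any stage can be
  rerun in isolation with identical results.
* Problem sizes used by the shipped experiments: the acceptance study runs
  150 images per class (450 total, the package's study-scale default);
  unit and property tests use 6–30 images or direct 16×16 patches.

## Known limitations

* 2D only: volumes are sliced; no 3D descriptors or inter-slice context.
* No anatomical realism in the phantoms (no tissue relaxometry, bias
  fields, or acquisition physics) and no skull-stripping/registration
  stand-in beyond masking and resampling.
* The descriptor is single-scale; no scale-space detection or subpixel
  refinement.
* The MLP is a reference implementation tuned for determinism and
  inspectability, not speed on large cohorts.
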