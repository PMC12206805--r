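---
title: "hyperleaf: models, design choices and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hyperleaf: models, design choices and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hyperleaf` implements a complete visible/near-infrared (400–1000 nm)
hyperspectral pipeline for classifying leaves into six composite-disease
groups — healthy, virus-infected, nitrogen-deficient, nitrogen-deficient +
virus, pesticide-damaged, pesticide-damaged + virus — as encountered in
citrus yellow vein clearing disease surveys. This vignette explains the
models the package implements, the parameters that matter, what the
synthetic generator does and does not emulate, and the numerical choices
behind the implementation.

## Reflectance calibration and region of interest

Raw line-scan intensities are converted to reflectance with a white
reference (a ≈99% diffuse reflectance standard) and a dark reference
(lens-closed scan):

$$ R = \frac{I_{raw} - I_{dark}}{I_{white} - I_{dark}}. $$

The ratio removes illumination non-uniformity and dark current, and is
invariant to any common affine rescaling of the three scans. Elements with
a degenerate denominator (|white − dark| < 1e−6) are zeroed and counted;
more than 1% of them aborts the calibration, since that indicates a broken
reference scan rather than a few dead pixels.

Leaves are far brighter than a dark background on the NIR plateau, so the
leaf mask is obtained by Otsu's histogram threshold on the band nearest
800 nm, keeping the largest 8-connected component and filling holes
(standard mask hygiene; holes are 4-connected background components that
do not touch the image border). The mean spectrum over the mask is the
unit of chemometric analysis; per-pixel spectra only feed the CNNs.

Analysis is restricted to 400–1000 nm. On the package's working axis this
window holds 761 bands; a 995-point axis on 305–1090 nm stands in for a
full sensor range in cropping tests (the true native band count of such a
sensor is not modelled).

## Spectral preprocessing

The standard normal variate (SNV) transform centres and scales each
spectrum to zero mean and unit standard deviation (sample, n−1
denominator). It removes multiplicative scatter and additive baseline
shifts caused by surface texture and path-length variation. SNV is
idempotent and invariant to positive affine maps of a spectrum; both
properties are enforced by tests. Constant spectra have no SNV image and
raise an error naming the offending row.

## Wavelength selection

**CARS** (competitive adaptive reweighted sampling) runs `N` Monte-Carlo
iterations (default 50, configurable — reference implementations often use
runs in the thousands; 50 keeps a desk-scale run in seconds while
preserving the selection behaviour). Each iteration draws 80% of the rows,
fits a PLS2 model on the surviving variables, and scores each variable by
the L2 norm of its row of the coefficient matrix. Survival is governed by
the exponentially decreasing function
$r_i = a e^{-k i}$ with $a = (p/2)^{1/(N-1)}$ and $k = \ln(p/2)/(N-1)$,
so run 1 keeps all $p$ variables and run $N$ keeps 2; adaptive reweighted
sampling (weighted draws with replacement) then thins the enforced set
further. The subset with the lowest 5-fold RMSECV wins. The number of PLS
components is fixed once, on the full matrix, by cross-validated RMSECV
over 1–10 components — tuning it per run would multiply the cost for
little benefit at these problem sizes.

Because classes are categorical, PLS runs in PLS2 form on one-hot
responses and variable importance is the row norm of the `p × K`
coefficient matrix — the standard multi-class extension of CARS.

**SPA** (successive projections algorithm) builds, from every possible
starting band, a chain of maximally orthogonal bands: each step appends
the band with the largest residual norm after projecting out the span of
the chain so far. Every chain prefix is scored by multiple linear
regression on one-hot labels and RMSEP on a validation fold; the global
minimiser is then shortened to the smallest prefix whose RMSEP is not
significantly above the minimum (F-test on the squared-error ratio at
α = 0.25, degrees of freedom = number of validation response entries).
The projection geometry is computed on the Gram matrix `X'X` with
incremental Gram–Schmidt updates, which is algebraically identical to
projecting the columns of `X` but reduces each step from O(np) to O(pm).

PLS itself is a NIPALS implementation written for this package: scores,
loadings and weights are exposed, the coefficient matrix is
`B = W (P'W)^{-1} Q'`, and predictions add the centring intercept.
Deflation tolerances (1e−10 on the score vector, 1e−14 on norms) follow
common chemometric practice; components with vanishing score variance
truncate the model rather than erroring.

## Classical classifiers

PLS-DA predicts the argmax of the one-hot PLS2 response; the component
count is grid-searched (default 1–20, capped by rank) on validation
accuracy with ties resolved toward fewer components. The RBF-kernel SVM is
libsvm's one-vs-one multi-class machine (via `e1071`) with the usual
exponential grids `C = 2^{-5..15}` and `γ = 2^{-15..3}` (step 2); ties
resolve toward smaller `C`, then smaller `γ`. SVM input is expected to be
SNV-corrected; spectra are not re-scaled internally (the grid covers the
relevant γ range for unit-variance rows).

## The network family

Five architectures share one vocabulary: ShuffleNetV2 *basic* units
(channel split, 1×1 conv + BN + ReLU, 3×3 depthwise + BN, 1×1 conv + BN +
ReLU, concatenation, channel shuffle with 2 groups) and *downsampling*
units (both branches strided; concatenation doubles the channels). The
channel shuffle is the fixed reshape–transpose permutation that mixes
information across branch groups.

* **3D-2D hybrid (`hybrid_lcnet`)** — input `1 × N × 112 × 112`
  (N spectral bands kept by CARS or SPA, 30 or 15 in the reference
  protocol; any N ≥ 8 works). Two 3×3×3 convolutions with stride 2 on all
  axes (1→16→32 channels, BN + ReLU after each) shrink the spectral axis
  N → ⌈N/2⌉ → ⌈N/4⌉ (30→15→8, 15→8→4) and the spatial axes 112→56→28.
  Adaptive average pooling reduces the spectral depth to 2 (spatial axes
  untouched), and the `32 × 2` channel/depth pair is reshaped into a
  64-channel 2-d map at 28×28. Four units follow: down 64→128 (14×14),
  basic 128, down 128→256 (7×7), basic 256; then a 1×1 convolution to 512,
  global average pooling, dropout 0.2 and a linear classifier. The stem
  widths 16/32 are the unique choice that makes the documented
  28×28×64 reshape work and lands the parameter total at 0.26 M.
* **`lcnet3d`** — identical stem and pooling, but the four units and head
  stay 3-d on the depth-2 volume (3×3×3 depthwise, 1×1×1 pointwise,
  strides (1,2,2)), with unit widths matching the hybrid (down 32→128,
  basic 128, down 128→256, basic 256). Relative to the hybrid only the
  depthwise kernels inflate, which reproduces the published 0.26 M →
  0.27 M parameter step.
* **`lcnet2d`** — bands-as-channels 2-d counterpart (stem N→16→64, then
  the same four units and head). This is a minimal reconstruction — the
  source architecture was never fully specified — so its parameter total
  (0.26 M here) is not treated as a reproduction target.
* **`shufflenetv2_2d` / `shufflenetv2_3d`** — ShuffleNetV2 at width
  multiplier 0.25: first conv to 24 channels (stride 2), 3×3 max-pool
  (stride 2), stages of 32/64/128 channels with 4/8/4 repeats, head conv
  to 1024. The 3-d variant strides the spectral axis only in the stem.

Convolutions followed by BN carry no bias; the final linear layer has the
only bias. Initialisation is Kaiming-normal, seeded; BN starts at
unit scale/zero shift with momentum 0.1 and ε = 1e−5.

Parameter counts are computed twice — by summing the stored arrays and by
closed-form per-layer formulas — and the two must agree exactly. FLOPs are
reported as 2 × multiply-accumulates over convolution and linear layers
only, for one input; the convention is embedded in every report because
published FLOP figures rarely state theirs, which is why printed FLOP
values are not used as reproduction targets.

### Numerical engine

No deep-learning framework is assumed: the forward/backward passes are
implemented in this package with im2col + BLAS GEMM kernels
(RcppArmadillo) in single precision — convolution stacks of this size are
GEMM-bound, and float halves both arithmetic and memory traffic without
affecting classification behaviour. Two execution paths exist: a generic
one-layer-at-a-time path used for audits, and fused fast-path kernels (the
3-d stem as one block; pointwise+BN+ReLU and depthwise+BN blocks in the
2-d stage) whose buffers persist across batches. Both paths share weights
for a given seed and agree to float precision; a test asserts this
equivalence, and finite-difference checks validate the gradients
end-to-end. Training is plain Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e−8) with
cross-entropy loss, initial learning rate 0.001 halved every 20 epochs,
batch 64 and 200 epochs in the reference protocol; the best-validation
checkpoint is returned. All randomness (shuffling, dropout,
initialisation) derives from the configured seed, so equal seeds give
identical histories.

The evaluation protocol keeps a fixed test fold and re-splits the
remaining 80% into 60/20 train/validation shares per repetition
(default 5); per-architecture accuracies are compared with Kruskal–Wallis
followed by Dunn's pairwise z tests with Bonferroni correction and a
compact letter display (groups sorted by median; groups that are not
significantly different share a letter).

## Metrics

Each class is collapsed one-vs-rest to (TP, TN, FP, FN) and scored by
accuracy, precision, recall, F1 and the Matthews correlation coefficient;
macro values are unweighted class means and overall accuracy is
trace/total. MCC is a binary statistic, so the multi-class value is
reported as the macro mean of per-class binary MCCs, consistent with the
macro treatment of the other metrics. Any 0/0 term is defined as 0. ROC
AUC is the midrank Mann–Whitney statistic per class one-vs-rest, macro
averaged over the classes present.

## The synthetic leaf generator

No public hyperspectral dataset exists for this six-class design, so the
package ships a seeded simulator that provides ground truth for every
pipeline stage. Its defaults are fixed once and define the study
conditions for all tests:

* **Spectra.** A common green-leaf template (low blue ≈0.06, green peak
  ≈0.15 at 550 nm, chlorophyll trough ≈0.05 at 680 nm, logistic red edge
  680–750 nm, NIR plateau ≈0.48) plus class offsets: an additive visible
  offset on 500–680 nm (0, 0, 0.04, 0.05, 0.065, 0.075 for classes 1–6)
  and an additive NIR offset of −0.06 for the virus-bearing classes
  (2, 4, 6). The offsets keep the two physiological contrasts — healthy
  and virus-only leaves lowest in the visible; virus-infected leaves
  depressed on the NIR plateau — while making all six templates pairwise
  distinct, so the default configuration is fully separable. Offset
  windows have 15 nm raised-cosine edges. The amplitudes are stand-ins
  chosen for clear separability, not measurements.
* **Scenes.** Elliptical leaves (axis ratio 1.4–2.6, random orientation,
  sinusoidal boundary) on a dark background (≈0.02), with a smooth ±10%
  multiplicative brightness field (mean 1 over the leaf) and per-pixel
  Gaussian jitter (sd 0.02).
* **Mean spectra.** A fast path draws leaf-level spectra directly:
  template × multiplicative scatter (sd 3%) + baseline shift (sd 0.005) +
  band noise (sd 0.003). This is the chemometric fixture.
* **Counts.** 90/90/79/81/90/92 leaves per class (522 total) by default.

For wavelength-selection recovery the broad-offset classes are the wrong
ground truth: SNV couples every band to the row mean and standard
deviation, so with broad offsets *every* band carries some class signal
and selectors legitimately pick scatter-reference bands outside the
physiological windows. Recovery experiments therefore use the
*planted-band* profiles: class signal exists only in ten narrow Gaussian
bumps (sd 5 nm; five in the chlorophyll window, five on the NIR plateau)
with a fixed class × band amplitude design `0.045((kj mod 11) − 5)/5`
that gives every class a distinct signature at every planted band. A
selector that works must concentrate its picks within a few nm of the
planted centres; the package scores the pooled fraction of selected
wavelengths falling within ±10 nm of a ground-truth window across five
generator seeds.

What the generator does **not** emulate: radiative-transfer realism
(PROSPECT-style leaf optics), vein and lesion texture, sensor noise
physics, smile/keystone distortions, or overlapping/occluded leaves.
Passing tests therefore demonstrate that the algorithms are implemented
correctly and behave as designed on data with known structure — not that
field accuracies on real orchard scans would match.

## Desk-scale validation sizes

The test suite runs everything at sizes a single CPU handles comfortably,
as the package's own validation design: selector recovery uses 300
spectra × 761 bands over 5 seeds; classifier sanity uses 300 spectra with
a 60/20/20 split; the imaging study trains the hybrid network on 600
simulated 112×112×15 scenes (100 per class, 60/20/20) for 15 epochs at
batch 16 over five seeds and requires a median test accuracy of at least
0.90; shrinking the class offsets toward zero drives accuracy toward the
1/6 chance level. The reference protocol's full 200-epoch schedule is
exercised symbolically (learning-rate checkpoints) and through short
training runs.

## Known limitations

* The 2-d counterpart network is a reconstruction; only its unit
  vocabulary, not its exact original topology, is certain.
* CARS's default 50 sampling runs trade fidelity to reference
  implementations (thousands of runs) for runtime; the run count is a
  configuration field.
* Sub-block geometry: the nominal window length
  `ceil(L/(k − (k−1)·overlap))` can violate the 30% pairwise-overlap cap
  once starts are rounded to pixel grids on short leaves; the window is
  shrunk minimally (never below the coverage bound `ceil(L/k)`) until the
  cap holds.
* The CNN engine is CPU-only and single-threaded by design; it is meant
  for desk-scale experiments and audits, not production training.
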