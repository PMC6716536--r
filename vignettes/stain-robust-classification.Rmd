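---
title: "Stain-robust patch classification: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stain-robust patch classification: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stainShift)
```

# The problem

Patch-level classifiers in computational pathology are trained on images
whose color depends on the preparing laboratory: dye concentrations,
section thickness and scanner hardware all shift the apparent stain.
A network trained on one center's appearance often ranks and calibrates
patches from another center much worse, even when the underlying
morphology is unchanged. This package implements and compares, end to end
on a controllable synthetic cohort, the three standard counter-measures:

* **stain normalization** — re-render every image in a fixed template's
  color frame (Macenko estimation + Beer–Lambert rendering);
* **color augmentation** — random channel-wise affine perturbations at
  training time;
* **domain-adversarial training (DANN)** — a two-head network whose shared
  features are trained to support the task while defeating a domain
  classifier through a gradient-reversal path.

# Color physics

All color reasoning happens in optical-density (OD) space. With background
intensity $I_0$ (default 255) and natural logarithms throughout, a pixel's
transmitted intensity in channel $c$ is

$$I_c = I_0 \exp(-S_c \cdot C),$$

where $S$ is the $2\times3$ matrix of per-channel absorbance coefficients
of hematoxylin and eosin and $C \ge 0$ the per-pixel concentration pair.
`rgbToOD()` inverts this with an intensity floor of 1 (raw 0 would give
infinite absorbance), `odToRGB()` applies it with rounding and clipping to
$[0,255]$, and `renderPatch()` composes $C \cdot S$ and the transmission.
Stain rows are stored unit-normalized; the scale lives in the
concentrations. This removes the multiplicative ambiguity of the
$S \cdot C$ factorization.

# Macenko estimation and template normalization

`estimateStainMatrix()` keeps pixels with OD above 0.15 in at least one
channel (pixels below it in every channel are background; requiring all
three channels to clear the threshold would discard pure-eosin pixels,
whose red absorbance is only 0.07 per unit concentration, and bias the
eosin direction by several degrees). The 2-D plane of the retained OD
cloud is taken from the SVD of the mean-centered pixels, but the retained
pixels are projected onto that plane *anchored at the origin*: stain
vectors are directions from zero absorbance, so angles must be measured
from the origin, not from the centroid. The directions at the 1st and 99th
percentile angles are the stain estimates ("clipping extreme values" with
the established defaults). Rows are labeled by angular proximity to the
canonical reference vectors (H $\approx(0.65,0.70,0.29)$,
E $\approx(0.07,0.99,0.11)$): the assignment minimizing the total angle is
taken. Simpler rules — larger red absorbance, or larger angle to the blue
axis — flip for strongly shifted stains (a $\sim$30° hue rotation can give
the eosin row the larger red coefficient), which silently swaps the
concentration channels during normalization; the nearest-canonical
assignment stays correct whenever each stain remains closer to its own
identity than to the other's, which the cohort generator also enforces
when drawing center stains. An image whose retained OD pixels span less
than 5° of angle is rejected as single-stain.

`estimateConcentrations()` solves the per-pixel two-variable non-negative
least-squares problem in closed form (unconstrained normal equations with
an active-set fallback, negatives clipped), vectorized over pixels.

`normalizeStains()` follows the template scheme: brightness-standardize,
estimate the source's own stain matrix and concentrations, rescale each
concentration channel by the ratio of the template's to the source's 99th
percentile, and re-render through the *template* stain matrix. Brightness
standardization converts to CIELAB and rescales L so its 95th percentile
maps to maximal lightness — the minimal transformation making "at least 5%
of the pixels white". It is idempotent up to round-off. Note that for
images without any near-white region the standardization brightens
substantially; the normalization fixed-point and convergence properties
are therefore stated (and tested) on patches that contain background
pixels, which is also the realistic case.

The template is an explicit, user-chosen input (`fitTemplate()`): the
method is known to be sensitive to the reference image, so the package
never picks one silently.

# Heatmap-guided patch extraction

`computeHeatmap()` scores each pixel on the raw 0–255 channel scale:

$$h_1 = \tanh\!\big(2(B-R)/(G+1) + 0.5\big) + 0.5,\quad
  h_2 = \tanh\!\big((640-R-G-B)/300 + 0.5\big) + 0.5,$$
$$h = 0.5\,\tanh(h_1 h_2 - 1.75) + 0.5 \in [0,1].$$

$h_1$ responds to purple hue (blue over red), $h_2$ to darkness; the
constants 640 and 300 presume unnormalized channels. Locations with
$h > 0.65$ count as tissue. `sampleLocations()` thresholds at the patch
*center* pixel by default (the simplest faithful reading; a window-mean
rule is available via `rule = "mean"`), samples uniformly without
replacement, and returns 0-based top-left origins of half-open windows.
The 10X-magnification context of the original heuristic is metadata only;
the arithmetic is resolution-agnostic.

# Color augmentation

`applyColorAugmentation()` implements $I_c' \leftarrow a_c I_c + b_c$
per channel with clipping, in RGB (default), HSV, or HED space. In HED the
fixed canonical H-E-DAB deconvolution matrix is used rather than a
per-image estimate, deliberately decoupling augmentation from the
normalization module. Defaults $a \in [0.9, 1.1]$, $b \in [-10, 10]$
(intensity levels) are conservative; the source ranges are not published,
so they are configuration, not claims. Shifts are rescaled by $1/255$ in
the unit-scale spaces. Fresh parameters are drawn per image presentation.
When combined with normalization, normalization is applied offline first
and augmentation online second; the order is an interpretation, flagged as
such.

# The domain-adversarial core

The two-head model (`buildModel()`) is a compact trunk — two convolutions,
two blocks of convolution + batch-normalization + max-pooling, dropout
(0.25), one more conv/BN/pool block — feeding a task head
(dense-128 → dense-2; the 128-wide layer is the exported feature
embedding) and, when adversarial, a domain head behind a gradient-reversal
node placed before any dense layer (color-sensitive units concentrate in
early layers, so the reversal must reach them).

Training (`trainModel()`) is plain SGD implementing the saddle-point
updates literally:

$$\theta_f \leftarrow \theta_f - \mu\big(\partial L_y/\partial\theta_f
  - \lambda\, \partial L_d/\partial\theta_f\big),\qquad
\theta_y \leftarrow \theta_y - \mu\, \partial L_y/\partial\theta_y,\qquad
\theta_d \leftarrow \theta_d - \mu\lambda\, \partial L_d/\partial\theta_d.$$

Because the domain-head rule carries the factor $\mu\lambda$, the warmup
($\lambda = 0$ for the first 100 iterations, the published setting) leaves
both the reversal path and the domain head inert — an adversarial run with
$\lambda = 0$ throughout reproduces the task-only baseline bit for bit at
matched seed, which the tests assert. $\mu = 0.01$ (the compact-model
value); $\lambda = 1$ after warmup (the operating $\lambda$ is not
published; 1.0 is the package default, exposed in `trainConfig()`).

Batches are domain-balanced: exactly `batchSize / nDomains` samples per
domain, minority domains drawn with replacement, domains presented to the
loss as one-hot labels. The same sampler feeds task-only baselines so the
two training paths differ only in the adversarial term. Within each
domain's quota the two task classes are drawn evenly and minority-class
duplicates receive random rotations/flips (the imbalance treatment:
geometric augmentation of the rare class only).

Two calibration-minded choices that are configuration, not model changes:
label smoothing of 0.1 on both cross-entropies (without it a separable
synthetic task drives logits to saturation and every decision threshold
becomes degenerate), and early stopping on validation F1 (snapshot with
the best validation F1 at its optimal threshold, checked every 25
iterations, restored at the end; a stopping rule is not published, so this
is a package design choice).

**Domain-only (n′) samples.** The DANN objective explicitly covers
samples for which only the domain label is known, including images from
the test distribution. `trainModel(domainOnlyImages=, domainOnlyDomains=)`
feeds such samples to the domain loss and the adversarial trunk update
while keeping them out of the task loss; their task labels are never read.
The mode is off by default. The experiment runner, however, enables it for
its adversarial arms (`externalDomainsForDann = TRUE`): with three
training centers whose stains differ by only a few degrees, adversarial
invariance learned on them alone does not extrapolate to a far-outside
external center — at desk scale the external advantage of DANN then
reduces to run-to-run noise. Supplying the external images as unlabeled,
domain-only samples is the semi-supervised adaptation regime under which
the adversarial feature alignment covers the shifted center, and is the
configuration under which the package's internal/external comparison is
run. The baseline arms never see these images in any form.

# The synthetic cohort

`makeCohort()` generates the study conditions: 3 training centers serving
train/validation/internal-test and 1 external center (disjoint domain
labels), 400/60/120 patches per training center per partition and 640
external patches (~2,400 patches of 64×64), positive fraction 0.2 — a
milder imbalance than the real mitosis cohorts (~1:27) chosen for
desk-scale statistical power; the ratio is configurable.

*Class signal* lives exclusively in morphology: negatives carry 9–16
nucleus-like elliptical Gaussian blobs of radius 1.8–3.2 px, positives
5–9 blobs of radius 2.6–4.4 px, with near-matched expected total
hematoxylin mass. The overlapping ranges give a realistically hard task
(internal F1 in the high 0.8s–0.9s rather than 1.0), and matching the mass
keeps mean color nearly class-blind — a linear probe on mean RGB
distinguishes centers (≥0.9 accuracy) but not classes within a center
(≤0.6). Eosin forms a smooth positive stroma texture attenuated inside
blobs by $e^{-2 c_H}$ (nuclei displace cytoplasm), which also leaves each
patch with near-pure pixels of both stains — the geometry Macenko-type
estimation assumes.

*Center identity* lives exclusively in color: per-center stain matrices
(training centers: canonical H&E rotated by random angles up to 4°;
external: exactly 32°), channel gains (training 0.92–1.08; external
1±0.20–0.35 per channel), brightness offsets (training ±10; external
±25–40) and Gaussian pixel noise (sd 3). The external parameters lie
deliberately outside the training range in every component: this is the
regime in which a morphology-capable baseline still loses external ranking
quality (external AUC drops into the ~0.85–0.95 range while internal stays
≥0.99), reproducing the generalization gap the pipeline exists to study.
With milder shifts (≤18°) the baseline was empirically unaffected and the
comparison degenerate.

What the generator does *not* emulate: real nuclear texture and chromatin
structure, spatial correlation between neighbouring patches of one slide,
staining artifacts (folds, bubbles), or scanner-specific sharpening.
Passing tests therefore demonstrate the pipeline's mechanics and its
behaviour under controlled color-vs-morphology factorization — not
clinical performance.

# Evaluation protocol

F1 (precision/recall conventions: 0 on zero denominators) and rank-based
AUC (ties 0.5) are computed per partition. The runner evaluates F1 at the
validation-optimized threshold (`optimalThreshold()`), since the operating
threshold of these models is typically far from 0.5; `f1Score()` itself
defaults to 0.5. Across the default four initializations,
`aggregateResults()` reports mean and sample (n−1) standard deviation.
`compareMethods()` applies the two-sided Wilcoxon signed-rank test to
paired per-record probabilities (correctness indicators available as an
option), dropping zero differences, exact for ≤25 untied pairs and
normal-approximated beyond. `exportEmbeddings()` samples 80 records,
extracts the 128-dimensional task-branch embedding and writes a 2-D
*linear* principal-component projection for plotting; `knnDomainPurity()`
and `domainProbe()` (multinomial logistic probe, held-out accuracy) are
the quantitative counterparts of "domain-mixed" embeddings.

# Numerical choices and degenerate inputs

* Intensity floor 1 before logarithms; absorbances clipped at 0.
* Rank-deficient OD clouds (single-stain images) raise an error rather
  than returning a degenerate matrix; too few tissue pixels (< 50 above
  the OD threshold) raise an error carrying the count.
* Angle percentiles use type-7 quantiles; permutation of pixels cannot
  change the estimate.
* Batch-norm uses $\epsilon = 10^{-5}$ and running-statistics momentum
  0.9; inference always uses running statistics and never reads domain
  labels.
* He initialization; the trunk and task head are seeded identically with
  and without a domain head (the domain head draws from an offset stream),
  so baselines and adversarial models start from the same shared weights.
* All entry points that consume randomness restore the caller's RNG state.

# Problem sizes

The shipped defaults run the full internal/external comparison — 2,380
patches, 2 model families × 4 initializations at 300 iterations of batch
30/32 — in roughly ten minutes on one CPU core, with conv/pool/batch-norm
kernels in C++ (im2col + BLAS). The bootstrap detector for hard-negative
mining uses 300 task-only iterations. These sizes were chosen as the
smallest at which the seed-to-seed variability of the comparison is
acceptable.

# Known limitations

* The compact architecture is fixed in shape (channel widths, one dropout
  site); the deeper pretrained-backbone variant of the original study is
  out of scope.
* Stain normalization assumes exactly two stains; DAB or other
  chromogens are not modeled.
* The Wilcoxon comparison treats per-patch probabilities as paired
  decisions; per-case aggregation is not implemented.
* The 2-D embedding export uses a linear projection; a non-linear
  manifold embedding may separate structure the linear view overlaps.
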