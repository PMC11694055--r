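---
title: "Estimating and visualizing skin-lesion depth from a single image"
author: "LesionDepth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and visualizing skin-lesion depth from a single image}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LesionDepth)
```

## The problem

Melanoma staging depends on how deep a lesion has invaded below the skin
surface, but a dermatoscopic photograph is a single 2D view. LesionDepth
implements a qualitative, non-invasive depth-estimation pipeline for such
images: it localizes the lesion, converts defocus blur into a dense
depth-proxy map, renders the map as a 3D point cloud on a diverging
red-blue scale, quantifies sub-surface involvement by counting "red
spots" in 100-unit depth bands, and summarizes the lesion as a conic
solid whose decreasing widths encode those counts. The output depth is in
uncalibrated *heatmap depth units* on a 0-1000 scale — it is not a
Breslow depth and supports qualitative comparison only.

## Pipeline stages and their assumptions

### Localization (gradient class activation mapping)

A convolutional classifier is attached through a duck-typed
`ModelAdapter` exposing three functions: the malignancy probability, the
feature maps $A^k$ of a named final convolution layer (default
`block5_conv4`), and the gradients $\partial y / \partial A^k$ of the
pre-activation logit with respect to those maps. `gradCAM()` computes
channel weights $\alpha_k$ as the spatial mean of each gradient map, forms
$\sum_k \alpha_k A^k$, rectifies at zero and min-max rescales to $[0,1]$.
Gradients are taken at the logit rather than the sigmoid output (the
standard choice; the sigmoid squashes gradient magnitudes without changing
the argmax). Two degenerate cases need a rule: a raw map that is
identically $\le 0$ stays all-zero, and a *constant positive* raw map
becomes all-ones — the whole frame is equally class-discriminative, and
collapsing it to zero would silently drop the localization.

The reference architecture behind the adapter is a VGG19 base
(`include_top = FALSE`) with a flatten step, five dense ReLU layers and a
one-unit sigmoid head. Training it requires an annotated archive and is
out of scope here; the packaged adapters are a fixed-probability stub
(whose single "feature map" is smoothed image darkness, so the CAM
highlights the dark blob) and a tiny seeded two-convolution network with
a global-average-pooling linear head, for which the gradients have the
closed form $w_k / (HW)$. Classification uses the sigmoid convention with
an *inclusive* 0.5 threshold: a tie is labelled malignant, favoring
sensitivity in a cancer screen.

`superimpose()` blends a jet-style colorization of the CAM over the image
with weight `alpha` (default 0.4; the blend weight is not prescribed
anywhere authoritative, so it is configurable).

### Depth from defocus

The depth proxy assumes a shallow depth of field: structure further from
the focal plane (read here as deeper below the surface) is more
defocused. The chain is:

1. **Edges.** `detectEdges()` is a classical Canny operator on 0-255
   luminance (Rec. 601 weights): unnormalized 3x3 Sobel gradients,
   orientation-quantized non-maximum suppression, hysteresis with
   thresholds (50, 150). No pre-smoothing is applied by default, matching
   the OpenCV operator the thresholds come from. The non-maximum
   tie-break is asymmetric (`>=` toward the preceding neighbor, `>`
   toward the following one) so the two equal-magnitude columns flanking
   a symmetric discrete step resolve to a single-pixel line
   deterministically.
2. **Blur at the edges.** `estimateEdgeBlur()` re-blurs the image with a
   known `sigma0` (default 1 px) and forms the gradient-magnitude ratio
   $R = |\nabla I| / |\nabla I_{\sigma_0}|$ at each edge pixel. For an
   ideal step edge blurred by $\sigma$, $R =
   \sqrt{(\sigma^2 + \sigma_0^2)/\sigma^2}$, so
   $\sigma = \sigma_0 / \sqrt{R^2 - 1}$. Estimates are clamped to
   `[0, maxBlur]` (default 5 px — beyond that the ratio is within noise
   of 1 and the estimate is uninformative). A ratio at or below 1, or a
   vanishing re-blurred gradient, is assigned the clamp value and
   *flagged* as censored. Discretization puts a floor of roughly one
   pixel on the estimate for perfectly sharp edges (the central
   difference of a hard step is finite), which is why sharp synthetic
   lesions read near $\sigma \approx 1$ rather than 0.
3. **Propagation.** `propagateDefocus()` spreads the sparse estimates
   inward: every pixel takes the inverse-distance-weighted (power 1) mean
   of its `m = 5` nearest edge pixels, computed exactly by a small C++
   routine; edge pixels keep their own values, and ties are broken by
   scan order so runs are deterministic. Flagged estimates are excluded
   from the source set by default — a censored value carries no blur
   information, and a single one would otherwise anchor a spurious
   maximal-depth spot. The output range is bounded by the sparse range
   (convexity), and an empty edge set degenerates to the all-zero field
   with a warning: "no defocus evidence" must read as shallow, never as
   deep.
4. **Normalization.** Two conventions are provided. `normalizeMinMax()`
   stretches the field to $[0,1]$ per image (constant fields map to
   all-zero) and backs the *displayed* defocus map. `normalizeAbsolute()`
   divides by `maxBlur`, keeping images on one common scale; it feeds the
   3D volume by default, because banded counts are compared *across*
   cases and a per-image stretch would force every image — however sharp
   — to attain the maximal depth somewhere, collapsing the comparison.

Edges are detected on the **original** image by default
(`edgeSource = "original"`). The alternative, running on the blended
localization output, is available but not the default: the blended
heatmap introduces its own smooth color ramps around the CAM contours,
which the gradient-ratio estimator reads as heavy defocus even on a
perfectly sharp image.

### Gabor depth volume

`depthVolume()` convolves the normalized map with the four-filter Gabor
bank (orientations $0, \pi/4, \pi/2, 3\pi/4$; frequency 0.1 for the
axis-aligned filters and 0.4 for the angled ones; envelope spread 0.01;
aspect ratio 0.5; 5x5 kernels). Kernels follow the OpenCV
parameterization: Gaussian envelope in rotated coordinates with the
minor axis scaled by `gamma`, times a cosine carrier at phase 0. With a
spread of 0.01 px the envelope underflows off-center and each kernel is
numerically a unit impulse — the bank passes the map through unchanged,
giving a sharply pixelated volume; larger spreads turn the stage into a
genuine oriented texture analysis.

Per pixel, the response magnitudes are combined (maximum by default,
mean behind a flag) into $U$ and coupled with the defocus value $d$ as
the geometric mean $\sqrt{U d}$, clamped to $[0,1]$; the depth is
$z = 1000 \sqrt{U d}$. The geometric mean was chosen over the plain
product because it is order-preserving, symmetric in the two factors,
and makes the construction collapse *exactly* to
$z = d \cdot \mathrm{depthScale}$ when the bank is a unit impulse — a
closed-form limit the unit tests pin down. One point is emitted per
pixel; each point is classed on the diverging scale (red above
$1.02 \times$ the midpoint 500, blue below $0.98 \times$, neutral in the
2% band — the neutral band width is a display convention, not a claim
about tissue).

### Red spot analysis

`redSpotProfile()` counts, for each threshold $t \in \{0, 100, \ldots,
1000\}$, the points strictly deeper than $t$ ("Below $t$"). Strict
inequality makes "Below 0" count exactly the sub-surface spots: a point
at the surface belongs to no band. Counts are non-increasing in $t$ by
construction. All points are counted regardless of color class by
default; whether the original analysis counted literally-red points or
all sub-threshold points is not decidable from its description, and the
reference table's near-total "Below 0" counts are consistent with the
all-points reading (a `mode = "red"` switch implements the other).
Anomaly bands — e.g. the documented preset $135 < y < 145$ for a dark
artifact line — are removed before counting, with strict inequalities on
both limits.

Two scalar readings summarize a profile: `depthBound()` is the smallest
zero-count threshold (the depth the lesion has *not* surpassed;
profiles with no zero return the sentinel 1100 with a `beyondRange`
flag), and `deepestExtent()` is the largest positive-count threshold.
Whenever both are in range the bound follows the extent by exactly one
band.

### Conic surface

`buildConic()` maps each positive-count band to a circular slice whose
radius is `rMax * count / counts[1]` (linear mode: width proportional to
the count, as the construction is described) or `rMax * sqrt(...)`
(sqrt mode: *area* proportional to the count, a defensible alternative).
A zero-radius apex closes the solid at the depth bound.
`meshFromConic()` revolves the slices into a triangle mesh with depth
running down the negative vertical axis; a `zRescale` of 0.002
reproduces the $[0, -2]$ display range. The mesh is watertight: side
walls between consecutive rings, an apex fan, and a top cap across the
first ring (the cap adds `nSides - 2` triangles beyond the bare lathe;
without it the solid would be open and unusable for mixed-reality
viewers that expect closed geometry). OBJ and PLY writers are ASCII; the
exported mesh is the hand-off boundary to any external viewer.

## The synthetic-fixture generator

No archive images ship with the package; `generateLesionImage()` emulates
the relevant structure of a dermoscopy image: a dark elliptical blob
(default semi-axes 55 x 40 px on a 224 x 224 frame) with a radially
perturbed border (four seeded sinusoidal harmonics; the border model is
the package's own choice, as no authoritative one exists), a controllable
Gaussian blur gradient at the boundary (`edgeBlurSigma`), and a smooth
low-amplitude texture field (amplitude 0.01) over the skin. The default
palette — skin (0.95, 0.80, 0.75), lesion (0.08, 0.05, 0.05) — was fixed
by a detectability analysis done once at design time: the Sobel magnitude
of a boundary of amplitude $A$ blurred by $\sigma_b$ is approximately
$8A/(\sigma_b\sqrt{2\pi})$ (255 scale), and the "malignant-like" default
$\sigma_b = 2$ must stay above the Canny seed threshold of 150, which
requires the high-contrast palette. The palette also inherits the
light-skin-tone bias of the public archives it emulates; this is a
documented limitation, not a recommendation.

`cloudFromProfile()` inverse-designs a point cloud from any monotone
profile by placing `counts[i] - counts[i+1]` depths uniformly in the
half-open band $(t_i, t_{i+1}]$, so the recomputed profile equals the
input *exactly* — this is what lets the banded-counting machinery be
tested against the four printed reference columns without the
(unidentified) source images.

What the generator does **not** emulate: hair, rulers and other
acquisition artifacts; photometric camera effects; irregular multi-focal
pigmentation; darker skin tones. Passing tests therefore demonstrate the
pipeline's internal consistency and its qualitative blur-to-depth
ordering on controlled geometry, not clinical performance on real
dermoscopy.

## Numerical choices

* Convolutions use even-symmetric (repeat-edge) reflection, which makes
  the convolution operator symmetric with unit row sums, so a normalized
  kernel conserves total mass exactly (the mirror-without-repeat variant
  does not).
* Bilinear upsampling of activation maps is align-corners, so constants
  and endpoint values are preserved exactly; downscaling is rejected.
* Min-max normalization maps constant inputs to all-zero; the all-zero
  activation map and the empty edge set degenerate analogously
  (everything reads shallow, nothing reads deep).
* All randomness (fixture noise, border phases, inverse-design band
  placement) flows from explicit integer seeds through a
  save-and-restore RNG wrapper, so library calls never perturb a user's
  RNG state and identical seeds give byte-identical artifacts.

## Problem sizes used by the test suite

Unit tests run on small grids (tiny hand-checkable matrices up to 96 x 96
steps); the paired benign/malignant ordering checks run the full
pipeline on 224 x 224 images across ten seeds, and the property suites
use 100 random monotone profiles and 100 random clouds of a few hundred
points against brute-force counters. The whole suite completes in well
under a minute on one CPU.

## Worked example

```{r example, eval = FALSE}
img <- generateLesionImage(lesionSpec(seed = 3, edgeBlurSigma = 2))
res <- runPipeline(img, stubAdapter(0.98),
                   pipelineConfig(seed = 3, outputDir = tempfile()))
res
profileCounts(res@profile)
```

## Known limitations

* Depth units are uncalibrated; no clinical staging claim is made or
  should be inferred.
* The defocus proxy requires visible lesion-to-skin contrast; a lesion
  whose color approaches the surrounding skin produces few or no edges
  and hence a near-zero depth map.
* The blur estimator's one-pixel discretization floor compresses
  differences between very sharp lesions.
* The blended-image edge source, though offered for fidelity to the
  original description, contaminates the defocus signal with heatmap
  contours (see above) and is not recommended.
* Model metrics (accuracy, Matthews correlation, areas under the ROC and
  precision-recall curves) require a trained classifier on archive data;
  only the formula-level metric operations are provided, including the
  precision/recall to F1 harmonic-mean consistency check.
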