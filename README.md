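# LesionDepth

Qualitative, non-invasive depth estimation and 3D reconstruction of skin
lesions from a single dermatoscopic-style RGB image, for researchers in
biomedical image analysis who want a reproducible, fully testable
implementation of the defocus-based lesion-depth pipeline — without
archive downloads, trained weights, or a mixed-reality headset.

## What it computes

Given one 224 x 224 RGB image, the pipeline runs:

1. **Localization** — a gradient class activation map from a pluggable
   convolutional model: channel weights are the spatially averaged
   gradients of the malignancy logit, the CAM is
   `relu(sum_k alpha_k A^k)` min-max rescaled to [0, 1], blended over the
   image as a jet heatmap.
2. **Depth from defocus** — Canny edges (thresholds 50/150), per-edge blur
   from the gradient ratio `sigma = sigma0 / sqrt(R^2 - 1)` with
   `R = |grad I| / |grad I_sigma0|`, inverse-distance propagation into the
   full frame, and normalization to a dense depth-proxy map.
3. **3D depth volume** — a four-filter Gabor bank (orientations
   0, pi/4, pi/2, 3pi/4; frequencies 0.1/0.4; sigma 0.01; gamma 0.5; 5x5)
   converts the map into a point cloud with `z` in 0-1000 heatmap depth
   units, colored red/blue/neutral on a diverging scale.
4. **Red spot analysis** — counts of points strictly deeper than each
   threshold 0, 100, ..., 1000 ("Below t" bands), with optional anomaly-band
   exclusion; two scalar readings summarize a profile: the *depth bound*
   (smallest zero-count threshold) and the *deepest extent* (largest
   positive-count threshold).
5. **Conic surface with decreasing widths** — one circular slice per
   positive band, radius proportional to the count, closed by an apex at
   the depth bound and exported as a watertight OBJ/PLY mesh for external
   3D or mixed-reality viewers.

A synthetic-fixture module generates lesion images (controllable boundary
blur, irregular borders, seeded determinism) and inverse-designs point
clouds whose banded counts match any monotone profile exactly, so every
stage is testable against the four published reference columns.

## Worked example

```r
library(LesionDepth)

img <- generateLesionImage(lesionSpec(seed = 3, edgeBlurSigma = 2))
res <- runPipeline(img, stubAdapter(0.98),
                   pipelineConfig(seed = 3, outputDir = tempfile()))
res
#> PipelineResult:
#>   malignancy probability 0.980 -> Malignant
#>   depth bound 500, deepest extent 400 (heatmap depth units)
#>   artifacts: blended.png, defocus.png, defocus.csv, cloud.ply, cloud.csv,
#>              profile.csv, summary.json, run.log, conic.obj, conic.ply
```

The blurred "malignant-like" fixture reads a deepest extent of 400 depth
units: its boundary blur (sigma 2 px) converts to a defocus depth of
about 0.4 on the absolute scale, so the lesion's points populate the
bands down to "Below 400" and vanish from "Below 500" onward — the conic
mesh ends in an apex at depth 500. A sharp "benign-like" rendering of the
same geometry (`edgeBlurSigma = 0`) stays an order of magnitude shallower.

The four published reference profiles are available directly and carry
the reported readings:

```r
p <- table1Profiles()[["malignant_99pct"]]
deepestExtent(p)            # 900  (the fourth case extends to "Below 900")
depthBound(table1Profiles()[["benign_10pct"]])   # 700 (no spots above 700)
round(f1Score(0.84, 0.86), 2)                    # 0.85
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/lesiondepth.R fixtures out/ --seed 3
Rscript inst/scripts/lesiondepth.R run out/malignant_blurred.png --stub-prob 0.98 --seed 3
Rscript inst/scripts/lesiondepth.R conic out/malignant_99pct.csv mesh.obj
```

## Scope

Depth units are uncalibrated heatmap units, not millimeters; no clinical
staging claim is made. Training the reference VGG19 classifier, archive
processing at scale, and mixed-reality packaging are out of scope — the
exported mesh is the hand-off boundary. See the methods vignette
(`vignettes/lesion-depth-methods.Rmd`) for the model, assumptions,
parameter defaults and limitations.
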