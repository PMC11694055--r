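#' @import methods
NULL

#' Synthetic lesion image specification
#'
#' Describes a synthetic dermatoscopic-style test image: a darker,
#' irregularly bordered elliptical blob (the lesion) on a lighter skin-tone
#' background, with a controllable blur gradient at the blob boundary.
#' Defaults emulate a high-contrast lesion on a light skin tone; archive
#' dermoscopy collections are known to be skewed toward lighter skin tones
#' and the default palette inherits that bias (a documented limitation, not
#' an endorsement).
#'
#' @slot seed integer; drives border phases and texture noise.
#' @slot imageSize side length in pixels (square image).
#' @slot lesionCenter numeric (row, col) of the ellipse center.
#' @slot lesionAxes numeric (a, b) semi-axes in pixels.
#' @slot borderIrregularity non-negative amplitude of the radial sinusoidal
#'   border perturbation (0 gives an exact ellipse).
#' @slot lesionColor,skinColor RGB triples in \[0, 1\]; the lesion must be
#'   strictly darker (lower mean channel value) than the skin.
#' @slot edgeBlurSigma Gaussian sigma (pixels) of the lesion-boundary blur
#'   gradient; 0 gives a hard boundary.
#' @slot textureAmplitude amplitude (in \[0, 1\] intensity units) of the
#'   smooth skin-texture noise field.
#' @export
setClass("SyntheticLesionSpec",
  representation(seed = "integer", imageSize = "integer",
    lesionCenter = "numeric", lesionAxes = "numeric",
    borderIrregularity = "numeric", lesionColor = "numeric",
    skinColor = "numeric", edgeBlurSigma = "numeric",
    textureAmplitude = "numeric"),
  prototype(seed = 1L, imageSize = 224L, lesionCenter = c(112, 112),
    lesionAxes = c(55, 40), borderIrregularity = 0.15,
    lesionColor = c(0.08, 0.05, 0.05), skinColor = c(0.95, 0.80, 0.75),
    edgeBlurSigma = 0, textureAmplitude = 0.01))

setValidity("SyntheticLesionSpec", function(object) {
  msg <- character()
  if (length(object@lesionCenter) != 2L || length(object@lesionAxes) != 2L)
    msg <- c(msg, "lesionCenter and lesionAxes must have length 2")
  if (any(object@lesionAxes <= 0)) msg <- c(msg, "lesionAxes must be positive")
  if (object@borderIrregularity < 0) msg <- c(msg, "borderIrregularity must be >= 0")
  if (object@edgeBlurSigma < 0) msg <- c(msg, "edgeBlurSigma must be >= 0")
  if (length(object@lesionColor) != 3L || length(object@skinColor) != 3L ||
      any(object@lesionColor < 0 | object@lesionColor > 1) ||
      any(object@skinColor < 0 | object@skinColor > 1))
    msg <- c(msg, "colors must be RGB triples in [0, 1]")
  else if (mean(object@lesionColor) >= mean(object@skinColor))
    msg <- c(msg, "lesionColor must be strictly darker (lower mean) than skinColor")
  # the worst-case perturbed ellipse must stay inside the frame
  reach <- max(object@lesionAxes) * (1 + object@borderIrregularity)
  ctr <- object@lesionCenter
  if (ctr[1] - reach < 1 || ctr[1] + reach > object@imageSize ||
      ctr[2] - reach < 1 || ctr[2] + reach > object@imageSize)
    msg <- c(msg, "lesion ellipse (including border perturbation) must fit within the image")
  if (length(msg)) msg else TRUE
})

#' A single-lesion RGB input image
#'
#' The pipeline's input: an H x W x 3 raster in \[0, 1\]. Synthetic images
#' carry the ground-truth lesion mask in \code{lesionMask}; images read from
#' disk have an empty mask.
#'
#' @slot raster H x W x 3 numeric array in \[0, 1\].
#' @slot lesionMask logical H x W ground-truth mask (may be 0 x 0).
#' @slot source free-text provenance ("synthetic" or a file path).
#' @export
setClass("LesionImage",
  representation(raster = "array", lesionMask = "matrix", source = "character"),
  prototype(lesionMask = matrix(logical(0), 0, 0), source = NA_character_))

setValidity("LesionImage", function(object) {
  d <- dim(object@raster)
  if (length(d) != 3L || d[3] != 3L) return("raster must be H x W x 3")
  if (any(object@raster < 0 | object@raster > 1)) return("raster values must lie in [0, 1]")
  if (length(object@lesionMask) && !identical(dim(object@lesionMask), d[1:2]))
    return("lesionMask must match the raster's spatial size")
  TRUE
})

#' Class activation map
#'
#' Normalized \[0, 1\] 2D heatmap locating the class-discriminative region
#' (the lesion), produced by \code{\link{gradCAM}} from a convolution
#' layer's feature maps and output gradients.
#'
#' @slot grid H x W numeric matrix in \[0, 1\].
#' @slot sourceLayer name of the tapped convolution layer.
#' @export
setClass("ActivationMap",
  representation(grid = "matrix", sourceLayer = "character"),
  prototype(sourceLayer = "block5_conv4"))

setValidity("ActivationMap", function(object) {
  g <- object@grid
  if (any(!is.finite(g))) return("grid must be finite")
  if (any(g < 0 | g > 1)) return("grid values must lie in [0, 1]")
  TRUE
})

#' Sparse per-edge defocus blur map
#'
#' Blur sigma estimates defined only at edge pixels (NA elsewhere), the raw
#' output of the gradient-ratio defocus estimator.
#'
#' @slot values H x W matrix; blur sigma at edge pixels, NA off edges.
#' @slot maxBlur clamp value (blur sigma upper bound, pixels).
#' @slot flagged logical H x W; TRUE where the estimator degenerated
#'   (vanishing or non-informative re-blurred gradient) and the clamp value
#'   was assigned.
#' @export
setClass("SparseBlurMap",
  representation(values = "matrix", maxBlur = "numeric", flagged = "matrix"))

setValidity("SparseBlurMap", function(object) {
  v <- object@values[!is.na(object@values)]
  if (length(v) && (min(v) < 0 || max(v) > object@maxBlur + 1e-9))
    return("defined blur values must lie in [0, maxBlur]")
  if (!identical(dim(object@flagged), dim(object@values)))
    return("flagged must match values in shape")
  TRUE
})

#' Dense normalized defocus depth-proxy map
#'
#' Values in \[0, 1\]; larger means more defocus blur, read as deeper below
#' the skin surface. Two normalizations exist: \code{"minmax"} (per-image
#' min-max stretch, the displayed artifact; min 0 and max 1 unless the map
#' is constant, in which case all 0) and \code{"absolute"} (blur sigma over
#' \code{maxBlur}, preserving cross-image comparability; used for the 3D
#' volume).
#'
#' @slot grid H x W numeric matrix in \[0, 1\].
#' @slot normalization "minmax" or "absolute".
#' @export
setClass("DefocusMap",
  representation(grid = "matrix", normalization = "character"),
  prototype(normalization = "minmax"))

setValidity("DefocusMap", function(object) {
  g <- object@grid
  if (any(!is.finite(g))) return("grid must be finite")
  if (any(g < 0 | g > 1)) return("grid values must lie in [0, 1]")
  if (!object@normalization %in% c("minmax", "absolute"))
    return("normalization must be 'minmax' or 'absolute'")
  if (object@normalization == "minmax" && max(g) > 0 &&
      (abs(max(g) - 1) > 1e-8 || min(g) > 1e-8))
    return("a non-constant minmax map must have min 0 and max 1")
  TRUE
})

#' Depth point cloud on a diverging red-blue scale
#'
#' One point per source pixel: (x = column, y = row, z = depth units, with
#' 0 the skin surface and larger deeper). Each point carries a color class
#' from the diverging scale: red (deep side), blue (shallow side) or
#' neutral (within 2\% of the midpoint).
#'
#' @slot coords n x 3 numeric matrix with columns x, y, z.
#' @slot colorClass factor with levels red, blue, neutral.
#' @slot depthScale maximum depth in heatmap depth units (default 1000).
#' @export
setClass("DepthPointCloud",
  representation(coords = "matrix", colorClass = "factor", depthScale = "numeric"),
  prototype(depthScale = 1000))

setValidity("DepthPointCloud", function(object) {
  if (ncol(object@coords) != 3L) return("coords must be n x 3 (x, y, z)")
  if (nrow(object@coords) != length(object@colorClass))
    return("colorClass length must equal the point count")
  z <- object@coords[, 3]
  if (length(z) && (min(z) < -1e-9 || max(z) > object@depthScale + 1e-9))
    return("z must lie in [0, depthScale]")
  if (!identical(levels(object@colorClass), c("red", "blue", "neutral")))
    return("colorClass levels must be red, blue, neutral")
  TRUE
})

#' Banded red-spot profile
#'
#' Counts of points deeper than each threshold 0, 100, ..., 1000 depth
#' units ("Below t" rows): \code{counts[i]} is the number of points with
#' z strictly greater than \code{thresholds[i]}, after any anomaly-band
#' exclusions. Non-increasing in the threshold by construction.
#'
#' @slot thresholds strictly increasing depth thresholds.
#' @slot counts non-negative integer counts, one per threshold.
#' @slot excludedBands list of \linkS4class{AnomalyBand} applied.
#' @slot label free-text case label.
#' @export
setClass("RedSpotProfile",
  representation(thresholds = "numeric", counts = "integer",
    excludedBands = "list", label = "character"),
  prototype(thresholds = seq(0, 1000, by = 100), excludedBands = list(),
    label = NA_character_))

setValidity("RedSpotProfile", function(object) {
  if (length(object@counts) != length(object@thresholds))
    return("counts and thresholds must have equal length")
  if (is.unsorted(object@thresholds, strictly = TRUE))
    return("thresholds must be strictly increasing")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (any(diff(object@counts) > 0))
    return("counts must be non-increasing with threshold")
  TRUE
})

#' Anomaly exclusion band
#'
#' An open coordinate band (lo < coordinate < hi on one axis) whose points
#' are discarded before profiling; used to drop artifact lines such as a
#' dark image border (the documented preset is y in (135, 145)).
#'
#' @slot axis "x" or "y".
#' @slot lo,hi band limits in pixel coordinates, lo < hi (strict, open band).
#' @export
setClass("AnomalyBand",
  representation(axis = "character", lo = "numeric", hi = "numeric"))

setValidity("AnomalyBand", function(object) {
  if (!object@axis %in% c("x", "y")) return("axis must be 'x' or 'y'")
  if (!(object@lo < object@hi)) return("lo must be < hi")
  TRUE
})

#' Gabor filter parameters
#'
#' Spatial-domain Gabor mask: Gaussian envelope (spread \code{sigma}, minor
#' axis scaled by \code{gamma}) times a cosine carrier of the given
#' frequency along orientation \code{theta}.
#'
#' @slot theta orientation in radians.
#' @slot frequency carrier frequency, cycles per pixel (> 0).
#' @slot sigma Gaussian envelope spread (pixels).
#' @slot gamma spatial aspect ratio in (0, 1]; multiplies the minor-axis
#'   coordinate.
#' @slot size kernel side length in pixels.
#' @export
setClass("GaborParams",
  representation(theta = "numeric", frequency = "numeric", sigma = "numeric",
    gamma = "numeric", size = "integer"),
  prototype(theta = 0, frequency = 0.1, sigma = 0.01, gamma = 0.5, size = 5L))

setValidity("GaborParams", function(object) {
  if (object@frequency <= 0) return("frequency must be > 0")
  if (object@sigma <= 0) return("sigma must be > 0")
  if (object@gamma <= 0 || object@gamma > 1) return("gamma must be in (0, 1]")
  if (object@size < 1L) return("size must be >= 1")
  TRUE
})

#' Conic lesion surface with decreasing widths
#'
#' Stack of circular slices, one per depth band with a positive red-spot
#' count, whose radii encode the band counts, closed by a zero-radius apex
#' at the profile's depth bound. The lathe of the slices is the exported
#' "conic surface with decreasing widths".
#'
#' @slot slices data.frame with columns \code{depth} (strictly increasing)
#'   and \code{radius} (non-negative; the final row is the apex, radius 0).
#' @slot radiusMode "linear" (radius proportional to count) or "sqrt"
#'   (cross-sectional area proportional to count).
#' @slot rMax model-unit radius of the top slice.
#' @export
setClass("ConicSurface",
  representation(slices = "data.frame", radiusMode = "character", rMax = "numeric"),
  prototype(radiusMode = "linear", rMax = 1))

setValidity("ConicSurface", function(object) {
  s <- object@slices
  if (!all(c("depth", "radius") %in% names(s)))
    return("slices must have columns depth and radius")
  if (nrow(s) && is.unsorted(s$depth, strictly = TRUE))
    return("slice depths must be strictly increasing")
  if (nrow(s) && any(s$radius < 0)) return("radii must be non-negative")
  if (!object@radiusMode %in% c("linear", "sqrt"))
    return("radiusMode must be 'linear' or 'sqrt'")
  TRUE
})

#' Pluggable convolutional-model adapter
#'
#' Duck-typed contract between the pipeline and whatever classifier backs
#' it: a reference VGG19-with-dense-head architecture, a tiny stand-in
#' network, or a fixed stub. The adapter exposes the malignancy
#' probability, the feature maps of a named final convolution layer, and
#' the output gradients with respect to those maps.
#'
#' @slot predictFun function(LesionImage) -> probability in \[0, 1\].
#' @slot featureFun function(LesionImage) -> H x W x K array of feature maps.
#' @slot gradFun function(LesionImage, target) -> H x W x K array of
#'   gradients of the target score w.r.t. each feature map.
#' @slot camLayer name of the tapped layer (default "block5_conv4").
#' @slot description free text.
#' @export
setClass("ModelAdapter",
  representation(predictFun = "function", featureFun = "function",
    gradFun = "function", camLayer = "character", description = "character"),
  prototype(camLayer = "block5_conv4", description = "adapter"))

#' Pipeline configuration
#'
#' Bundles every stage-level tunable of \code{\link{runPipeline}}.
#'
#' @slot camLayer tapped convolution layer name.
#' @slot blendAlpha heatmap blend weight in \[0, 1\].
#' @slot cannyLow,cannyHigh Canny hysteresis thresholds (0-255 gradient scale).
#' @slot sigma0 re-blur sigma of the defocus estimator (pixels).
#' @slot maxBlur blur clamp (pixels).
#' @slot depthScale maximum depth in heatmap units.
#' @slot thresholds red-spot profile thresholds.
#' @slot exclusions list of \linkS4class{AnomalyBand}.
#' @slot radiusMode conic radius mode, "linear" or "sqrt".
#' @slot depthNormalization defocus normalization feeding the 3D volume:
#'   "absolute" (default) or "minmax".
#' @slot edgeSource image the edges are detected on: "blended" or "original".
#' @slot seed integer seed for all stage-level randomness.
#' @slot outputDir directory receiving the artifacts.
#' @export
setClass("PipelineConfig",
  representation(camLayer = "character", blendAlpha = "numeric",
    cannyLow = "numeric", cannyHigh = "numeric", sigma0 = "numeric",
    maxBlur = "numeric", depthScale = "numeric", thresholds = "numeric",
    exclusions = "list", radiusMode = "character",
    depthNormalization = "character", edgeSource = "character",
    seed = "integer", outputDir = "character"),
  prototype(camLayer = "block5_conv4", blendAlpha = 0.4, cannyLow = 50,
    cannyHigh = 150, sigma0 = 1, maxBlur = 5, depthScale = 1000,
    thresholds = seq(0, 1000, by = 100), exclusions = list(),
    radiusMode = "linear", depthNormalization = "absolute",
    edgeSource = "original", seed = 1L, outputDir = NA_character_))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@blendAlpha < 0 || object@blendAlpha > 1)
    msg <- c(msg, "blendAlpha must be in [0, 1]")
  if (object@cannyLow < 0 || object@cannyHigh < object@cannyLow)
    msg <- c(msg, "need cannyHigh >= cannyLow >= 0")
  if (object@sigma0 <= 0) msg <- c(msg, "sigma0 must be > 0")
  if (object@maxBlur <= 0) msg <- c(msg, "maxBlur must be > 0")
  if (is.unsorted(object@thresholds, strictly = TRUE))
    msg <- c(msg, "thresholds must be strictly increasing")
  if (!object@radiusMode %in% c("linear", "sqrt"))
    msg <- c(msg, "radiusMode must be 'linear' or 'sqrt'")
  if (!object@depthNormalization %in% c("absolute", "minmax"))
    msg <- c(msg, "depthNormalization must be 'absolute' or 'minmax'")
  if (!object@edgeSource %in% c("blended", "original"))
    msg <- c(msg, "edgeSource must be 'blended' or 'original'")
  if (length(msg)) msg else TRUE
})

#' Pipeline run result
#'
#' File paths of the five pipeline artifacts plus the machine-readable
#' summary, together with the headline numbers.
#'
#' @slot probability malignancy probability.
#' @slot label "Malignant" or "Benign".
#' @slot depthBound smallest zero-count threshold of the profile.
#' @slot deepestExtent largest positive-count threshold of the profile.
#' @slot profile the \linkS4class{RedSpotProfile}.
#' @slot files named character vector of artifact paths.
#' @export
setClass("PipelineResult",
  representation(probability = "numeric", label = "character",
    depthBound = "numeric", deepestExtent = "numeric",
    profile = "RedSpotProfile", files = "character"))
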