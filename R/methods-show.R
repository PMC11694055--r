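# Accessors and show methods for the central classes.

#' Accessors for pipeline objects
#'
#' \code{grid} returns the numeric matrix backing an
#' \linkS4class{ActivationMap} or \linkS4class{DefocusMap};
#' \code{raster}/\code{lesionMask} the image array and ground-truth mask of
#' a \linkS4class{LesionImage}; \code{cloudPoints}/\code{colorClass}/
#' \code{depthScale} the coordinates, diverging-scale classes and depth
#' scale of a \linkS4class{DepthPointCloud};
#' \code{profileCounts}/\code{profileThresholds} the banded counts of a
#' \linkS4class{RedSpotProfile}; \code{conicSlices} the depth/radius table
#' of a \linkS4class{ConicSurface}.
#'
#' @param object the object to access.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases grid raster lesionMask cloudPoints colorClass depthScale
#'   profileCounts profileThresholds conicSlices
NULL

#' @rdname accessors
#' @export
setMethod("grid", "ActivationMap", function(object) object@grid)
#' @rdname accessors
#' @export
setMethod("grid", "DefocusMap", function(object) object@grid)
#' @rdname accessors
#' @export
setMethod("raster", "LesionImage", function(object) object@raster)
#' @rdname accessors
#' @export
setMethod("lesionMask", "LesionImage", function(object) object@lesionMask)
#' @rdname accessors
#' @export
setMethod("cloudPoints", "DepthPointCloud", function(object) object@coords)
#' @rdname accessors
#' @export
setMethod("colorClass", "DepthPointCloud", function(object) object@colorClass)
#' @rdname accessors
#' @export
setMethod("depthScale", "DepthPointCloud", function(object) object@depthScale)
#' @rdname accessors
#' @export
setMethod("profileCounts", "RedSpotProfile", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("profileThresholds", "RedSpotProfile", function(object) object@thresholds)
#' @rdname accessors
#' @export
setMethod("conicSlices", "ConicSurface", function(object) object@slices)

setMethod("show", "LesionImage", function(object) {
  d <- dim(object@raster)
  cat("LesionImage:", d[1], "x", d[2], "RGB,",
      if (length(object@lesionMask)) "with" else "no", "ground-truth mask\n")
  cat("  source:", object@source, "\n")
})

setMethod("show", "ActivationMap", function(object) {
  cat("ActivationMap:", nrow(object@grid), "x", ncol(object@grid),
      "from layer", object@sourceLayer, "\n")
  cat(sprintf("  range [%.3f, %.3f], mean %.3f\n",
      min(object@grid), max(object@grid), mean(object@grid)))
})

setMethod("show", "DefocusMap", function(object) {
  cat("DefocusMap:", nrow(object@grid), "x", ncol(object@grid),
      paste0("(", object@normalization, " normalization)"), "\n")
  cat(sprintf("  range [%.3f, %.3f], mean %.3f\n",
      min(object@grid), max(object@grid), mean(object@grid)))
})

setMethod("show", "SparseBlurMap", function(object) {
  nd <- sum(!is.na(object@values))
  cat("SparseBlurMap:", nd, "edge pixels, maxBlur", object@maxBlur, "\n")
  if (nd) cat(sprintf("  sigma range [%.3f, %.3f], %d flagged\n",
      min(object@values, na.rm = TRUE), max(object@values, na.rm = TRUE),
      sum(object@flagged)))
})

setMethod("show", "DepthPointCloud", function(object) {
  n <- nrow(object@coords)
  cat("DepthPointCloud:", n, "points, depth scale", object@depthScale, "\n")
  if (n) {
    tb <- table(object@colorClass)
    cat(sprintf("  z range [%.1f, %.1f]; red %d, blue %d, neutral %d\n",
        min(object@coords[, 3]), max(object@coords[, 3]),
        tb[["red"]], tb[["blue"]], tb[["neutral"]]))
  }
})

setMethod("show", "RedSpotProfile", function(object) {
  cat("RedSpotProfile",
      if (!is.na(object@label)) paste0("('", object@label, "')"), "\n")
  print(stats::setNames(object@counts, paste0("Below ", object@thresholds)))
  if (length(object@excludedBands))
    cat("  ", length(object@excludedBands), "anomaly band(s) excluded\n")
})

setMethod("show", "ConicSurface", function(object) {
  cat("ConicSurface:", nrow(object@slices), "slices (incl. apex),",
      object@radiusMode, "radius mode\n")
  if (nrow(object@slices))
    cat(sprintf("  apex depth %.0f, top radius %.3f\n",
        max(object@slices$depth), object@slices$radius[1]))
})

setMethod("show", "ModelAdapter", function(object) {
  cat("ModelAdapter:", object@description, "(CAM layer", object@camLayer, ")\n")
})

setMethod("show", "PipelineResult", function(object) {
  cat("PipelineResult:\n")
  cat(sprintf("  malignancy probability %.3f -> %s\n",
      object@probability, object@label))
  cat(sprintf("  depth bound %.0f, deepest extent %.0f (heatmap depth units)\n",
      object@depthBound, object@deepestExtent))
  cat("  artifacts:", paste(basename(object@files), collapse = ", "), "\n")
})
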