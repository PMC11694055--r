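# Red spot analysis: diverging-scale color classes, anomaly-band
# exclusion, banded counts below depth thresholds, and the two depth
# readings (depth bound, deepest extent).

#' Classify a depth value on the diverging red-blue scale
#'
#' For midpoint m and tolerance eps = 0.02: z > m (1 + eps) is red (the
#' deep, far side), z < m (1 - eps) is blue (shallow, near side), anything
#' within the band is neutral. Vectorized over z; negative depths are
#' rejected.
#'
#' @param z depth value(s) in heatmap units (>= 0).
#' @param midpoint diverging-scale midpoint (depth units).
#' @param eps relative neutral half-band (default 0.02).
#' @return character vector in \{"red", "blue", "neutral"\}.
#' @examples
#' classifySpotColor(c(0, 500, 1000), midpoint = 500)
#' @export
classifySpotColor <- function(z, midpoint, eps = 0.02) {
  if (any(z < 0)) stop("depth values must be non-negative")
  ifelse(z > midpoint * (1 + eps), "red",
         ifelse(z < midpoint * (1 - eps), "blue", "neutral"))
}

#' Construct an anomaly exclusion band
#'
#' @param axis "x" or "y".
#' @param lo,hi open-band limits (points with lo < coordinate < hi are
#'   dropped; the limits themselves survive).
#' @return an \linkS4class{AnomalyBand}.
#' @export
anomalyBand <- function(axis, lo, hi) new("AnomalyBand", axis = axis, lo = lo, hi = hi)

#' The documented artifact-line exclusion preset
#'
#' The horizontal artifact band y in (135, 145) observed as a spurious
#' line of red spots in one reference malignant case (a dark image
#' outline, not lesion tissue).
#'
#' @return an \linkS4class{AnomalyBand}.
#' @export
figure3dBand <- function() anomalyBand("y", 135, 145)

#' Remove an anomaly band from a depth point cloud
#'
#' Drops every point with \code{lo < coordinate < hi} on the band's axis
#' (strict inequalities: points exactly on the limits are kept). Applying
#' the same band twice is idempotent; an empty result is permitted.
#'
#' @param object a \linkS4class{DepthPointCloud}.
#' @param band an \linkS4class{AnomalyBand}.
#' @return the filtered \linkS4class{DepthPointCloud}.
#' @rdname excludeBand
#' @export
setMethod("excludeBand", signature("DepthPointCloud", "AnomalyBand"),
  function(object, band) {
    validObject(band)
    coord <- object@coords[, if (band@axis == "x") 1L else 2L]
    keep <- !(coord > band@lo & coord < band@hi)
    new("DepthPointCloud", coords = object@coords[keep, , drop = FALSE],
        colorClass = object@colorClass[keep], depthScale = object@depthScale)
  })

#' Banded red-spot profile of a depth point cloud
#'
#' After removing any anomaly bands, counts for every threshold t the
#' points lying strictly deeper than t ("Below t"): a spot exactly at the
#' surface (z = 0) is counted by no threshold, so "Below 0" counts exactly
#' the sub-surface spots. Counts are non-increasing in the threshold by
#' construction. All points are counted regardless of color class by
#' default (\code{mode = "all"}); \code{mode = "red"} restricts to points
#' classed red on the diverging scale.
#'
#' @param object a \linkS4class{DepthPointCloud}.
#' @param thresholds strictly increasing depth thresholds (default 0, 100,
#'   ..., 1000).
#' @param exclusions list of \linkS4class{AnomalyBand} to apply first.
#' @param mode "all" (default) or "red".
#' @return a \linkS4class{RedSpotProfile}.
#' @rdname redSpotProfile
#' @export
setMethod("redSpotProfile", "DepthPointCloud",
  function(object, thresholds = seq(0, 1000, by = 100), exclusions = list(),
           mode = c("all", "red")) {
    mode <- match.arg(mode)
    if (is.unsorted(thresholds, strictly = TRUE))
      stop("thresholds must be strictly increasing")
    for (band in exclusions) object <- excludeBand(object, band)
    z <- object@coords[, 3]
    if (mode == "red") z <- z[object@colorClass == "red"]
    counts <- vapply(thresholds, function(t) sum(z > t), integer(1))
    new("RedSpotProfile", thresholds = as.numeric(thresholds),
        counts = counts, excludedBands = exclusions)
  })

#' Depth bound of a red-spot profile
#'
#' The smallest threshold whose count is zero: the lesion has not
#' surpassed that depth. When no count is zero the profile is flagged
#' beyond range and the sentinel \code{max(thresholds) + band width} is
#' returned (attribute \code{beyondRange = TRUE}).
#'
#' @param object a \linkS4class{RedSpotProfile}.
#' @return depth in heatmap units, possibly with attribute
#'   \code{beyondRange}.
#' @examples
#' depthBound(table1Profiles()[["benign_10pct"]])   # 700
#' @rdname depthBound
#' @export
setMethod("depthBound", "RedSpotProfile", function(object) {
  validObject(object)
  i <- which(object@counts == 0L)
  if (length(i)) return(object@thresholds[min(i)])
  thr <- object@thresholds
  band <- if (length(thr) > 1L) thr[length(thr)] - thr[length(thr) - 1L] else 0
  structure(thr[length(thr)] + band, beyondRange = TRUE)
})

#' Deepest extent of a red-spot profile
#'
#' The largest threshold whose count is strictly positive; 0 when every
#' count is zero (surface only).
#'
#' @param object a \linkS4class{RedSpotProfile}.
#' @return depth in heatmap units.
#' @examples
#' deepestExtent(table1Profiles()[["malignant_99pct"]])   # 900
#' @rdname deepestExtent
#' @export
setMethod("deepestExtent", "RedSpotProfile", function(object) {
  validObject(object)
  i <- which(object@counts > 0L)
  if (!length(i)) return(0)
  object@thresholds[max(i)]
})

#' Write a red-spot profile as CSV
#'
#' Two columns, \code{threshold} ("Below t" rows) and \code{count},
#' mirroring the reference table layout.
#'
#' @param profile a \linkS4class{RedSpotProfile}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeProfileCSV <- function(profile, path) {
  utils::write.csv(data.frame(threshold = profile@thresholds,
                              count = profile@counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a red-spot profile from CSV
#'
#' @param path CSV with columns threshold and count.
#' @param label optional case label.
#' @return a \linkS4class{RedSpotProfile}.
#' @export
readProfileCSV <- function(path, label = NA_character_) {
  tab <- utils::read.csv(path)
  new("RedSpotProfile", thresholds = as.numeric(tab$threshold),
      counts = as.integer(tab$count), label = label)
}
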