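#' @rdname depthBound
#' @export
setGeneric("depthBound", function(object, ...) standardGeneric("depthBound"))

#' @rdname deepestExtent
#' @export
setGeneric("deepestExtent", function(object, ...) standardGeneric("deepestExtent"))

#' @rdname excludeBand
#' @export
setGeneric("excludeBand", function(object, band, ...) standardGeneric("excludeBand"))

#' @rdname redSpotProfile
#' @export
setGeneric("redSpotProfile", function(object, ...) standardGeneric("redSpotProfile"))

#' @rdname buildConic
#' @export
setGeneric("buildConic", function(object, ...) standardGeneric("buildConic"))

#' @rdname accessors
#' @export
setGeneric("grid", function(object) standardGeneric("grid"))

#' @rdname accessors
#' @export
setGeneric("raster", function(object) standardGeneric("raster"))

#' @rdname accessors
#' @export
setGeneric("lesionMask", function(object) standardGeneric("lesionMask"))

#' @rdname accessors
#' @export
setGeneric("cloudPoints", function(object) standardGeneric("cloudPoints"))

#' @rdname accessors
#' @export
setGeneric("colorClass", function(object) standardGeneric("colorClass"))

#' @rdname accessors
#' @export
setGeneric("depthScale", function(object) standardGeneric("depthScale"))

#' @rdname accessors
#' @export
setGeneric("profileCounts", function(object) standardGeneric("profileCounts"))

#' @rdname accessors
#' @export
setGeneric("profileThresholds", function(object) standardGeneric("profileThresholds"))

#' @rdname accessors
#' @export
setGeneric("conicSlices", function(object) standardGeneric("conicSlices"))
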