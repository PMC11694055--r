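# Dense depth-proxy estimation from single-image defocus: Canny edges,
# gradient-ratio blur estimation at the edges, inverse-distance propagation
# inward, and normalization.

#' Canny edge detection
#'
#' Classical Canny on a 0-255 grayscale grid: Sobel gradients, orientation-
#' quantized non-maximum suppression, then hysteresis — magnitudes above
#' \code{high} seed edges, magnitudes in \code{[low, high]} are kept only
#' when 8-connected to a seed, anything below \code{low} is discarded. The
#' default thresholds are (50, 150). No pre-smoothing is applied by
#' default; pass \code{smoothSigma > 0} to blur first.
#'
#' The non-maximum tie-break is directionally asymmetric (>= against the
#' preceding neighbor, > against the following one) so a symmetric discrete
#' step yields a single-pixel edge line rather than a tied pair.
#'
#' @param gray H x W numeric matrix on the 0-255 scale (see
#'   \code{\link{luminance}}).
#' @param low,high hysteresis thresholds, \code{high >= low >= 0}.
#' @param smoothSigma optional Gaussian pre-smoothing sigma (0 = none).
#' @return logical H x W edge map.
#' @examples
#' step <- matrix(0, 32, 32); step[, 17:32] <- 255
#' which(colSums(detectEdges(step)) > 0)    # single edge column
#' @export
detectEdges <- function(gray, low = 50, high = 150, smoothSigma = 0) {
  if (!is.matrix(gray)) stop("detectEdges expects a 2D grayscale matrix")
  if (low < 0 || high < low) stop("need high >= low >= 0")
  if (smoothSigma > 0) gray <- convSeparable(gray, gaussianKernel1d(smoothSigma))
  nr <- nrow(gray); nc <- ncol(gray)
  sh <- function(m, dr, dc) m[reflectIndex(seq_len(nr) + dr, nr),
                              reflectIndex(seq_len(nc) + dc, nc)]
  # Sobel (unnormalized, OpenCV convention)
  gx <- (sh(gray, -1, 1) + 2 * sh(gray, 0, 1) + sh(gray, 1, 1)) -
        (sh(gray, -1, -1) + 2 * sh(gray, 0, -1) + sh(gray, 1, -1))
  gy <- (sh(gray, 1, -1) + 2 * sh(gray, 1, 0) + sh(gray, 1, 1)) -
        (sh(gray, -1, -1) + 2 * sh(gray, -1, 0) + sh(gray, -1, 1))
  mag <- sqrt(gx^2 + gy^2)
  # quantize orientation to 4 bins: 0 (E-W), 45, 90 (N-S), 135 degrees
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  bin <- as.integer(round(ang / (pi / 4))) %% 4L
  nms <- matrix(FALSE, nr, nc)
  offs <- list(`0` = c(0L, 1L), `1` = c(1L, 1L), `2` = c(1L, 0L), `3` = c(1L, -1L))
  for (b in 0:3) {
    dd <- offs[[b + 1L]]
    fwd <- sh(mag, dd[1], dd[2])
    bwd <- sh(mag, -dd[1], -dd[2])
    keep <- bin == b & mag >= bwd & mag > fwd
    nms <- nms | keep
  }
  mag[!nms] <- 0
  strong <- mag > high
  weak <- mag >= low & mag <= high
  # hysteresis: grow strong into 8-connected weak pixels until stable
  repeat {
    grown <- strong
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      grown <- grown | sh(strong, dr, dc)
    }
    newEdges <- grown & weak & !strong
    if (!any(newEdges)) break
    strong <- strong | newEdges
  }
  strong
}

#' Gaussian smoothing
#'
#' Separable convolution with a normalized Gaussian kernel (4-sigma
#' support) under reflective boundary handling, so the mean intensity is
#' preserved to numerical tolerance.
#'
#' @param gray numeric matrix.
#' @param sigma Gaussian sigma in pixels (> 0).
#' @return the smoothed matrix.
#' @export
gaussianSmooth <- function(gray, sigma) {
  if (!is.matrix(gray)) stop("gaussianSmooth expects a matrix")
  if (sigma <= 0) stop("sigma must be > 0")
  convSeparable(gray, gaussianKernel1d(sigma))
}

#' Estimate per-edge defocus blur by the gradient ratio
#'
#' At each edge pixel the ratio \eqn{R = |\nabla original| / |\nabla
#' reblurred|} of gradient magnitudes between the original image and its
#' re-blurred copy (known sigma0) identifies the local defocus sigma of an
#' ideal blurred step edge in closed form:
#' \eqn{\sigma = \sigma_0 / \sqrt{R^2 - 1}}. R is clamped above 1; a ratio
#' at or below 1 (pure noise) and a vanishing re-blurred gradient are
#' assigned \code{maxBlur} and flagged. Estimates are clamped to
#' \code{[0, maxBlur]} and undefined (NA) off the edge set.
#'
#' @param original 0-255 grayscale matrix.
#' @param reblurred \code{gaussianSmooth(original, sigma0)}.
#' @param edges logical edge map from \code{\link{detectEdges}}.
#' @param sigma0 the re-blur sigma used to produce \code{reblurred}.
#' @param maxBlur clamp value for the estimates (pixels).
#' @return a \linkS4class{SparseBlurMap}.
#' @export
estimateEdgeBlur <- function(original, reblurred, edges, sigma0 = 1,
                             maxBlur = 5) {
  stopifnot(identical(dim(original), dim(reblurred)),
            identical(dim(original), dim(edges)))
  g0 <- gradientMagnitude(original)
  g1 <- gradientMagnitude(reblurred)
  vals <- matrix(NA_real_, nrow(original), ncol(original))
  flag <- matrix(FALSE, nrow(original), ncol(original))
  idx <- which(edges)
  if (length(idx)) {
    a <- g0[idx]; b <- g1[idx]
    sig <- rep(maxBlur, length(idx))
    bad <- b <= .Machine$double.eps | a <= b      # R <= 1 or degenerate
    R <- ifelse(bad, NA_real_, a / b)
    ok <- !bad
    sig[ok] <- pmin(sigma0 / sqrt(R[ok]^2 - 1), maxBlur)
    vals[idx] <- sig
    flag[idx] <- bad
  }
  new("SparseBlurMap", values = vals, maxBlur = maxBlur, flagged = flag)
}

#' Propagate sparse edge blur into the full frame
#'
#' Assigns every pixel the inverse-distance-weighted mean of the
#' \code{m} nearest edge-pixel blur values, producing a dense defocus
#' field; edge pixels keep their own value. The output range is bounded by
#' the sparse range (convexity of weighted means). An empty edge set
#' degenerates to the all-zero map with a warning (no defocus evidence is
#' read as "no measurable depth", not maximal depth).
#'
#' Flagged estimates (degenerate ratios assigned the clamp value) carry no
#' blur information and are excluded from the source set by default.
#'
#' @param sparse a \linkS4class{SparseBlurMap}.
#' @param m number of nearest edge pixels (default 5).
#' @param dropFlagged exclude flagged (censored) estimates from the
#'   sources (default TRUE).
#' @return dense numeric matrix of blur sigmas.
#' @export
propagateDefocus <- function(sparse, m = 5L, dropFlagged = TRUE) {
  v <- sparse@values
  idx <- if (dropFlagged) which(!is.na(v) & !sparse@flagged) else which(!is.na(v))
  if (!length(idx)) {
    warning("empty edge set: propagating the all-zero defocus field")
    return(matrix(0, nrow(v), ncol(v)))
  }
  er <- ((idx - 1L) %% nrow(v)) + 1L
  ec <- ((idx - 1L) %/% nrow(v)) + 1L
  dense <- propagate_idw_cpp(er, ec, v[idx], nrow(v), ncol(v),
                             as.integer(min(m, length(idx))))
  dense
}

#' Min-max normalize a dense map
#'
#' \code{(x - min) / (max - min)}; a constant input maps to all zeros (no
#' defocus contrast is read as shallowest, never as maximal depth).
#' Non-finite values are rejected.
#'
#' @param map dense numeric matrix.
#' @return a \linkS4class{DefocusMap} with \code{normalization = "minmax"}.
#' @examples
#' grid(normalizeMinMax(matrix(c(0, 5, 10, 10), 2)))
#' @export
normalizeMinMax <- function(map) {
  if (is(map, "DefocusMap")) map <- map@grid
  if (any(!is.finite(map))) stop("map must be finite")
  rng <- range(map)
  g <- if (diff(rng) < 1e-12) map * 0 else (map - rng[1]) / diff(rng)
  new("DefocusMap", grid = g, normalization = "minmax")
}

#' Normalize a blur field on the absolute scale
#'
#' Divides the dense blur-sigma field by \code{maxBlur}, mapping it to
#' \[0, 1\] while preserving cross-image comparability of depth (two images
#' keep their relative blur; a per-image min-max stretch would not). This
#' is the normalization feeding the 3D depth volume by default.
#'
#' @param map dense numeric matrix of blur sigmas.
#' @param maxBlur the blur clamp the sigmas were estimated under.
#' @return a \linkS4class{DefocusMap} with \code{normalization = "absolute"}.
#' @export
normalizeAbsolute <- function(map, maxBlur = 5) {
  if (any(!is.finite(map))) stop("map must be finite")
  g <- pmin(pmax(map / maxBlur, 0), 1)
  new("DefocusMap", grid = g, normalization = "absolute")
}

#' Full defocus-occurrence depth map from an image
#'
#' Convenience chain: luminance, Canny edges, Gaussian re-blur, gradient-
#' ratio blur estimation at the edges, inverse-distance propagation, and
#' normalization.
#'
#' @param image a \linkS4class{LesionImage} (typically the blended
#'   localization output).
#' @param cannyLow,cannyHigh Canny thresholds.
#' @param sigma0 re-blur sigma.
#' @param maxBlur blur clamp.
#' @param normalization "absolute" or "minmax".
#' @param m neighbors for the propagation.
#' @return a \linkS4class{DefocusMap}.
#' @export
estimateDefocusMap <- function(image, cannyLow = 50, cannyHigh = 150,
                               sigma0 = 1, maxBlur = 5,
                               normalization = c("absolute", "minmax"),
                               m = 5L) {
  normalization <- match.arg(normalization)
  gray <- luminance(image@raster)
  edges <- detectEdges(gray, cannyLow, cannyHigh)
  reblur <- gaussianSmooth(gray, sigma0)
  sparse <- estimateEdgeBlur(gray, reblur, edges, sigma0, maxBlur)
  dense <- suppressWarnings(propagateDefocus(sparse, m))
  if (normalization == "absolute") normalizeAbsolute(dense, maxBlur)
  else normalizeMinMax(dense)
}
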