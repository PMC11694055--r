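# Gabor filter bank and construction of the 3D depth point cloud.

#' Construct Gabor filter parameters
#'
#' @param theta orientation in radians.
#' @param frequency carrier frequency in cycles/pixel (> 0).
#' @param sigma Gaussian envelope spread (default 0.01: a near-delta,
#'   sharply pixelated response).
#' @param gamma spatial aspect ratio in (0, 1]; scales the minor-axis
#'   coordinate of the envelope (anti-isotropic analysis).
#' @param size kernel side length in pixels.
#' @return a \linkS4class{GaborParams}.
#' @export
gaborParams <- function(theta = 0, frequency = 0.1, sigma = 0.01,
                        gamma = 0.5, size = 5L) {
  new("GaborParams", theta = theta, frequency = frequency, sigma = sigma,
      gamma = gamma, size = as.integer(size))
}

#' Evaluate a spatial Gabor kernel
#'
#' Real (cosine-phase) Gabor mask on a \code{size x size} grid centered at
#' the origin: a Gaussian envelope with spread \code{sigma} whose
#' minor-axis coordinate is scaled by \code{gamma}, multiplied by a cosine
#' carrier of the given frequency along orientation \code{theta}:
#' \deqn{g(x, y) = \exp\!\big(-(x'^2 + \gamma^2 y'^2) / (2\sigma^2)\big)
#'   \cos(2\pi f x')}
#' with \eqn{x' = x\cos\theta + y\sin\theta},
#' \eqn{y' = -x\sin\theta + y\cos\theta} (the OpenCV parameterization with
#' phase offset 0).
#'
#' @param p a \linkS4class{GaborParams}.
#' @return a \code{size x size} numeric kernel; rows index y, columns x.
#' @examples
#' makeGaborKernel(gaborParams(theta = 0, sigma = 1.5))
#' @export
makeGaborKernel <- function(p) {
  validObject(p)
  n <- p@size
  half <- (n - 1) / 2
  x <- matrix(seq_len(n) - 1 - half, n, n, byrow = TRUE)
  y <- matrix(seq_len(n) - 1 - half, n, n)
  xr <- x * cos(p@theta) + y * sin(p@theta)
  yr <- -x * sin(p@theta) + y * cos(p@theta)
  env <- exp(-(xr^2 + (p@gamma * yr)^2) / (2 * p@sigma^2))
  k <- env * cos(2 * pi * p@frequency * xr)
  if (any(!is.finite(k))) stop("non-finite Gabor kernel values")
  k
}

#' The four-filter default Gabor bank
#'
#' Orientations 0, pi/4, pi/2 and 3 pi/4; frequency 0.1 for the
#' axis-aligned filters (fine horizontal/vertical detail) and 0.4 for the
#' angled filters (coarse detail); sigma 0.01 along both axes and gamma
#' 0.5 on 5 x 5 grids.
#'
#' @return list of four \linkS4class{GaborParams}.
#' @export
defaultGaborBank <- function() {
  th <- c(0, pi / 4, pi / 2, 3 * pi / 4)
  fr <- c(0.1, 0.4, 0.1, 0.4)
  mapply(function(t, f) gaborParams(theta = t, frequency = f),
         th, fr, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Build the 3D depth point cloud from a defocus map
#'
#' Convolves the normalized defocus map with every filter of the bank
#' (reflect padding, same-size output), combines the per-pixel response
#' magnitudes (\code{combine = "max"} by default, \code{"mean"}
#' available), couples the combined response U with the defocus value d as
#' the geometric mean \eqn{\sqrt{U d}} (clamped to \[0, 1\]), and emits one
#' point per pixel with \code{z = depthScale * composite} and a diverging
#' red/blue/neutral class from \code{\link{classifySpotColor}} at midpoint
#' \code{depthScale / 2}. Substituting a single unit-impulse kernel for
#' the bank collapses the construction to \code{z = defocus * depthScale}
#' exactly.
#'
#' @param map a \linkS4class{DefocusMap}.
#' @param bank non-empty list of \linkS4class{GaborParams} (default the
#'   four-filter bank).
#' @param depthScale maximum depth in heatmap units (default 1000).
#' @param combine "max" or "mean" response combination.
#' @return a \linkS4class{DepthPointCloud} with one point per pixel
#'   (x = column, y = row).
#' @export
depthVolume <- function(map, bank = defaultGaborBank(), depthScale = 1000,
                        combine = c("max", "mean")) {
  combine <- match.arg(combine)
  if (!length(bank)) stop("the Gabor bank must be non-empty")
  d <- map@grid
  resp <- lapply(bank, function(p) {
    kern <- if (is.matrix(p)) p else makeGaborKernel(p)
    abs(conv2Reflect(d, kern))
  })
  U <- if (combine == "max") Reduce(pmax, resp)
       else Reduce(`+`, resp) / length(resp)
  composite <- pmin(sqrt(U * d), 1)
  z <- depthScale * composite
  nr <- nrow(d); nc <- ncol(d)
  coords <- cbind(x = rep(seq_len(nc), each = nr),
                  y = rep(seq_len(nr), times = nc),
                  z = as.vector(z))
  cl <- factor(classifySpotColor(coords[, 3], depthScale / 2),
               levels = c("red", "blue", "neutral"))
  new("DepthPointCloud", coords = coords, colorClass = cl,
      depthScale = depthScale)
}
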