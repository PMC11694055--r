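# Synthetic fixtures: lesion images emulating dermoscopy archive inputs and
# inverse-designed depth point clouds whose red-spot profiles are exact.

#' Construct a synthetic lesion specification
#'
#' Convenience constructor for \linkS4class{SyntheticLesionSpec} with
#' validity checking. The defaults draw a high-contrast, mildly irregular
#' dark blob centered on a 224 x 224 light-skin background.
#'
#' @param seed integer seed controlling border phases and texture noise.
#' @param imageSize square image side in pixels.
#' @param lesionCenter numeric (row, col).
#' @param lesionAxes numeric (a, b) semi-axes in pixels.
#' @param borderIrregularity radial perturbation amplitude (>= 0).
#' @param lesionColor,skinColor RGB triples in \[0, 1\].
#' @param edgeBlurSigma boundary blur sigma in pixels (>= 0).
#' @param textureAmplitude skin texture noise amplitude.
#' @return a validated \linkS4class{SyntheticLesionSpec}.
#' @examples
#' spec <- lesionSpec(seed = 7, edgeBlurSigma = 2)
#' img <- generateLesionImage(spec)
#' @export
lesionSpec <- function(seed = 1L, imageSize = 224L,
                       lesionCenter = c(imageSize / 2, imageSize / 2),
                       lesionAxes = c(55, 40) * imageSize / 224,
                       borderIrregularity = 0.15,
                       lesionColor = c(0.08, 0.05, 0.05),
                       skinColor = c(0.95, 0.80, 0.75),
                       edgeBlurSigma = 0, textureAmplitude = 0.01) {
  new("SyntheticLesionSpec", seed = as.integer(seed),
      imageSize = as.integer(imageSize), lesionCenter = lesionCenter,
      lesionAxes = lesionAxes, borderIrregularity = borderIrregularity,
      lesionColor = lesionColor, skinColor = skinColor,
      edgeBlurSigma = edgeBlurSigma, textureAmplitude = textureAmplitude)
}

#' Generate a synthetic lesion image
#'
#' Renders the specified lesion: an elliptical blob whose boundary radius is
#' perturbed by a seed-controlled sinusoidal series (irregular border), hard
#' or blur-graded against the skin, over a smooth low-amplitude texture
#' field. Deterministic for a fixed seed. The ground-truth lesion mask is
#' recorded in the returned \linkS4class{LesionImage}.
#'
#' @param spec a valid \linkS4class{SyntheticLesionSpec}.
#' @return a \linkS4class{LesionImage} with \code{lesionMask} set.
#' @examples
#' img <- generateLesionImage(lesionSpec(seed = 1))
#' mean(lesionMask(img))
#' @export
generateLesionImage <- function(spec) {
  validObject(spec)
  n <- spec@imageSize
  withSeed(spec@seed, {
    # radial sinusoidal border perturbation: s(phi) = 1 + irr * sum_j a_j sin(j phi + phase_j)
    nh <- 4L
    amp <- stats::runif(nh)
    amp <- amp / sum(amp)                      # total perturbation bounded by irr
    phase <- stats::runif(nh, 0, 2 * pi)
    row <- matrix(seq_len(n), n, n)
    col <- matrix(seq_len(n), n, n, byrow = TRUE)
    dy <- row - spec@lesionCenter[1]
    dx <- col - spec@lesionCenter[2]
    rho <- sqrt((dy / spec@lesionAxes[1])^2 + (dx / spec@lesionAxes[2])^2)
    phi <- atan2(dy, dx)
    s <- 1
    if (spec@borderIrregularity > 0) {
      s <- 1 + spec@borderIrregularity *
        Reduce(`+`, lapply(seq_len(nh), function(j) amp[j] * sin(j * phi + phase[j])))
    }
    mask <- rho <= s
    soft <- mask + 0
    if (spec@edgeBlurSigma > 0)
      soft <- convSeparable(soft, gaussianKernel1d(spec@edgeBlurSigma))
    texture <- matrix(stats::rnorm(n * n), n, n)
    texture <- convSeparable(texture, gaussianKernel1d(1.5))
    texture <- spec@textureAmplitude * texture / max(stats::sd(texture), 1e-12)
    ras <- array(0, c(n, n, 3))
    for (ch in 1:3) {
      plane <- soft * spec@lesionColor[ch] + (1 - soft) * spec@skinColor[ch] + texture
      ras[, , ch] <- pmin(pmax(plane, 0), 1)
    }
    new("LesionImage", raster = ras, lesionMask = mask, source = "synthetic")
  })
}

#' The four printed red-spot reference profiles
#'
#' Returns the four study cases of the banded red-spot reference table
#' (10\% benign, 98\% malignant, 2\% benign, 99\% malignant) as
#' \linkS4class{RedSpotProfile} objects, read from the CSV shipped in
#' \code{inst/extdata/table1_redspot_profiles.csv}.
#'
#' @return named list of four \linkS4class{RedSpotProfile}s.
#' @examples
#' profs <- table1Profiles()
#' profileCounts(profs[["malignant_99pct"]])
#' @export
table1Profiles <- function() {
  path <- system.file("extdata", "table1_redspot_profiles.csv",
                      package = "LesionDepth", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  labs <- names(tab)[-1]
  out <- lapply(labs, function(lb)
    new("RedSpotProfile", thresholds = as.numeric(tab$threshold),
        counts = as.integer(tab[[lb]]), label = lb))
  stats::setNames(out, labs)
}

#' Inverse-design a depth point cloud from a red-spot profile
#'
#' Builds a \linkS4class{DepthPointCloud} whose recomputed red-spot profile
#' (counts of points with z strictly greater than each threshold) equals
#' the given profile exactly: the i-th depth band (t_i, t_i + band] receives
#' \code{counts[i] - counts[i + 1]} points with depths uniform in the
#' half-open interval. The final count must be 0 so no point exceeds the
#' depth scale. x/y coordinates are uniform over a 224 x 224 frame.
#'
#' @param profile a monotone \linkS4class{RedSpotProfile}.
#' @param seed integer seed for the uniform band placement.
#' @param frameSize side of the pixel frame for x/y placement.
#' @return a \linkS4class{DepthPointCloud} with
#'   \code{depthScale = max(thresholds)}.
#' @examples
#' p <- table1Profiles()[[1]]
#' cl <- cloudFromProfile(p, seed = 42)
#' identical(profileCounts(redSpotProfile(cl)), profileCounts(p))
#' @export
cloudFromProfile <- function(profile, seed = 1L, frameSize = 224L) {
  validObject(profile)     # rejects non-monotone profiles
  thr <- profile@thresholds
  cnt <- profile@counts
  k <- length(thr)
  if (cnt[k] != 0L)
    stop("the final count must be 0: points beyond the deepest threshold have no band")
  scale <- max(thr)
  bandN <- cnt[-k] - cnt[-1]
  total <- cnt[1]
  withSeed(seed, {
    z <- numeric(total)
    pos <- 0L
    for (i in seq_len(k - 1L)) {
      nb <- bandN[i]
      if (nb == 0L) next
      u <- stats::runif(nb)
      while (any(u <= 0 | u >= 1)) u[u <= 0 | u >= 1] <- stats::runif(sum(u <= 0 | u >= 1))
      # depths strictly inside (t_i, t_{i+1}]: upper endpoint approached, never t_i
      z[pos + seq_len(nb)] <- thr[i] + u * (thr[i + 1L] - thr[i])
      pos <- pos + nb
    }
    x <- stats::runif(total, 1, frameSize)
    y <- stats::runif(total, 1, frameSize)
    cl <- if (total) factor(classifySpotColor(z, scale / 2),
                            levels = c("red", "blue", "neutral"))
          else factor(character(), levels = c("red", "blue", "neutral"))
    new("DepthPointCloud",
        coords = cbind(x = x, y = y, z = z),
        colorClass = cl, depthScale = scale)
  })
}

#' Random monotone red-spot profile
#'
#' Draws a valid random profile (non-increasing counts, final count 0) for
#' property-style testing of the cloud/profile round trip.
#'
#' @param seed integer seed.
#' @param maxCount upper bound for the surface count.
#' @param thresholds threshold grid.
#' @return a \linkS4class{RedSpotProfile}.
#' @export
randomMonotoneProfile <- function(seed = 1L, maxCount = 2000L,
                                  thresholds = seq(0, 1000, by = 100)) {
  withSeed(seed, {
    k <- length(thresholds)
    # geometric-ish decay with random gaps, mimicking the reference table
    raw <- sort(stats::rpois(k - 1L, lambda = stats::runif(k - 1L, 0, maxCount / 4)),
                decreasing = TRUE)
    counts <- as.integer(c(pmin(raw, maxCount), 0L))
    new("RedSpotProfile", thresholds = thresholds, counts = counts,
        label = sprintf("random-%d", seed))
  })
}

#' Write a lesion image as PNG
#'
#' @param image a \linkS4class{LesionImage}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeLesionImage <- function(image, path) {
  png::writePNG(image@raster, path)
  invisible(path)
}

#' Read a lesion image from PNG or JPEG-decoded array
#'
#' Reads a PNG file into a \linkS4class{LesionImage} (no ground-truth
#' mask). Grayscale images are expanded to three channels; an alpha channel
#' is dropped.
#'
#' @param path PNG file path.
#' @return a \linkS4class{LesionImage}.
#' @export
readLesionImage <- function(path) {
  if (!file.exists(path)) stop("input image not found: ", path)
  a <- png::readPNG(path)
  if (is.matrix(a)) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  new("LesionImage", raster = a, source = path)
}
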