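# Low-level raster helpers shared across the pipeline stages.
# Images are H x W (x 3) double arrays in [0, 1]; grayscale work is done on
# the 0-255 luminance scale so the classical Canny thresholds apply directly.

#' Convert an RGB raster to 0-255 luminance
#'
#' Rec. 601 luma weights (0.299, 0.587, 0.114). A matrix input is assumed to
#' already be grayscale in [0, 1] and is only rescaled.
#'
#' @param raster H x W x 3 array in \[0, 1\], or an H x W matrix.
#' @return H x W numeric matrix on the 0-255 scale.
#' @export
luminance <- function(raster) {
  if (is.matrix(raster)) return(raster * 255)
  stopifnot(length(dim(raster)) == 3L, dim(raster)[3] >= 3L)
  255 * (0.299 * raster[, , 1] + 0.587 * raster[, , 2] + 0.114 * raster[, , 3])
}

# even-symmetric (repeat-edge) reflection index for 1-based position i in
# 1..n; chosen over mirror-without-repeat because the induced convolution
# operator is symmetric with unit row sums, so a normalized symmetric
# kernel conserves total mass exactly
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- (i - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  as.integer(ifelse(j >= n, period - 1L - j, j)) + 1L
}

# 1D normalized Gaussian taps; radius chosen at 4 sigma
gaussianKernel1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with reflective boundary; exact mass preservation
convSeparable <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (o in -r:r) out <- out + k[o + r + 1L] * m[reflectIndex(seq_len(nr) + o, nr), ]
  m2 <- out
  out <- matrix(0, nr, nc)
  for (o in -r:r) out <- out + k[o + r + 1L] * m2[, reflectIndex(seq_len(nc) + o, nc)]
  out
}

# full 2D convolution (kernel flipped, i.e. true convolution) with reflect padding
conv2Reflect <- function(m, kern) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- nrow(kern); kc <- ncol(kern)
  cr <- (kr + 1L) %/% 2L; cc <- (kc + 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    ri <- reflectIndex(seq_len(nr) - (i - cr), nr)
    for (j in seq_len(kc)) {
      if (kern[i, j] == 0) next
      cj <- reflectIndex(seq_len(nc) - (j - cc), nc)
      out <- out + kern[i, j] * m[ri, cj]
    }
  }
  out
}

# central-difference gradient magnitude (replicated border)
gradientMagnitude <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  lf <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  gy <- (dn - up) / 2
  gx <- (rt - lf) / 2
  sqrt(gx^2 + gy^2)
}

# classic 'jet' diverging-to-hot colormap, v in [0,1] -> n x 3 RGB in [0,1]
jetColors <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  cbind(r, g, b)
}

# compact viridis approximation used when writing defocus-map PNGs
viridisAnchors <- matrix(c(
  0.267, 0.005, 0.329,  0.283, 0.141, 0.458,  0.254, 0.265, 0.530,
  0.207, 0.372, 0.553,  0.164, 0.471, 0.558,  0.128, 0.567, 0.551,
  0.135, 0.659, 0.518,  0.267, 0.749, 0.441,  0.478, 0.821, 0.318,
  0.741, 0.873, 0.150,  0.993, 0.906, 0.144), ncol = 3, byrow = TRUE)

viridisColors <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  n <- nrow(viridisAnchors)
  pos <- v * (n - 1)
  i0 <- pmin(floor(pos), n - 2) + 1
  fr <- pos - (i0 - 1)
  viridisAnchors[i0, , drop = FALSE] * (1 - fr) +
    viridisAnchors[i0 + 1, , drop = FALSE] * fr
}

# 4-neighbor binary erosion (replicated border), for boundary extraction
erodeOnce <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  mask &
    mask[c(1L, seq_len(nr - 1L)), ] & mask[c(seq_len(nr)[-1L], nr), ] &
    mask[, c(1L, seq_len(nc - 1L))] & mask[, c(seq_len(nc)[-1L], nc)]
}

# run expr with a temporary RNG state seeded by `seed`
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
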