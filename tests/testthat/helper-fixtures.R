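# Shared helpers: independent brute-force oracles and tiny constructors.

# double-loop counting oracle for banded profiles (independent of the
# vectorized implementation)
bruteForceCounts <- function(z, thresholds) {
  counts <- integer(length(thresholds))
  for (i in seq_along(thresholds)) {
    n <- 0L
    for (p in z) if (p > thresholds[i]) n <- n + 1L
    counts[i] <- n
  }
  counts
}

# random depth point cloud with depths anywhere in [0, scale]
randomCloud <- function(seed, n = 400L, scale = 1000) {
  withr::with_seed(seed, {
    z <- runif(n, 0, scale)
    new("DepthPointCloud",
        coords = cbind(x = runif(n, 1, 224), y = runif(n, 1, 224), z = z),
        colorClass = factor(classifySpotColor(z, scale / 2),
                            levels = c("red", "blue", "neutral")),
        depthScale = scale)
  })
}

# ideal vertical step image on the 0-255 scale
stepImage <- function(n = 64L, at = n %/% 2L, amplitude = 255) {
  m <- matrix(0, n, n)
  m[, (at + 1L):n] <- amplitude
  m
}

# unit-impulse kernel (odd side) for the depth-volume limit check
deltaKernel <- function(size = 5L) {
  k <- matrix(0, size, size)
  k[(size + 1L) %/% 2L, (size + 1L) %/% 2L] <- 1
  k
}
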