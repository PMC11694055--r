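# Model adapters. The pipeline talks to its classifier only through the
# ModelAdapter contract, so it runs with a fixed stub, with the tiny
# stand-in network below, or with a full transfer-learning backend wired in
# by the user. The reference architecture (VGG19 base, include_top = FALSE,
# Flatten, five dense ReLU layers, one sigmoid unit, CAM tapped at
# block5_conv4) is documented here but not shipped: it needs trained
# weights, which this package deliberately does not carry.

#' Fixed-probability stub adapter
#'
#' Returns a constant malignancy probability and a saliency-style feature
#' map. With \code{cam = "darkness"} the single feature map is the
#' (smoothed) darkness of the image, so the resulting activation map
#' highlights the dark lesion blob; \code{cam = "uniform"} gives a flat
#' map. Gradients are all ones, so the CAM equals the rectified,
#' normalized feature map.
#'
#' @param probability constant probability in \[0, 1\].
#' @param cam "darkness" or "uniform".
#' @param mapSize spatial side of the emitted feature maps (the layer
#'   resolution; upsampled later).
#' @return a \linkS4class{ModelAdapter}.
#' @examples
#' ad <- stubAdapter(0.98)
#' classifyLesion(generateLesionImage(lesionSpec()), ad)$label
#' @export
stubAdapter <- function(probability, cam = c("darkness", "uniform"),
                        mapSize = 28L) {
  cam <- match.arg(cam)
  featureFun <- function(image) {
    g <- luminance(image@raster) / 255
    f <- if (cam == "darkness") {
      dk <- convSeparable(1 - g, gaussianKernel1d(2))
      bilinearResize(dk, mapSize, mapSize)
    } else matrix(1, mapSize, mapSize)
    array(f, c(mapSize, mapSize, 1L))
  }
  new("ModelAdapter",
      predictFun = function(image) probability,
      featureFun = featureFun,
      gradFun = function(image, target = 1) array(1, c(mapSize, mapSize, 1L)),
      camLayer = "block5_conv4",
      description = sprintf("stub (p = %.2f, %s CAM)", probability, cam))
}

#' Tiny convolutional stand-in network
#'
#' A two-convolution network with seeded random weights exercising the full
#' adapter contract analytically: conv 3x3 (K1 channels, ReLU), 2x2 mean
#' pool, conv 3x3 (K2 channels, ReLU) giving the tapped feature maps A^k,
#' then global average pooling and a linear head to the pre-activation
#' logit; the sigmoid of the logit is the predicted probability. Gradients
#' of the logit with respect to A^k are exactly \code{w_k / (H W)}
#' (constant grids), which the adapter returns in closed form. No trained
#' weights are involved; the network exists to exercise the contract, not
#' to classify.
#'
#' @param seed integer seed for the random weights.
#' @param k1,k2 channel counts of the two convolutions.
#' @return a \linkS4class{ModelAdapter}.
#' @export
tinyCNNAdapter <- function(seed = 1L, k1 = 3L, k2 = 4L) {
  withSeed(seed, {
    W1 <- array(stats::rnorm(3 * 3 * k1, sd = 0.5), c(3, 3, k1))
    W2 <- array(stats::rnorm(3 * 3 * k1 * k2, sd = 0.5), c(3, 3, k1, k2))
    wHead <- stats::rnorm(k2)
    bHead <- stats::rnorm(1, sd = 0.1)
  })
  forward <- function(image) {
    g <- luminance(image@raster) / 255
    h1 <- lapply(seq_len(k1), function(k) pmax(conv2Reflect(g, W1[, , k]), 0))
    pool <- lapply(h1, function(m) {
      nr <- 2L * (nrow(m) %/% 2L); nc <- 2L * (ncol(m) %/% 2L)
      m <- m[seq_len(nr), seq_len(nc)]
      (m[seq(1, nr, 2), seq(1, nc, 2)] + m[seq(2, nr, 2), seq(1, nc, 2)] +
       m[seq(1, nr, 2), seq(2, nc, 2)] + m[seq(2, nr, 2), seq(2, nc, 2)]) / 4
    })
    A <- array(0, c(nrow(pool[[1]]), ncol(pool[[1]]), k2))
    for (k in seq_len(k2)) {
      acc <- 0
      for (j in seq_len(k1)) acc <- acc + conv2Reflect(pool[[j]], W2[, , j, k])
      A[, , k] <- pmax(acc, 0)
    }
    A
  }
  new("ModelAdapter",
      predictFun = function(image) {
        A <- forward(image)
        logit <- sum(wHead * apply(A, 3, mean)) + bHead
        1 / (1 + exp(-logit))
      },
      featureFun = forward,
      gradFun = function(image, target = 1) {
        A <- forward(image)
        d <- dim(A)
        G <- array(0, d)
        for (k in seq_len(k2)) G[, , k] <- wHead[k] / (d[1] * d[2])
        G
      },
      camLayer = "conv2",
      description = sprintf("tiny 2-conv stand-in (seed %d)", seed))
}
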