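test_that("gradCAM matches hand-computed weighted sums and handles degenerate maps", {
  # unit weight on a single channel: rescaled rectification of the map itself
  Fm <- matrix(c(-1, 0, 2, 4), 2, 2)
  out <- gradCAM(Fm, matrix(1, 2, 2))
  expect_equal(grid(out), pmax(Fm, 0) / 4)

  # all-zero gradients give the all-zero map
  expect_equal(grid(gradCAM(Fm, matrix(0, 2, 2))), matrix(0, 2, 2))

  # K = 2 with alpha = (1, 0.5): raw map constant 1 -> all-ones rule
  A <- array(c(1, 0, 0, 1, 0, 2, 2, 0), c(2, 2, 2))
  G <- array(c(rep(1, 4), rep(0.5, 4)), c(2, 2, 2))
  expect_equal(grid(gradCAM(A, G)), matrix(1, 2, 2))

  # brute-force elementwise oracle on random stacks
  withr::with_seed(42, {
    for (rep in 1:5) {
      K <- sample(1:4, 1)
      A <- array(rnorm(4 * K), c(2, 2, K))
      G <- array(rnorm(4 * K), c(2, 2, K))
      raw <- matrix(0, 2, 2)
      for (i in 1:2) for (j in 1:2) {
        acc <- 0
        for (k in seq_len(K)) acc <- acc + mean(G[, , k]) * A[i, j, k]
        raw[i, j] <- max(acc, 0)
      }
      expected <- if (max(raw) <= 0) raw * 0
        else if (diff(range(raw)) < 1e-12) raw * 0 + 1
        else (raw - min(raw)) / diff(range(raw))
      expect_equal(grid(gradCAM(A, G)), expected)
    }
  })

  expect_error(gradCAM(matrix(1, 2, 2), matrix(1, 3, 3)), "identical dimensions")
})

test_that("gradCAM is invariant to positive gradient rescaling and channel dominance", {
  withr::with_seed(7, {
    A <- array(runif(64 * 3), c(8, 8, 3))
    G <- array(rnorm(64 * 3), c(8, 8, 3))
    expect_equal(grid(gradCAM(A, G)), grid(gradCAM(A, G * 37.5)))
    # one dominant channel, others zero-gradient
    G2 <- G; G2[, , 2:3] <- 0; G2[, , 1] <- abs(G2[, , 1])
    dom <- pmax(mean(G2[, , 1]) * A[, , 1], 0)
    expect_equal(grid(gradCAM(A, G2)),
                 (dom - min(dom)) / diff(range(dom)))
  })
})

test_that("bilinear upsampling preserves constants and matches the closed form", {
  cmap <- new("ActivationMap", grid = matrix(0.5, 2, 2))
  expect_equal(grid(upsampleMap(cmap, c(7, 5))), matrix(0.5, 7, 5))
  one <- new("ActivationMap", grid = matrix(1, 1, 1))
  expect_equal(grid(upsampleMap(one, c(4, 4))), matrix(1, 4, 4))
  # 2 x 2 ramp -> 2 x 4: align-corners column positions 1, 4/3, 5/3, 2
  ramp <- new("ActivationMap", grid = matrix(c(0, 0, 1, 1), 2, 2))
  expect_equal(grid(upsampleMap(ramp, c(2, 4))),
               matrix(rep(c(0, 1 / 3, 2 / 3, 1), each = 2), 2, 4))
  expect_error(upsampleMap(cmap, c(1, 1)), "downscale")
})

test_that("superimposition blends convexly and is exact at the extremes", {
  img <- generateLesionImage(lesionSpec(seed = 2, imageSize = 64,
                                        lesionAxes = c(16, 12)))
  cmap <- new("ActivationMap", grid = matrix(0.25, 64, 64))
  expect_identical(raster(superimpose(img, cmap, 0)), raster(img))
  heat <- LesionDepth:::jetColors(0.25)
  full <- raster(superimpose(img, cmap, 1))
  expect_equal(as.vector(full[1, 1, ]), as.vector(heat))
  half <- raster(superimpose(img, cmap, 0.5))
  expect_equal(half[3, 5, 2], (raster(img)[3, 5, 2] + heat[2]) / 2)
  expect_error(superimpose(img, cmap, 1.5), "alpha")
})

test_that("classification labels follow the inclusive 0.5 threshold", {
  img <- generateLesionImage(lesionSpec(seed = 1, imageSize = 64,
                                        lesionAxes = c(16, 12)))
  expect_identical(classifyLesion(img, stubAdapter(0.98))$label, "Malignant")
  expect_identical(classifyLesion(img, stubAdapter(0.10))$label, "Benign")
  expect_identical(classifyLesion(img, stubAdapter(0.5))$label, "Malignant")
  bad <- stubAdapter(0.5)
  bad@predictFun <- function(image) stop("backend down")
  expect_error(classifyLesion(img, bad), "adapter failed")
})

test_that("confusion metrics match direct formulas and a counting oracle", {
  perfect <- evaluateBinary(10, 0, 10, 0)
  expect_equal(unname(perfect), rep(1, 5))
  even <- evaluateBinary(1, 1, 1, 1)
  expect_equal(even[["accuracy"]], 0.5)
  expect_equal(even[["mcc"]], 0)
  expect_error(evaluateBinary(-1, 0, 0, 0), "non-negative")
  # degenerate denominators flag NA rather than erroring
  expect_true(is.na(evaluateBinary(0, 0, 5, 0)[["precision"]]))

  withr::with_seed(99, {
    for (rep in 1:50) {
      n <- sample(5:40, 1)
      truth <- sample(c(0L, 1L), n, replace = TRUE)
      pred <- sample(c(0L, 1L), n, replace = TRUE)
      tp <- sum(truth == 1 & pred == 1); fp <- sum(truth == 0 & pred == 1)
      tn <- sum(truth == 0 & pred == 0); fn <- sum(truth == 1 & pred == 0)
      m <- evaluateBinary(tp, fp, tn, fn)
      expect_equal(m[["accuracy"]], mean(truth == pred))
      if (!is.na(m[["recall"]]) && sum(truth) > 0)
        expect_equal(m[["recall"]], sum(pred[truth == 1]) / sum(truth))
    }
  })
})

test_that("the tiny stand-in network honors the adapter contract", {
  ad <- tinyCNNAdapter(seed = 4)
  img <- generateLesionImage(lesionSpec(seed = 5, imageSize = 64,
                                        lesionAxes = c(16, 12)))
  p <- ad@predictFun(img)
  expect_gte(p, 0); expect_lte(p, 1)
  A <- ad@featureFun(img)
  G <- ad@gradFun(img, 1)
  expect_identical(dim(A), dim(G))
  cam <- gradCAM(A, G, sourceLayer = ad@camLayer)
  expect_true(all(grid(cam) >= 0 & grid(cam) <= 1))
  # GAP head: gradient of the logit w.r.t. map k is w_k / (H W), a constant grid
  expect_true(all(apply(G, 3, function(m) diff(range(m)) == 0)))
})
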