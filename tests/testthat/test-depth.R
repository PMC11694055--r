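test_that("Canny finds a single-pixel vertical line on a step and nothing on a constant", {
  expect_identical(sum(detectEdges(matrix(128, 32, 32))), 0L)
  step <- stepImage(32, at = 16)
  e <- detectEdges(step)
  cols <- which(colSums(e) > 0)
  expect_length(cols, 1L)            # one-pixel-wide vertical line
  expect_true(cols %in% c(16L, 17L)) # adjacent to the step
  expect_equal(unname(colSums(e)[cols]), 32)
  expect_error(detectEdges(array(0, c(2, 2, 2))), "2D")
  expect_error(detectEdges(step, low = 100, high = 50), "high >= low")
})

test_that("hysteresis keeps weak edges only when connected to a strong seed", {
  # a ramp edge whose magnitude sits between the thresholds everywhere
  m <- matrix(0, 24, 24)
  m[, 13:24] <- 20                          # Sobel magnitude 80: weak only
  expect_identical(sum(detectEdges(m, 50, 150)), 0L)
  # same weak edge, but strong in the lower half: the weak half is adopted
  m2 <- matrix(0, 24, 24)
  m2[1:12, 13:24] <- 60                     # strong segment (240)
  m2[13:24, 13:24] <- 20                    # weak segment (80)
  e2 <- detectEdges(m2, 50, 150)
  expect_gt(sum(e2[13:24, ]), 0)
})

test_that("Gaussian smoothing preserves mass and matches the kernel on an impulse", {
  m <- matrix(0, 21, 21); m[11, 11] <- 1
  sm <- gaussianSmooth(m, 1)
  k <- LesionDepth:::gaussianKernel1d(1)
  r <- (length(k) - 1) / 2
  expect_equal(sm[11, 11 + (-r:r)], k * k[r + 1])
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  img <- matrix(runif(400), 20, 20)
  expect_equal(sum(gaussianSmooth(img, 2.5)), sum(img), tolerance = 1e-6)
  expect_equal(gaussianSmooth(matrix(3, 8, 8), 1.7), matrix(3, 8, 8))
  expect_error(gaussianSmooth(img, 0), "sigma")
})

test_that("the gradient ratio recovers a known blur and clamps degenerate ratios", {
  # edge pre-blurred with sigma 2, re-blur sigma0 1: recovered within 15%
  blurred <- gaussianSmooth(stepImage(64), 2)
  edges <- detectEdges(blurred)
  sp <- estimateEdgeBlur(blurred, gaussianSmooth(blurred, 1), edges,
                         sigma0 = 1, maxBlur = 5)
  est <- median(sp@values[!is.na(sp@values) & !sp@flagged])
  expect_lt(abs(est - 2) / 2, 0.15)

  # a sharp step reads far sharper than the blurred one
  sharp <- stepImage(64)
  spS <- estimateEdgeBlur(sharp, gaussianSmooth(sharp, 1),
                          detectEdges(sharp), 1, 5)
  expect_lt(median(spS@values, na.rm = TRUE), est / 1.5)

  # R <= 1 clamps to maxBlur and flags
  flat <- matrix(10, 16, 16)
  fakeEdges <- matrix(FALSE, 16, 16); fakeEdges[8, 8] <- TRUE
  spF <- estimateEdgeBlur(flat, flat, fakeEdges, 1, 5)
  expect_equal(spF@values[8, 8], 5)
  expect_true(spF@flagged[8, 8])
})

test_that("propagation interpolates by inverse distance and stays within the sparse range", {
  # single source: constant field
  v <- matrix(NA_real_, 9, 9); v[5, 5] <- 3
  sp <- new("SparseBlurMap", values = v, maxBlur = 5,
            flagged = matrix(FALSE, 9, 9))
  expect_equal(propagateDefocus(sp), matrix(3, 9, 9))

  # two parallel lines with blurs 1 and 3: midline is 2 under m = 2
  v2 <- matrix(NA_real_, 9, 9)
  v2[, 2] <- 1; v2[, 8] <- 3
  sp2 <- new("SparseBlurMap", values = v2, maxBlur = 5,
             flagged = matrix(FALSE, 9, 9))
  dense <- propagateDefocus(sp2, m = 2)
  expect_equal(dense[, 5], rep(2, 9))
  expect_lte(max(dense), 3 + 1e-9); expect_gte(min(dense), 1 - 1e-9)
  # hand-computed weights on a single-row grid: sources at distances 2 and 4
  v1d <- matrix(NA_real_, 1, 9); v1d[1, 2] <- 1; v1d[1, 8] <- 3
  sp1d <- new("SparseBlurMap", values = v1d, maxBlur = 5,
              flagged = matrix(FALSE, 1, 9))
  expect_equal(propagateDefocus(sp1d, m = 2)[1, 4],
               (1 / 2 * 1 + 1 / 4 * 3) / (1 / 2 + 1 / 4))
  # edge pixels keep their own values
  expect_equal(dense[3, 2], 1); expect_equal(dense[7, 8], 3)

  # equal sparse values reproduce the constant field exactly
  v3 <- matrix(NA_real_, 7, 7); v3[2, c(2, 5)] <- 1.4; v3[6, 3] <- 1.4
  sp3 <- new("SparseBlurMap", values = v3, maxBlur = 5,
             flagged = matrix(FALSE, 7, 7))
  expect_equal(propagateDefocus(sp3), matrix(1.4, 7, 7))

  # empty edge set degenerates to zero with a warning
  spE <- new("SparseBlurMap", values = matrix(NA_real_, 4, 4), maxBlur = 5,
             flagged = matrix(FALSE, 4, 4))
  expect_warning(out <- propagateDefocus(spE), "empty edge set")
  expect_equal(out, matrix(0, 4, 4))
})

test_that("min-max normalization is exact, idempotent and order-preserving", {
  expect_equal(as.vector(grid(normalizeMinMax(matrix(c(0, 5, 10, 10), 2)))),
               c(0, 0.5, 1, 1))
  expect_equal(grid(normalizeMinMax(matrix(7, 3, 3))), matrix(0, 3, 3))
  withr::with_seed(8, {
    m <- matrix(rnorm(100), 10)
    n1 <- grid(normalizeMinMax(m))
    expect_equal(min(n1), 0); expect_equal(max(n1), 1)
    expect_identical(order(n1), order(m))          # order preserved
    expect_equal(grid(normalizeMinMax(n1)), n1)    # idempotent
  })
  expect_error(normalizeMinMax(matrix(c(1, NA), 1)), "finite")
})

test_that("stronger lesion blur yields a deeper mean defocus inside the mask", {
  sharp <- generateLesionImage(lesionSpec(seed = 6, edgeBlurSigma = 0))
  soft <- generateLesionImage(lesionSpec(seed = 6, edgeBlurSigma = 2))
  dSharp <- estimateDefocusMap(sharp)
  dSoft <- estimateDefocusMap(soft)
  msk <- lesionMask(sharp)
  expect_gt(mean(grid(dSoft)[msk]), mean(grid(dSharp)[msk]))
})
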