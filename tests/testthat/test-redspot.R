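test_that("diverging color classes split around the midpoint with a 2% neutral band", {
  expect_identical(classifySpotColor(500, 500), "neutral")
  expect_identical(classifySpotColor(1000, 500), "red")
  expect_identical(classifySpotColor(0, 500), "blue")
  expect_identical(classifySpotColor(c(509, 511, 490, 489), 500),
                   c("neutral", "red", "neutral", "blue"))
  expect_error(classifySpotColor(-1, 500), "non-negative")
})

test_that("anomaly bands drop strictly interior points, idempotently", {
  z <- c(10, 10, 10)
  cl <- new("DepthPointCloud",
            coords = cbind(x = c(5, 5, 5), y = c(135, 140, 145), z = z),
            colorClass = factor(classifySpotColor(z, 500),
                                levels = c("red", "blue", "neutral")),
            depthScale = 1000)
  cut1 <- excludeBand(cl, figure3dBand())
  expect_equal(cloudPoints(cut1)[, 2], c(135, 145))  # only y = 140 removed
  expect_identical(cloudPoints(excludeBand(cut1, figure3dBand())),
                   cloudPoints(cut1))                # idempotent
  # band outside the cloud extent changes nothing
  expect_identical(cloudPoints(excludeBand(cl, anomalyBand("x", 100, 200))),
                   cloudPoints(cl))
  expect_error(anomalyBand("y", 5, 5), "lo must be")
})

test_that("profiles count strictly-deeper points and match a brute-force oracle", {
  emptyCl <- new("DepthPointCloud",
                 coords = matrix(0, 0, 3,
                                 dimnames = list(NULL, c("x", "y", "z"))),
                 colorClass = factor(character(),
                                     levels = c("red", "blue", "neutral")),
                 depthScale = 1000)
  expect_true(all(profileCounts(redSpotProfile(emptyCl)) == 0L))

  z <- c(rep(50, 7), rep(250, 3))
  cl <- new("DepthPointCloud",
            coords = cbind(x = seq_along(z), y = seq_along(z), z = z),
            colorClass = factor(classifySpotColor(z, 500),
                                levels = c("red", "blue", "neutral")),
            depthScale = 1000)
  p <- redSpotProfile(cl, thresholds = c(0, 100, 200, 300))
  expect_identical(profileCounts(p), c(10L, 3L, 3L, 0L))
  expect_error(redSpotProfile(cl, thresholds = c(100, 0)), "strictly increasing")

  # 100 random clouds against the double-loop counter
  for (s in 1:100) {
    rc <- randomCloud(s, n = 200L)
    counts <- profileCounts(redSpotProfile(rc))
    expect_identical(counts, bruteForceCounts(cloudPoints(rc)[, 3],
                                              seq(0, 1000, 100)))
    expect_true(all(diff(counts) <= 0L))
  }
})

test_that("exclusion never increases any band count", {
  for (s in c(3, 14, 159)) {
    rc <- randomCloud(s, n = 300L)
    before <- profileCounts(redSpotProfile(rc))
    after <- profileCounts(redSpotProfile(rc,
      exclusions = list(figure3dBand(), anomalyBand("x", 40, 90))))
    expect_true(all(after <= before))
  }
})

test_that("depth bound and deepest extent read the printed columns as reported", {
  profs <- table1Profiles()
  expect_equal(as.numeric(depthBound(profs[["benign_10pct"]])), 700)
  expect_equal(deepestExtent(profs[["malignant_99pct"]]), 900)
  # the last positive count of the second case sits at "Below 700"
  expect_equal(deepestExtent(profs[["malignant_98pct"]]), 700)
})

test_that("depth readings handle boundary profiles and the sentinel", {
  thr <- seq(0, 1000, 100)
  zero <- new("RedSpotProfile", thresholds = thr, counts = rep(0L, 11))
  expect_equal(as.numeric(depthBound(zero)), 0)
  expect_equal(deepestExtent(zero), 0)
  noZero <- new("RedSpotProfile", thresholds = thr,
                counts = as.integer(seq(110, 10, by = -10)))
  db <- depthBound(noZero)
  expect_equal(as.numeric(db), 1100)
  expect_true(isTRUE(attr(db, "beyondRange")))
  # the first zero follows the last positive band whenever in range
  for (s in 1:25) {
    p <- randomMonotoneProfile(seed = s)
    db <- depthBound(p); de <- deepestExtent(p)
    if (is.null(attr(db, "beyondRange")) && profileCounts(p)[1] > 0)
      expect_gte(as.numeric(db), de + 100)
  }
})

test_that("profile CSV round-trips", {
  p <- table1Profiles()[["malignant_98pct"]]
  f <- tempfile(fileext = ".csv")
  writeProfileCSV(p, f)
  p2 <- readProfileCSV(f)
  expect_identical(profileCounts(p2), profileCounts(p))
  expect_equal(profileThresholds(p2), profileThresholds(p))
})
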