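test_that("conic slices encode band counts as decreasing radii", {
  thr <- seq(0, 1000, 100)
  p <- new("RedSpotProfile", thresholds = thr,
           counts = c(100L, 50L, rep(0L, 9)))
  lin <- buildConic(p)
  s <- conicSlices(lin)
  expect_equal(s$radius, c(1, 0.5, 0))
  expect_equal(s$depth, c(0, 100, 200))      # apex at the depth bound
  sq <- conicSlices(buildConic(p, radiusMode = "sqrt"))
  expect_equal(sq$radius, c(1, sqrt(0.5), 0))

  # reference case 1: seven positive slices, apex at 700
  c1 <- conicSlices(buildConic(table1Profiles()[["benign_10pct"]]))
  expect_identical(nrow(c1), 8L)
  expect_equal(max(c1$depth), 700)

  # empty profile -> empty surface; non-monotone impossible by class validity
  zero <- new("RedSpotProfile", thresholds = thr, counts = rep(0L, 11))
  expect_identical(nrow(conicSlices(buildConic(zero))), 0L)
})

test_that("radii are non-increasing for every monotone profile", {
  for (p in table1Profiles())
    expect_true(all(diff(conicSlices(buildConic(p))$radius) <= 0))
  for (s in 1:100) {
    p <- randomMonotoneProfile(seed = s)
    if (profileCounts(p)[1] == 0L) next
    expect_true(all(diff(conicSlices(buildConic(p))$radius) <= 0))
  }
})

test_that("the lathe mesh has the predicted size and is watertight", {
  thr <- seq(0, 1000, 100)
  one <- new("RedSpotProfile", thresholds = thr,
             counts = c(10L, rep(0L, 10)))
  m1 <- meshFromConic(buildConic(one), nSides = 3)
  expect_identical(nrow(m1$vertices), 4L)    # smallest cone: 3 ring + apex
  expect_true(isWatertight(m1))

  two <- new("RedSpotProfile", thresholds = thr,
             counts = c(100L, 40L, rep(0L, 9)))
  m2 <- meshFromConic(buildConic(two), nSides = 4)
  expect_identical(nrow(m2$vertices), 9L)    # 4 * 2 rings + apex
  # walls 2*4 + apex fan 4 + top cap (4 - 2)
  expect_identical(nrow(m2$faces), 14L)
  expect_true(isWatertight(m2))

  # no degenerate triangles: every face has three distinct vertices
  expect_true(all(apply(m2$faces, 1, function(f) length(unique(f)) == 3L)))
  expect_error(meshFromConic(buildConic(new("RedSpotProfile",
    thresholds = thr, counts = rep(0L, 11)))), "empty")
})

test_that("meshes for the reference cases are watertight and malignant apexes are deeper", {
  profs <- table1Profiles()
  apex <- vapply(profs, function(p) max(conicSlices(buildConic(p))$depth), 1)
  for (p in profs) {
    mesh <- meshFromConic(buildConic(p), nSides = 16)
    expect_true(isWatertight(mesh))
  }
  expect_gt(min(apex[c("malignant_98pct", "malignant_99pct")]),
            max(apex[c("benign_10pct", "benign_2pct")]))
})

test_that("OBJ and PLY exports round-trip vertex coordinates", {
  p <- table1Profiles()[["benign_2pct"]]
  mesh <- meshFromConic(buildConic(p), nSides = 8, zRescale = 0.002)
  fo <- tempfile(fileext = ".obj")
  writeOBJ(mesh, fo)
  back <- readOBJ(fo)
  expect_equal(back$vertices, unname(mesh$vertices), tolerance = 1e-6)
  expect_identical(back$faces, mesh$faces)
  fp <- tempfile(fileext = ".ply")
  writePLY(mesh, fp)
  ply <- readLines(fp)
  expect_identical(ply[1], "ply")
  expect_identical(sum(grepl("^3 ", ply)), nrow(mesh$faces))
  # display rescale maps the 0-1000 depth range onto [0, -2]
  expect_equal(min(mesh$vertices[, 3]), -2 * max(conicSlices(buildConic(p))$depth) / 1000)
})
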