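test_that("a convex disc has an empty concave mask and a populated convex mask", {
  sil <- circleSilhouette()
  pm <- buildPolarityMasks(computeCurvature(sil), sil)
  expect_equal(roiArea(pm$concave), 0L)
  expect_gt(roiArea(pm$convex), 0L)
  expect_identical(roiLabel(pm$concave), "concave")
})

test_that("a notched disc concentrates concavity at the notch", {
  m <- discMask(200, c(99, 99), 80)
  m[91:109, 1:100] <- 0L  # wedge-like notch cut into the top
  sil <- extractContour(m)
  pm <- buildPolarityMasks(computeCurvature(sil), sil)
  cm <- maskMatrix(pm$concave)
  expect_gt(sum(cm), 0)
  idx <- which(cm > 0, arr.ind = TRUE)
  centroid <- colMeans(idx) - 1  # 0-based px
  # notch bounding box (x 90..110, y up to ~100), padded by the disk radius
  expect_true(centroid[1] > 70 && centroid[1] < 130)
  expect_lt(centroid[2], 120)
})

test_that("polarity disks grow monotonically with rMax", {
  sil <- circleSilhouette()
  cv <- computeCurvature(sil)
  a <- buildPolarityMasks(cv, sil, rMax = 10)
  b <- buildPolarityMasks(cv, sil, rMax = 20)
  expect_gte(roiArea(b$convex), roiArea(a$convex))
  # and every disk is centred on the contour: mask within rMax of it
  p <- contourPoints(sil)
  idx <- which(maskMatrix(b$convex) > 0, arr.ind = TRUE) - 1
  dmin <- vapply(seq_len(nrow(idx)), function(i) {
    min(sqrt((p[, 1] - idx[i, 1])^2 + (p[, 2] - idx[i, 2])^2))
  }, numeric(1))
  expect_lte(max(dmin), 20 + 1)
})

test_that("concavity extrema detection honours sign and prominence", {
  ell <- extractContour({
    m <- matrix(0L, 400, 400)
    sil <- generateShape(list(partPrimitive("ellipse", c(200, 200), c(120, 70))),
                         framePx = 400L, seed = 1)
    maskMatrix(sil)
  })
  expect_length(detectConcavityExtrema(computeCurvature(ell)), 0L)
  cv <- dumbbellCurvature()
  ex <- detectConcavityExtrema(cv)
  expect_length(ex, 2L)
  expect_identical(ex, sort(ex))
  expect_length(detectConcavityExtrema(cv, prominence = 1e6), 0L)
  expect_error(detectConcavityExtrema(cv, prominence = 0), "prominence")
})

test_that("the minima/short-cut rule recovers the dumbbell neck", {
  shp <- dumbbellShape()
  sil <- silhouette(shp)
  cuts <- computePartCuts(sil, detectConcavityExtrema(dumbbellCurvature()))
  expect_equal(nrow(cuts), 1L)
  expect_equal(cuts$length_px, 2 * sqrt(60^2 - 50^2), tolerance = 0.10)
  expect_lt(abs(cuts$x1 - 400), 6)  # the cut crosses the neck plane
  expect_true(cutMatches(cuts, trueCuts(shp)[1, ]))
})

test_that("a three-disc chain yields one cut per junction", {
  shp <- chain3Shape()
  sil <- silhouette(shp)
  cuts <- computePartCuts(sil, detectConcavityExtrema(computeCurvature(sil)))
  tc <- trueCuts(shp)
  expect_equal(nrow(cuts), 2L)
  expect_equal(nrow(tc), 2L)
  for (i in seq_len(nrow(tc))) {
    expect_true(cutMatches(cuts, tc[i, ]), info = paste("junction", i))
  }
})

test_that("convex shapes admit zero cuts", {
  sil <- circleSilhouette()
  cuts <- computePartCuts(sil, detectConcavityExtrema(computeCurvature(sil)))
  expect_equal(nrow(cuts), 0L)
})

test_that("part-boundary bands have the expected area and stay inside", {
  shp <- dumbbellShape()
  sil <- silhouette(shp)
  empty <- buildPartBoundaryMask(sil, computePartCuts(sil, integer(0)))
  expect_equal(roiArea(empty), 0L)
  # synthetic interior chord far from the boundary: area ~ L * 2b
  cuts <- data.frame(x1 = 320, y1 = 400, x2 = 380, y2 = 400)
  band <- buildPartBoundaryMask(sil, cuts, bandPx = 8)
  expect_equal(roiArea(band), 60 * 16, tolerance = 0.15)
  # clipping contract: band never leaves the silhouette
  cuts2 <- computePartCuts(sil, detectConcavityExtrema(dumbbellCurvature()))
  band2 <- buildPartBoundaryMask(sil, cuts2, bandPx = 10)
  expect_true(all(maskMatrix(band2) <= maskMatrix(sil)))
  expect_identical(roiLabel(band2), "part_boundary")
  expect_error(buildPartBoundaryMask(sil, cuts2, bandPx = 0), "bandPx")
})

test_that("cut tables export to CSV", {
  shp <- dumbbellShape()
  sil <- silhouette(shp)
  cuts <- computePartCuts(sil, detectConcavityExtrema(dumbbellCurvature()))
  p <- tempfile(fileext = ".csv")
  writeCutsCSV(cuts, p)
  back <- read.csv(p)
  expect_named(back, c("cut_id", "x1", "y1", "x2", "y2", "length_px"))
  expect_equal(nrow(back), nrow(cuts))
})
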