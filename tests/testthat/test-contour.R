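test_that("a traced disc has the circumference of its circle", {
  sil <- circleSilhouette()
  expect_equal(nrow(contourPoints(sil)), 2 * pi * 100, tolerance = 0.02)
  # canonical orientation: positive signed area in the y-up frame
  expect_gt(froa:::.signedAreaYUp(contourPoints(sil), 256), 0)
})

test_that("a 10x10 pixel square traces to its pixel-centre perimeter", {
  sq <- matrix(0L, 64, 64)
  sq[21:30, 21:30] <- 1L
  sil <- extractContour(sq)
  expect_lte(abs(nrow(contourPoints(sil)) - 36), 2)
})

test_that("defective masks are rejected with a named defect", {
  two <- matrix(0L, 128, 128)
  two[10:40, 10:40] <- 1L
  two[80:110, 80:110] <- 1L
  expect_error(extractContour(two), "component")
  holey <- discMask(128, c(63, 63), 40)
  holey[60:66, 60:66] <- 0L
  expect_error(extractContour(holey), "hole")
  expect_error(extractContour(matrix(0L, 64, 64)), "area")
})

test_that("circle curvature is +1/r at every sample", {
  k <- curvatureValues(computeCurvature(circleSilhouette()))
  expect_lt(max(abs(k - 0.01)) / 0.01, 0.10)
})

test_that("curvature is scale covariant (kappa ~ 1/s)", {
  k100 <- curvatureValues(computeCurvature(circleSilhouette()))
  k50 <- curvatureValues(computeCurvature(circle50Silhouette()))
  expect_equal(median(k50) / median(k100), 2, tolerance = 0.10)
  expect_lt(max(abs(k50 - 0.02)) / 0.02, 0.10)
})

test_that("straight segments have near-zero curvature", {
  big <- matrix(0L, 400, 400)
  big[101:300, 101:300] <- 1L
  sil <- extractContour(big)
  p <- contourPoints(sil)
  k <- curvatureValues(computeCurvature(sil))
  mid <- abs(p[, 2] - 200) < 5 & p[, 1] < 150  # left side midpoints
  expect_true(any(mid))
  expect_lt(max(abs(k[mid])), 0.002)
})

test_that("the dumbbell neck is concave", {
  shp <- dumbbellShape()
  p <- contourPoints(silhouette(shp))
  k <- curvatureValues(dumbbellCurvature())
  neck <- abs(p[, 1] - 400) < 4  # samples near the junction plane
  expect_true(any(k[neck] < 0))
  expect_lt(min(k[neck]), -0.01)
})

test_that("curvature is unchanged by traversal direction after canonicalisation", {
  sil <- circleSilhouette()
  ct <- contourPoints(sil)
  rev_ct <- ct[rev(seq_len(nrow(ct))), ]
  # reversed contour violates the orientation invariant...
  expect_error(new("Silhouette", mask = maskMatrix(sil), contour = rev_ct),
               "orientation")
  # ...and re-canonicalising restores the identical sample sequence
  again <- rev_ct[rev(seq_len(nrow(rev_ct))), ]
  expect_identical(again, ct)
})

test_that("degenerate curvature inputs error", {
  expect_error(computeCurvature(circleSilhouette(), smoothingSigma = 0.5),
               "smoothingSigma")
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  short <- new("Silhouette", mask = discMask(64, c(31, 31), 20),
               contour = cbind(x = 31 + 2 * cos(th),
                               y = 63 - (31 + 2 * sin(th))))
  expect_error(computeCurvature(short), "fewer than 20")
})

test_that("mask PNG round trip preserves the pixel grid", {
  m <- discMask(128, c(63, 63), 40)
  p <- tempfile(fileext = ".png")
  writeMaskPNG(m, p)
  expect_identical(readMaskPNG(p), m)
})
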