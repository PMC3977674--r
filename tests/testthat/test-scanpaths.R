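test_that("degenerate mixtures put every non-initial fixation in the ROI", {
  shp <- dumbbellShape()
  roi <- concaveRoiOf(shp)
  fx <- fixations(generateScanpath(shp, roi,
                                   scanPathConfig(nFixations = 200,
                                                  roiPreference = 1,
                                                  seed = 5)))
  expect_equal(nrow(fx), 200L)
  expect_equal(unname(unlist(fx[1, c("x_px", "y_px")])), c(399.5, 399.5))
  inroi <- froa:::.insideMask(maskMatrix(roi), fx$x_px[-1], fx$y_px[-1])
  expect_true(all(inroi))
})

test_that("a pure uniform-frame null hits an ROI by its area share", {
  shp <- dumbbellShape()
  roi <- matrix(0L, 800, 800)
  roi[1:400, 1:400] <- 1L  # 25% of the frame
  n <- 4000
  fx <- fixations(generateScanpath(
    shp, NULL, scanPathConfig(nFixations = n + 1, roiPreference = 0,
                              nullDensity = "uniform_frame", seed = 6)))
  frac <- mean(froa:::.insideMask(roi, fx$x_px[-1], fx$y_px[-1]))
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("mixture hit rates follow pi + (1 - pi) * area share", {
  shp <- dumbbellShape()
  roi <- matrix(0L, 800, 800)
  roi[1:400, 1:400] <- 1L
  for (p in c(0.3, 0.7)) {
    fx <- fixations(generateScanpath(
      shp, roiMask(roi), scanPathConfig(nFixations = 3001,
                                        roiPreference = p,
                                        nullDensity = "uniform_frame",
                                        seed = 9)))
    expected <- p + (1 - p) * 0.25
    frac <- mean(froa:::.insideMask(roi, fx$x_px[-1], fx$y_px[-1]))
    expect_lt(abs(frac - expected),
              4 * sqrt(expected * (1 - expected) / 3000))
  }
})

test_that("step mode reproduces a commanded mean saccade amplitude", {
  shp <- dumbbellShape()
  geom <- viewingGeometry()
  fx <- fixations(generateScanpath(
    shp, NULL, scanPathConfig(nFixations = 1001, stepMean = 3.64,
                              stepShape = (3.64 / 1.71)^2, seed = 11),
    geometry = geom))
  amp <- sqrt(diff(fx$x_px)^2 + diff(fx$y_px)^2) / pxPerDeg(geom)
  expect_equal(mean(amp), 3.64, tolerance = 0.05)
})

test_that("durations are gamma with the configured mean", {
  shp <- dumbbellShape()
  n <- 2000
  fx <- fixations(generateScanpath(
    shp, NULL, scanPathConfig(nFixations = n, roiPreference = 0,
                              durationMean = 198, durationShape = 18,
                              seed = 21)))
  se <- 198 / sqrt(18) / sqrt(n)
  expect_lt(abs(mean(fx$duration_ms) - 198), 2 * se)
  expect_true(all(fx$duration_ms > 0))
})

test_that("every fixation lies inside the frame for any seed", {
  shp <- dumbbellShape()
  roi <- concaveRoiOf(shp)
  for (s in 1:5) {
    fx <- fixations(generateScanpath(
      shp, roi, scanPathConfig(nFixations = 50, roiPreference = 0.5,
                               seed = s)))
    expect_true(all(fx$x_px >= 0 & fx$x_px <= 799))
    expect_true(all(fx$y_px >= 0 & fx$y_px <= 799))
    fx2 <- fixations(generateScanpath(
      shp, NULL, scanPathConfig(nFixations = 50, stepMean = 6,
                                seed = s)))
    expect_true(all(fx2$x_px >= 0 & fx2$x_px <= 799))
    expect_true(all(fx2$y_px >= 0 & fx2$y_px <= 799))
  }
})

test_that("scanpath generation is deterministic and validates inputs", {
  shp <- dumbbellShape()
  roi <- concaveRoiOf(shp)
  cfg <- scanPathConfig(nFixations = 30, roiPreference = 0.4, seed = 2)
  a <- fixations(generateScanpath(shp, roi, cfg))
  b <- fixations(generateScanpath(shp, roi, cfg))
  expect_identical(a, b)
  empty <- matrix(0L, 800, 800)
  expect_error(generateScanpath(shp, empty,
                                scanPathConfig(roiPreference = 0.5)),
               "non-empty")
  expect_error(scanPathConfig(roiPreference = 1.5), "roiPreference")
  expect_error(scanPathConfig(stepMean = -1), "stepMean")
  expect_error(scanPathConfig(durationMean = 0), "durationMean")
})
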