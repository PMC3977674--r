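test_that("fixation-region maps are disk unions with the right area", {
  geom <- viewingGeometry()
  fm <- fixationRegionMap(data.frame(x_px = 400, y_px = 400), geom, 1)
  expect_equal(sum(maskMatrix(fm)), pi * (800 / 18)^2, tolerance = 0.05)
  two <- fixationRegionMap(data.frame(x_px = c(400, 400),
                                      y_px = c(400, 400)), geom, 1)
  expect_identical(maskMatrix(two), maskMatrix(fm))  # union idempotence
  small <- fixationRegionMap(data.frame(x_px = 400, y_px = 400), geom, 0.5)
  expect_lt(sum(maskMatrix(small)), sum(maskMatrix(fm)))
  expect_error(fixationRegionMap(data.frame(x_px = numeric(0),
                                            y_px = numeric(0)), geom),
               "at least one")
})

test_that("overlap percentages follow set relations", {
  geom <- viewingGeometry()
  fm <- fixationRegionMap(data.frame(x_px = 400, y_px = 400), geom, 1)
  full <- matrix(1L, 800, 800)
  none <- matrix(0L, 800, 800)
  expect_equal(overlapPercent(fm, full), 100)
  expect_equal(overlapPercent(fm, none), 0)
  half <- matrix(0L, 800, 800)
  half[1:400, ] <- 1L  # half-plane through the disk centre
  expect_equal(overlapPercent(fm, half), 50, tolerance = 0.04)
  expect_error(overlapPercent(fm, matrix(1L, 10, 10)), "dimensions")
  expect_error(overlapPercent(matrix(0L, 800, 800), full), "empty")
})

test_that("point-fixation overlap equals brute-force pixel intersection", {
  geom <- viewingGeometry(16L, 18)
  set.seed(7)
  for (i in 1:30) {
    n <- sample(1:6, 1)
    fx <- data.frame(x_px = sample(0:15, n, replace = TRUE),
                     y_px = sample(0:15, n, replace = TRUE))
    roi <- matrix(rbinom(256, 1, 0.4), 16, 16)
    o <- overlapPercent(fixationRegionMap(fx, geom, 0), roi)
    pix <- unique(paste(fx$x_px, fx$y_px))
    hits <- sum(vapply(strsplit(pix, " "), function(p) {
      roi[as.integer(p[1]) + 1L, as.integer(p[2]) + 1L] > 0
    }, logical(1)))
    expect_equal(o, 100 * hits / length(pix))
  }
})

test_that("chance distributions behave at the extremes", {
  geom <- viewingGeometry(100L, 18)
  full <- roiMask(matrix(1L, 100, 100))
  cd <- chanceDistribution(3, full, "uniform_frame", geom, 0.5, 100, 1)
  expect_true(all(chanceOverlaps(cd) == 100))
  expect_equal(chanceBound(cd), 100)
  none <- roiMask(matrix(0L, 100, 100))
  cd0 <- chanceDistribution(3, none, "uniform_frame", geom, 0.5, 100, 1)
  expect_true(all(chanceOverlaps(cd0) == 0))
  expect_error(chanceDistribution(3, full, "uniform_frame", geom, 0.5,
                                  50, 1), "nIterations")
  expect_error(chanceDistribution(3, roiMask(matrix(1L, 100, 100)),
                                  matrix(0, 100, 100), geom, 0.5, 100, 1),
               "zero mass")
  neg <- matrix(1, 100, 100); neg[1, 1] <- -1
  expect_error(chanceDistribution(3, full, neg, geom, 0.5, 100, 1),
               "negative")
})

test_that("uniform nulls give the analytic expected overlap for points", {
  geom <- viewingGeometry()
  roi <- matrix(0L, 800, 800)
  roi[1:400, 1:400] <- 1L
  means <- vapply(1:4, function(s) {
    cd <- chanceDistribution(1, roiMask(roi), "uniform_frame", geom,
                             regionRadiusDeg = 0, nIterations = 1000,
                             seed = s)
    mean(chanceOverlaps(cd))
  }, numeric(1))
  expect_lt(abs(mean(means) - 25), 3)
})

test_that("chance bounds are reproducible and seed-stable", {
  geom <- viewingGeometry(200L, 18)
  roi <- roiMask(discMask(200, c(99, 99), 56))
  a <- chanceDistribution(10, roi, "uniform_frame", geom, 0.5, 500, 42)
  b <- chanceDistribution(10, roi, "uniform_frame", geom, 0.5, 500, 42)
  expect_identical(chanceOverlaps(a), chanceOverlaps(b))
  c <- chanceDistribution(10, roi, "uniform_frame", geom, 0.5, 1000, 43)
  d <- chanceDistribution(10, roi, "uniform_frame", geom, 0.5, 1000, 44)
  expect_lt(abs(chanceBound(c) - chanceBound(d)), 2)
})

test_that("the MMC statistic is the observed overlap minus the bound", {
  geom <- viewingGeometry(100L, 18)
  none <- roiMask(matrix(0L, 100, 100))
  cd0 <- chanceDistribution(3, none, "uniform_frame", geom, 0.5, 100, 1)
  r <- mmcStatistic(30, cd0)
  expect_equal(mmcValue(r), 30)
  r0 <- mmcStatistic(chanceBound(cd0), cd0)
  expect_equal(mmcValue(r0), 0)
  expect_equal(mmcValue(r), observedOverlap(r) - chanceBound(r))
})

test_that("saliency maps are normalised densities shaped by contrast", {
  gray <- matrix(0.5, 128, 128)
  d <- saliencyMap(gray)
  expect_equal(sum(d), 1, tolerance = 1e-9)
  expect_lt(max(d) / min(d), 1.5)
  img <- matrix(0, 128, 128)
  img[froa::discMask(128, c(63, 63), 15) > 0] <- 1
  d2 <- saliencyMap(img)
  expect_equal(sum(d2), 1, tolerance = 1e-9)
  near <- discMask(128, c(63, 63), 30)  # within two disk radii
  expect_gte(sum(d2[near > 0]), 0.6)
  expect_true(all(d2 >= 0))
})

test_that("runFroa produces one row per participant and model", {
  shp <- dumbbellShape()
  sil <- silhouette(shp)
  pm <- buildPolarityMasks(computeCurvature(sil), sil)
  cuts <- computePartCuts(sil, detectConcavityExtrema(computeCurvature(sil)))
  models <- list(s1 = list(concave = pm$concave, convex = pm$convex,
                           part_boundary = buildPartBoundaryMask(sil, cuts)))
  rec <- do.call(rbind, lapply(sprintf("p%02d", 1:12), function(p) {
    fx <- fixations(generateScanpath(
      shp, pm$concave, scanPathConfig(nFixations = 9, roiPreference = 0.7,
                                      seed = utf8ToInt(substr(p, 3, 3)) +
                                        13 * utf8ToInt(substr(p, 2, 2)))))
    data.frame(participant = p, group = "a", trial = 1L, stimulus = "s1",
               fix_index = seq_len(nrow(fx)), x_px = fx$x_px,
               y_px = fx$y_px, duration_ms = fx$duration_ms)
  }))
  rec <- preprocessFixations(rec)
  tab <- runFroa(rec, list(s1 = sil), models, nIterations = 100, seed = 5)
  expect_equal(nrow(tab), 36L)
  expect_setequal(unique(tab$model),
                  c("concave", "convex", "part_boundary"))
  expect_error(runFroa(rec, list(s1 = sil), list(other = models$s1),
                       nIterations = 100, seed = 5), "s1")
})
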