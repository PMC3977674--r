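test_that("well-formed fixation tables round trip", {
  p <- writeFixationCSV(simpleFixations())
  tab <- readFixations(p)
  expect_equal(nrow(tab), 3L)
  expect_type(tab$x_px, "double")
  expect_type(tab$fix_index, "integer")
})

test_that("malformed tables fail with the offending row or column named", {
  bad <- simpleFixations()
  bad$x_px[2] <- "NA"
  expect_error(readFixations(writeFixationCSV(bad)), "row 2")
  expect_error(readFixations(writeFixationCSV(simpleFixations()[, -7])),
               "y_px")
  mono <- simpleFixations()
  mono$fix_index <- c(1L, 3L, 2L)
  expect_error(readFixations(writeFixationCSV(mono)), "strictly increasing")
  neg <- simpleFixations()
  neg$duration_ms[3] <- -5
  expect_error(readFixations(writeFixationCSV(neg)), "duration")
})

test_that("an empty table is readable with a warning", {
  p <- writeFixationCSV(simpleFixations()[0, ])
  expect_warning(tab <- readFixations(p), "empty")
  expect_equal(nrow(tab), 0L)
})

test_that("preprocessing discards first fixations and out-of-frame fixations", {
  fx <- do.call(rbind, lapply(1:3, function(tr) {
    data.frame(participant = "p01", group = "a", trial = tr,
               stimulus = "s1", fix_index = 1:7,
               x_px = c(400, 100, 900, 300, 420, 80, 640),
               y_px = 400, duration_ms = 200)
  }))
  fx$x_px[fx$trial == 2] <- c(400, 120, 220, 320, 420, 520, 620)
  out <- preprocessFixations(fx)
  expect_equal(attr(out, "nFirstDiscarded"), 3L)
  expect_equal(attr(out, "nOutOfFrame"), 2L)  # the two 900-px fixations
  expect_equal(nrow(out), nrow(fx) - 3L - 2L)
  expect_false(any(out$fix_index == 1L))
})

test_that("trials emptied by preprocessing are flagged", {
  fx <- data.frame(participant = c("p01", "p01"), group = "a",
                   trial = c(1L, 2L), stimulus = "s1", fix_index = 1L,
                   x_px = 100, y_px = 100, duration_ms = 150)
  fx <- rbind(fx, data.frame(participant = "p01", group = "a", trial = 2L,
                             stimulus = "s1", fix_index = 2L, x_px = 200,
                             y_px = 200, duration_ms = 150))
  out <- preprocessFixations(fx)
  flagged <- attr(out, "flaggedTrials")
  expect_equal(flagged$trial, 1L)  # single-fixation trial ends up empty
  expect_equal(nrow(out), 1L)
})

test_that("saccade amplitudes convert px to degrees and respect trials", {
  geom <- viewingGeometry()
  fx <- data.frame(participant = "p01", group = "a",
                   trial = c(1L, 1L, 2L, 2L), stimulus = "s1",
                   fix_index = c(2L, 3L, 2L, 3L),
                   x_px = c(0, 800 / 18, 100, 100),
                   y_px = c(0, 0, 100, 100 + 2 * 800 / 18),
                   duration_ms = 100)
  amps <- saccadeAmplitudes(fx, geom)
  expect_equal(amps$mean_amplitude_deg, 1.5)  # (1 deg + 2 deg) / 2
  expect_equal(amps$n_saccades, 2L)
  # scaling the subtended angle scales amplitudes linearly
  amps2 <- saccadeAmplitudes(fx, viewingGeometry(800L, 36))
  expect_equal(amps2$mean_amplitude_deg, 3)
})

test_that("participants without saccades are excluded with a warning", {
  fx <- data.frame(participant = c("p01", "p02", "p02"), group = "a",
                   trial = 1L, stimulus = "s1", fix_index = c(2L, 2L, 3L),
                   x_px = c(10, 10, 30), y_px = 10, duration_ms = 100)
  expect_warning(amps <- saccadeAmplitudes(fx), "p01")
  expect_equal(amps$participant, "p02")
})

test_that("dwell times are per-participant duration means", {
  fx <- data.frame(participant = c("p01", "p01", "p02"), group = "a",
                   trial = 1L, stimulus = "s1", fix_index = c(2L, 3L, 2L),
                   x_px = 10, y_px = 10, duration_ms = c(100, 300, 250))
  dw <- dwellTimes(fx)
  expect_equal(dw$mean_dwell_ms, c(200, 250))
  p <- tempfile(fileext = ".csv")
  writeMetricsCSV(suppressWarnings(saccadeAmplitudes(fx)), dw, p)
  out <- read.csv(p)
  expect_named(out, c("participant", "group", "mean_amplitude_deg",
                      "mean_dwell_ms", "n_saccades"))
})

test_that("dwell estimates recover the generator duration mean", {
  shp <- dumbbellShape()
  fx <- fixations(generateScanpath(
    shp, NULL, scanPathConfig(nFixations = 2000, roiPreference = 0,
                              durationMean = 198, durationShape = 18,
                              seed = 31)))
  rec <- data.frame(participant = "p01", group = "a", trial = 1L,
                    stimulus = "s1", fix_index = seq_len(nrow(fx)),
                    x_px = fx$x_px, y_px = fx$y_px,
                    duration_ms = fx$duration_ms)
  dw <- dwellTimes(preprocessFixations(rec))
  se <- 198 / sqrt(18) / sqrt(2000)
  expect_lt(abs(dw$mean_dwell_ms - 198), 2.5 * se)
})
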