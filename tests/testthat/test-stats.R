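test_that("split-plot ANOVA matches the brute-force sums of squares", {
  d <- fixed2x3Data()
  an <- mixedAnova(d)
  d$y <- d$mmc
  o <- bruteSplitPlot(d)
  got <- an$SS
  want <- c(o$SSg, o$SSsub, o$SSm, o$SSgm, o$SSwe)
  expect_lt(max(abs(got - want) / pmax(abs(want), 1e-12)), 1e-8)
  # F and partial eta^2 from the same identities
  expect_equal(an$F[3], (o$SSm / 2) / (o$SSwe / an$df[5]), tolerance = 1e-8)
  expect_equal(an$pes[3], o$SSm / (o$SSm + o$SSwe), tolerance = 1e-10)
  # SS decomposition: effects + errors add to the total
  expect_equal(sum(an$SS), sum((d$y - mean(d$y))^2), tolerance = 1e-8)
})

test_that("ANOVA is invariant to relabeling and constant shifts", {
  d <- fixed2x3Data()
  an <- mixedAnova(d)
  d2 <- d
  d2$participant <- factor(d2$participant,
                           labels = sample(LETTERS[1:8]))
  d2$mmc <- d2$mmc + 100
  an2 <- mixedAnova(d2)
  expect_equal(an$F, an2$F, tolerance = 1e-10)
  expect_equal(an$SS, an2$SS, tolerance = 1e-8)
})

test_that("degenerate ANOVA inputs follow the documented conventions", {
  d <- fixed2x3Data()
  d$mmc <- 7
  an <- mixedAnova(d)
  expect_true(all(an$F[c(1, 3, 4)] == 0))
  expect_true(all(an$p[c(1, 3, 4)] == 1))
  shift <- fixed2x3Data()
  shift$mmc <- ifelse(shift$group == "basic", 5, 1)  # pure group shift
  an2 <- mixedAnova(shift)
  expect_gt(an2$F[1], 0)
  expect_equal(an2$F[3], 0)
  miss <- fixed2x3Data()[-1, ]
  expect_error(mixedAnova(miss), "balanced")
})

test_that("planned comparisons match the textbook t formulas", {
  d <- fixed2x3Data()
  pc <- plannedComparisons(d)
  expect_equal(nrow(pc), 9L)  # 3 paired per group + 3 between
  x <- d$mmc[d$group == "basic" & d$model == "concave"]
  y <- d$mmc[d$group == "basic" & d$model == "convex"]
  x <- x[order(d$participant[d$group == "basic" & d$model == "concave"])]
  y <- y[order(d$participant[d$group == "basic" & d$model == "convex"])]
  dd <- x - y
  tHand <- mean(dd) / (sd(dd) / sqrt(length(dd)))
  got <- pc$statistic[pc$contrast == "basic: concave vs convex (paired)"]
  expect_equal(got, tHand, tolerance = 1e-10)
  pHand <- 2 * pt(-abs(tHand), length(dd) - 1)
  expect_equal(pc$p[pc$contrast == "basic: concave vs convex (paired)"],
               pHand, tolerance = 1e-10)
})

test_that("degenerate comparisons are flagged, not mangled", {
  d <- expand.grid(participant = sprintf("s%d", 1:4),
                   model = c("A", "B"))
  d$group <- "g1"
  d$mmc <- ifelse(d$model == "A", 5, 5)
  pc <- plannedComparisons(d)
  expect_equal(pc$statistic[1], 0)
  expect_equal(pc$p[1], 1)
  d$mmc <- ifelse(d$model == "A", 6, 5)  # constant non-zero difference
  pc2 <- plannedComparisons(d)
  expect_true(is.infinite(pc2$statistic[1]))
  expect_equal(pc2$p[1], 0)
  expect_true(pc2$degenerate[1])
})

test_that("two-sample t and Mann-Whitney follow their exact references", {
  same <- data.frame(group = rep(c("a", "b"), each = 4),
                     mean_amplitude_deg = rep(c(1, 2, 3, 4), 2))
  tt <- twoSampleTests(same)
  expect_equal(tt$statistic[1], 0)
  sep <- data.frame(group = rep(c("a", "b"), each = 3), acc = c(1, 2, 3, 4, 5, 6))
  mw <- mannWhitneyExact(sep$acc[1:3], sep$acc[4:6], "less")
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / choose(6, 3))
  # full-enumeration oracle for n <= 8 per group
  set.seed(5)
  x <- rnorm(5); y <- rnorm(6) + 0.8
  mwx <- mannWhitneyExact(x, y, "less")
  ranks <- rank(c(x, y))
  Uobs <- sum(ranks[1:5]) - 5 * 6 / 2
  combos <- combn(11, 5)
  Uall <- apply(combos, 2, function(ix) sum(rank(c(x, y))[ix]) - 15)
  expect_equal(mwx$U, Uobs)
  expect_equal(mwx$p, mean(Uall <= Uobs))
  expect_error(twoSampleTests(data.frame(group = c("a", "b"),
                                         mean_amplitude_deg = c(1, 2))),
               "n >= 2")
})
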