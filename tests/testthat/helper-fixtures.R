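# Shared fixtures, built in code and memoised so expensive geometry is
# computed once per test run.

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureEnv)) {
    assign(name, builder(), envir = .fixtureEnv)
  }
  get(name, envir = .fixtureEnv)
}

circleSilhouette <- function() {
  fixture("circle100", function() extractContour(discMask(256, c(127, 127), 100)))
}

circle50Silhouette <- function() {
  fixture("circle50", function() extractContour(discMask(160, c(79, 79), 50)))
}

dumbbellShape <- function() {
  # two discs r = 60 px, centres 100 px apart: junction chord
  # 2 * sqrt(60^2 - 50^2) = 66.33 px by circle-circle intersection
  fixture("dumbbell6060", function() {
    generateShape(list(partPrimitive("ellipse", c(350, 400), c(60, 60)),
                       partPrimitive("ellipse", c(450, 400), c(60, 60))),
                  seed = 3, familyId = "dumbbell-test")
  })
}

dumbbellCurvature <- function() {
  fixture("dumbbellCurv", function() computeCurvature(silhouette(dumbbellShape())))
}

chain3Shape <- function() {
  fixture("chain3", function() generateShape("chain3", seed = 11))
}

concaveRoiOf <- function(shape) {
  sil <- silhouette(shape)
  buildPolarityMasks(computeCurvature(sil), sil)$concave
}

writeFixationCSV <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

simpleFixations <- function() {
  data.frame(participant = "p01", group = "a", trial = 1L,
             stimulus = "s1", fix_index = 1:3,
             x_px = c(400, 100, 200), y_px = c(400, 150, 250),
             duration_ms = c(180, 220, 240))
}

# Match a true junction chord against a computed cut table: TRUE when some
# cut has both endpoints within tol px of the chord endpoints (either
# pairing order).
cutMatches <- function(cuts, chord, tol = 10) {
  a <- chord[1:2]; b <- chord[3:4]
  for (j in seq_len(NROW(cuts))) {
    p1 <- c(cuts$x1[j], cuts$y1[j])
    p2 <- c(cuts$x2[j], cuts$y2[j])
    d <- min(max(sqrt(sum((p1 - a)^2)), sqrt(sum((p2 - b)^2))),
             max(sqrt(sum((p1 - b)^2)), sqrt(sum((p2 - a)^2))))
    if (d <= tol) return(TRUE)
  }
  FALSE
}
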