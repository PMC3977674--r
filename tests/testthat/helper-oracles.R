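# Independent statistics oracles, coded from the cell-mean identities
# rather than via any model-fitting routine.

bruteSplitPlot <- function(d) {
  gm <- mean(d$y)
  a <- length(unique(d$group))
  b <- length(unique(d$model))
  n <- length(unique(d$participant)) / a
  Ai <- tapply(d$y, d$group, mean)
  Bj <- tapply(d$y, d$model, mean)
  ABij <- tapply(d$y, list(d$group, d$model), mean)
  Sk <- tapply(d$y, d$participant, mean)
  grp <- tapply(as.character(d$group), d$participant, `[`, 1L)
  SSg <- b * n * sum((Ai - gm)^2)
  SSm <- a * n * sum((Bj - gm)^2)
  SSgm <- n * sum((ABij - outer(Ai - gm, Bj - gm, "+") - gm)^2)
  SSsub <- b * sum((Sk - Ai[grp])^2)
  SSwe <- sum((d$y - gm)^2) - SSg - SSm - SSgm - SSsub
  list(SSg = SSg, SSsub = SSsub, SSm = SSm, SSgm = SSgm, SSwe = SSwe)
}

fixed2x3Data <- function(nPer = 4) {
  set.seed(2026)
  d <- expand.grid(participant = sprintf("s%02d", seq_len(2 * nPer)),
                   model = c("concave", "convex", "part_boundary"))
  d$group <- ifelse(as.integer(sub("s", "", d$participant)) <= nPer,
                    "basic", "subordinate")
  eff <- c(concave = 8, convex = -4, part_boundary = 3)
  d$mmc <- eff[as.character(d$model)] +
    ifelse(d$group == "basic", 1.5, 0) + rnorm(nrow(d), sd = 2)
  d
}
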