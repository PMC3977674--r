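#' Split-plot (mixed) ANOVA on MMC values
#'
#' A 2 (task group, between subjects) x 3 (ROI model, within subjects)
#' split-plot decomposition: the group effect is tested against subjects
#' within groups, the model and group x model effects against the
#' model x subjects-within-groups error. Partial eta squared is
#' SS_effect / (SS_effect + SS_error-of-its-stratum). Only balanced
#' complete designs are accepted (every participant contributes every
#' model level; equal group sizes are not required, but missing cells
#' are an error). No sphericity correction is applied by default; with
#' three within levels and planned contrasts this matches common
#' reporting practice. Greenhouse-Geisser-corrected p-values are
#' available on request.
#'
#' The zero-variance convention: an effect with (numerically) zero sum of
#' squares is reported as F = 0, p = 1; a positive effect over a zero
#' error stratum as F = Inf, p = 0.
#'
#' @param mmcTable long data.frame with columns \code{participant},
#'   \code{group}, \code{model} and a response column.
#' @param response name of the response column (default \code{"mmc"}).
#' @param ggCorrection apply the Greenhouse-Geisser epsilon to the
#'   within-subject p-values.
#' @return data.frame \code{effect, SS, df, MS, F, p, pes} with rows
#'   group, model, group:model and the two error strata.
#' @examples
#' tab <- expand.grid(participant = paste0("p", 1:6),
#'                    model = c("concave", "convex", "part_boundary"))
#' tab$group <- ifelse(tab$participant %in% paste0("p", 1:3), "a", "b")
#' tab$mmc <- rnorm(nrow(tab))
#' mixedAnova(tab)
#' @importFrom stats aov pf var
#' @export
mixedAnova <- function(mmcTable, response = "mmc", ggCorrection = FALSE) {
  need <- c("participant", "group", "model", response)
  if (!all(need %in% names(mmcTable))) {
    stop("mmcTable needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d <- data.frame(participant = factor(mmcTable$participant),
                  group = factor(mmcTable$group),
                  model = factor(mmcTable$model),
                  y = mmcTable[[response]])
  counts <- table(d$participant, d$model)
  if (any(counts != 1L)) {
    stop("design is not balanced/complete: every participant needs ",
         "exactly one value per model level", call. = FALSE)
  }
  gsz <- table(unique(d[, c("participant", "group")])$group)
  if (any(gsz < 2L)) {
    stop("each group needs >= 2 participants", call. = FALSE)
  }
  fit <- aov(y ~ group * model + Error(participant / model), data = d)
  sm <- summary(fit)
  pick <- function(stratum, term) {
    tab <- sm[[stratum]][[1L]]
    rn <- trimws(rownames(tab))
    i <- match(term, rn)
    c(SS = tab[i, "Sum Sq"], df = tab[i, "Df"])
  }
  ssG <- pick("Error: participant", "group")
  ssSe <- pick("Error: participant", "Residuals")
  ssM <- pick("Error: participant:model", "model")
  ssGM <- pick("Error: participant:model", "group:model")
  ssWe <- pick("Error: participant:model", "Residuals")

  eps <- 1
  if (ggCorrection) {
    wide <- unstack(d, y ~ model)
    S <- cov(wide)
    k <- ncol(S)
    dbar <- diag(S)
    num <- (k * (mean(diag(S)) - mean(S)))^2
    den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) +
                        k^2 * mean(S)^2)
    eps <- if (den > 0) num / den else 1
    eps <- min(max(eps, 1 / (k - 1)), 1)
  }

  row <- function(effect, ss, err, gg = FALSE) {
    MS <- ss[["SS"]] / ss[["df"]]
    MSe <- err[["SS"]] / err[["df"]]
    tol <- 1e-12 * max(1, abs(ss[["SS"]]) + abs(err[["SS"]]))
    if (ss[["SS"]] <= tol) {
      Fv <- 0; pv <- 1
    } else if (err[["SS"]] <= tol) {
      Fv <- Inf; pv <- 0
    } else {
      Fv <- MS / MSe
      e <- if (gg) eps else 1
      pv <- pf(Fv, e * ss[["df"]], e * err[["df"]], lower.tail = FALSE)
    }
    pes <- if (ss[["SS"]] + err[["SS"]] > 0) {
      ss[["SS"]] / (ss[["SS"]] + err[["SS"]])
    } else 0
    data.frame(effect = effect, SS = ss[["SS"]], df = ss[["df"]], MS = MS,
               F = Fv, p = pv, pes = pes)
  }
  out <- rbind(
    row("group", ssG, ssSe),
    data.frame(effect = "participant_within_group", SS = ssSe[["SS"]],
               df = ssSe[["df"]], MS = ssSe[["SS"]] / ssSe[["df"]],
               F = NA_real_, p = NA_real_, pes = NA_real_),
    row("model", ssM, ssWe, gg = ggCorrection),
    row("group:model", ssGM, ssWe, gg = ggCorrection),
    data.frame(effect = "model_x_participant_within_group",
               SS = ssWe[["SS"]], df = ssWe[["df"]],
               MS = ssWe[["SS"]] / ssWe[["df"]], F = NA_real_,
               p = NA_real_, pes = NA_real_))
  rownames(out) <- NULL
  out
}

# Two-sided t statistic and p by the textbook formulas, with the
# degenerate conventions documented in plannedComparisons.
#' @importFrom stats pt sd
.tResult <- function(contrast, tvalue, df) {
  p <- if (is.infinite(tvalue)) 0 else 2 * pt(-abs(tvalue), df)
  data.frame(contrast = contrast, statistic = tvalue, df = df, p = p,
             degenerate = is.infinite(tvalue) |
               (tvalue == 0 & p == 1 & df == 0))
}

.pairedT <- function(contrast, x, y) {
  d <- x - y
  n <- length(d)
  sdd <- sd(d)
  if (sdd == 0) {
    tv <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    out <- data.frame(contrast = contrast, statistic = tv, df = n - 1L,
                      p = if (tv == 0) 1 else 0, degenerate = TRUE)
    return(out)
  }
  tv <- mean(d) / (sdd / sqrt(n))
  .tResult(contrast, tv, n - 1L)
}

.indepT <- function(contrast, x, y, welch = FALSE) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    dlt <- mean(x) - mean(y)
    tv <- if (dlt == 0) 0 else sign(dlt) * Inf
    return(data.frame(contrast = contrast, statistic = tv,
                      df = nx + ny - 2L, p = if (tv == 0) 1 else 0,
                      degenerate = TRUE))
  }
  if (welch) {
    se <- sqrt(vx / nx + vy / ny)
    df <- se^4 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  .tResult(contrast, (mean(x) - mean(y)) / se, df)
}

#' Planned comparisons on the MMC table
#'
#' Within each task group, paired t-tests between every pair of ROI
#' models; between the task groups, independent t-tests on each model.
#' All p-values are two-sided and uncorrected by default (Bonferroni
#' optional). Degenerate inputs follow a documented convention: identical
#' vectors give t = 0, p = 1; a constant non-zero difference with zero
#' variance gives t = +-Inf, p = 0, flagged in the \code{degenerate}
#' column.
#'
#' @param mmcTable long data.frame \code{participant, group, model} +
#'   response.
#' @param response response column name.
#' @param bonferroni multiply p-values by the number of comparisons
#'   (capped at 1).
#' @return data.frame \code{contrast, statistic, df, p, degenerate}.
#' @export
plannedComparisons <- function(mmcTable, response = "mmc",
                               bonferroni = FALSE) {
  d <- data.frame(participant = as.character(mmcTable$participant),
                  group = as.character(mmcTable$group),
                  model = as.character(mmcTable$model),
                  y = mmcTable[[response]])
  groups <- sort(unique(d$group))
  models <- sort(unique(d$model))
  res <- list()
  for (g in groups) {
    sub <- d[d$group == g, , drop = FALSE]
    for (i in seq_along(models)) {
      for (j in seq_along(models)) {
        if (j <= i) next
        xi <- sub[sub$model == models[i], ]
        xj <- sub[sub$model == models[j], ]
        xi <- xi[order(xi$participant), ]
        xj <- xj[order(xj$participant), ]
        if (nrow(xi) < 2L || !identical(xi$participant, xj$participant)) {
          stop("need >= 2 complete participants per cell for group ", g,
               call. = FALSE)
        }
        res[[length(res) + 1L]] <- .pairedT(
          sprintf("%s: %s vs %s (paired)", g, models[i], models[j]),
          xi$y, xj$y)
      }
    }
  }
  if (length(groups) == 2L) {
    for (m in models) {
      x <- d$y[d$group == groups[1L] & d$model == m]
      y <- d$y[d$group == groups[2L] & d$model == m]
      if (length(x) < 2L || length(y) < 2L) {
        stop("need >= 2 participants per group for model ", m,
             call. = FALSE)
      }
      res[[length(res) + 1L]] <- .indepT(
        sprintf("%s: %s vs %s (independent)", m, groups[1L], groups[2L]),
        x, y)
    }
  }
  out <- do.call(rbind, res)
  if (bonferroni) {
    out$p <- pmin(1, out$p * nrow(out))
  }
  rownames(out) <- NULL
  out
}

#' Two-sample tests on per-participant scanpath metrics
#'
#' Independent-samples t-tests (pooled variance by default, Welch
#' optional) for continuous metrics such as saccade amplitude, dwell time
#' or reaction time, and an exact Mann-Whitney U for bounded accuracy
#' scores (exact permutation null when both groups have n <= 12 and no
#' ties, normal approximation otherwise). All p-values two-sided.
#'
#' @param metricsTable data.frame with a \code{group} column (exactly two
#'   levels) and the metric columns.
#' @param metrics character vector of metric column names to test with
#'   t-tests.
#' @param accuracy optional name of an accuracy column to test with
#'   Mann-Whitney.
#' @param welch use the Welch t-test.
#' @return data.frame \code{contrast, statistic, df, p, degenerate}
#'   (\code{df = NA} and \code{statistic = U} for Mann-Whitney rows).
#' @importFrom stats wilcox.test
#' @export
twoSampleTests <- function(metricsTable, metrics = "mean_amplitude_deg",
                           accuracy = NULL, welch = FALSE) {
  groups <- sort(unique(as.character(metricsTable$group)))
  if (length(groups) != 2L) {
    stop("metricsTable must contain exactly two groups", call. = FALSE)
  }
  split2 <- function(col) {
    x <- metricsTable[[col]][metricsTable$group == groups[1L]]
    y <- metricsTable[[col]][metricsTable$group == groups[2L]]
    if (length(x) < 2L || length(y) < 2L) {
      stop("each group needs n >= 2 for ", col, call. = FALSE)
    }
    list(x = x, y = y)
  }
  res <- list()
  for (m in metrics) {
    v <- split2(m)
    res[[length(res) + 1L]] <- .indepT(
      sprintf("%s: %s vs %s", m, groups[1L], groups[2L]),
      v$x, v$y, welch = welch)
  }
  if (!is.null(accuracy)) {
    v <- split2(accuracy)
    exact <- max(length(v$x), length(v$y)) <= 12 &&
      !any(duplicated(c(v$x, v$y)))
    wt <- suppressWarnings(
      wilcox.test(v$x, v$y, exact = exact, correct = !exact))
    res[[length(res) + 1L]] <- data.frame(
      contrast = sprintf("%s: %s vs %s (Mann-Whitney)", accuracy,
                         groups[1L], groups[2L]),
      statistic = unname(wt$statistic), df = NA_real_, p = wt$p.value,
      degenerate = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U with exact permutation p-value
#'
#' Thin wrapper around \code{wilcox.test} exposing the exact small-sample
#' null (full permutation distribution of U, no ties) used for accuracy
#' comparisons. One- or two-sided.
#'
#' @param x,y numeric samples.
#' @param alternative \code{"two.sided"}, \code{"less"} or
#'   \code{"greater"} (of x relative to y).
#' @return list with \code{U} (for the first sample) and \code{p}.
#' @export
mannWhitneyExact <- function(x, y,
                             alternative = c("two.sided", "less",
                                             "greater")) {
  alternative <- match.arg(alternative)
  exact <- !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Plain-text report of the group-level results
#'
#' Mirrors the conventional reporting format (F(df1, df2), partial eta
#' squared, t(df), p) for the ANOVA, the planned comparisons and the
#' scanpath-metric tests.
#'
#' @param anovaTable output of \code{\link{mixedAnova}}.
#' @param comparisons output of \code{\link{plannedComparisons}}.
#' @param metricTests output of \code{\link{twoSampleTests}} (optional).
#' @param path optional file to write to.
#' @return character vector of report lines (invisibly when writing).
#' @export
formatStatsReport <- function(anovaTable, comparisons = NULL,
                              metricTests = NULL, path = NULL) {
  fmtP <- function(p) {
    ifelse(p < 1e-4, "p < .0001", sprintf("p = %.4g", p))
  }
  lines <- c("Mixed ANOVA (between: group; within: model)")
  errw <- anovaTable[anovaTable$effect ==
                       "model_x_participant_within_group", ]
  errb <- anovaTable[anovaTable$effect == "participant_within_group", ]
  for (eff in c("group", "model", "group:model")) {
    r <- anovaTable[anovaTable$effect == eff, ]
    dfe <- if (eff == "group") errb$df else errw$df
    lines <- c(lines, sprintf(
      "  %s: F(%d, %d) = %.2f, %s, pes = %.3f", eff, r$df, dfe, r$F,
      fmtP(r$p), r$pes))
  }
  if (!is.null(comparisons)) {
    lines <- c(lines, "Planned comparisons")
    lines <- c(lines, sprintf("  %s: t(%g) = %.3f, %s",
                              comparisons$contrast, comparisons$df,
                              comparisons$statistic, fmtP(comparisons$p)))
  }
  if (!is.null(metricTests)) {
    lines <- c(lines, "Scanpath metrics")
    lines <- c(lines, sprintf("  %s: %s(%s) = %.3f, %s",
                              metricTests$contrast,
                              ifelse(is.na(metricTests$df), "U", "t"),
                              ifelse(is.na(metricTests$df), "",
                                     format(metricTests$df, digits = 4)),
                              metricTests$statistic, fmtP(metricTests$p)))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
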