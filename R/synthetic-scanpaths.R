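#' Configuration of the synthetic scanpath generator
#'
#' Two location models are available. In the default \emph{mixture} mode
#' (when \code{stepMean} is \code{NA}), each non-initial fixation lands
#' uniformly inside the target ROI with probability \code{roiPreference},
#' and otherwise is drawn from the null density (\code{uniform_frame},
#' \code{uniform_object}, or a supplied density map). In \emph{step} mode
#' (\code{stepMean} set, in degrees of visual angle), fixations follow a
#' random walk whose step lengths are gamma-distributed with the given
#' mean and shape and whose directions are uniform, with directions
#' resampled so the walk stays inside the frame. Fixation durations are
#' always i.i.d. gamma with mean \code{durationMean} ms and shape
#' \code{durationShape}. The first fixation of every scanpath is pinned to
#' the frame centre, mimicking central fixation at trial onset (and giving
#' the first-fixation discard a deterministic effect).
#'
#' Default durations (mean 198 ms, shape 18) give a fixation-duration
#' spread typical of object-viewing data (SD ~ 46 ms).
#'
#' @param nFixations number of fixations per scanpath (>= 1).
#' @param roiPreference mixture weight pi in [0, 1] toward the target ROI.
#' @param nullDensity \code{"uniform_frame"}, \code{"uniform_object"},
#'   \code{"saliency"} or \code{"custom"} (the latter two require a
#'   density map at generation time).
#' @param stepMean mean step length in degrees (NA = mixture mode).
#' @param stepShape gamma shape of the step-length distribution.
#' @param durationMean mean fixation duration (ms).
#' @param durationShape gamma shape of the duration distribution.
#' @param seed integer seed.
#' @return a list of class \code{ScanPathConfig}.
#' @export
scanPathConfig <- function(nFixations = 20L, roiPreference = 0,
                           nullDensity = c("uniform_object",
                                           "uniform_frame", "saliency",
                                           "custom"),
                           stepMean = NA_real_, stepShape = 4,
                           durationMean = 198, durationShape = 18,
                           seed = 1L) {
  nullDensity <- match.arg(nullDensity)
  if (!.isCount(nFixations) || nFixations < 1) {
    stop("nFixations must be a positive count", call. = FALSE)
  }
  if (roiPreference < 0 || roiPreference > 1) {
    stop("roiPreference must be in [0, 1]", call. = FALSE)
  }
  if (!is.na(stepMean) && stepMean <= 0) {
    stop("stepMean must be > 0", call. = FALSE)
  }
  if (durationMean <= 0 || durationShape <= 0 || stepShape <= 0) {
    stop("durationMean, durationShape and stepShape must be > 0",
         call. = FALSE)
  }
  structure(list(nFixations = as.integer(nFixations),
                 roiPreference = roiPreference, nullDensity = nullDensity,
                 stepMean = stepMean, stepShape = stepShape,
                 durationMean = durationMean,
                 durationShape = durationShape,
                 seed = as.integer(seed)),
            class = "ScanPathConfig")
}

# Draw n locations (0-based px) from a pixel density: NULL = uniform over
# the frame (continuous); a mask/weight matrix = sample a pixel by weight
# then jitter uniformly within the pixel.
.sampleLocations <- function(n, framePx, weights = NULL) {
  if (n == 0L) {
    return(cbind(x = numeric(0), y = numeric(0)))
  }
  if (is.null(weights)) {
    return(cbind(x = runif(n, 0, framePx) - 0.5,
                 y = runif(n, 0, framePx) - 0.5))
  }
  w <- as.vector(weights)
  if (all(w <= 0)) {
    stop("null density has zero mass", call. = FALSE)
  }
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  W <- nrow(weights)
  cbind(x = ((idx - 1L) %% W) + runif(n, -0.5, 0.5),
        y = ((idx - 1L) %/% W) + runif(n, -0.5, 0.5))
}

#' Generate one synthetic scanpath
#'
#' @param shape a \code{\link{SyntheticShape-class}},
#'   \code{\link{Silhouette-class}} or binary mask (used for the
#'   \code{uniform_object} null and for the frame size).
#' @param targetRoi a \code{\link{RoiMask-class}} or binary mask; required
#'   (non-empty) when \code{roiPreference > 0}.
#' @param cfg a \code{\link{scanPathConfig}}.
#' @param geometry a \code{\link{viewingGeometry}} (step lengths are
#'   specified in degrees).
#' @param nullMap optional density matrix for the \code{saliency}/
#'   \code{custom} null.
#' @return a \code{\link{ScanPath-class}}; all fixations lie inside the
#'   frame and the first sits at the frame centre.
#' @export
generateScanpath <- function(shape, targetRoi = NULL, cfg = scanPathConfig(),
                             geometry = viewingGeometry(), nullMap = NULL) {
  mask <- if (is(shape, "SyntheticShape")) shape@silhouette@mask
          else if (is(shape, "Silhouette")) shape@mask
          else shape
  .assertMask(mask, "object mask")
  framePx <- nrow(mask)
  roi <- if (is(targetRoi, "RoiMask")) targetRoi@mask else targetRoi
  if (cfg$roiPreference > 0) {
    if (is.null(roi) || sum(roi > 0) == 0L) {
      stop("targetRoi must be non-empty when roiPreference > 0",
           call. = FALSE)
    }
  }
  n <- cfg$nFixations
  ctr <- (framePx - 1) / 2
  .withSeed(cfg$seed, {
    xy <- matrix(0, n, 2L)
    xy[1L, ] <- c(ctr, ctr)
    if (n > 1L) {
      if (!is.na(cfg$stepMean)) {
        xy[2:n, ] <- .stepWalk(n - 1L, start = c(ctr, ctr), framePx,
                               meanPx = cfg$stepMean * pxPerDeg(geometry),
                               shape = cfg$stepShape)
      } else {
        m <- n - 1L
        fromRoi <- runif(m) < cfg$roiPreference
        nullW <- switch(cfg$nullDensity,
          uniform_frame = NULL,
          uniform_object = mask,
          saliency = ,
          custom = {
            if (is.null(nullMap)) {
              stop("nullMap required for '", cfg$nullDensity,
                   "' null density", call. = FALSE)
            }
            nullMap
          })
        loc <- matrix(0, m, 2L)
        if (any(fromRoi)) {
          loc[fromRoi, ] <- .sampleLocations(sum(fromRoi), framePx, roi)
        }
        if (any(!fromRoi)) {
          loc[!fromRoi, ] <- .sampleLocations(sum(!fromRoi), framePx,
                                              nullW)
        }
        xy[2:n, ] <- loc
      }
    }
    xy <- pmin(pmax(xy, 0), framePx - 1)
    dur <- rgamma(n, shape = cfg$durationShape,
                  scale = cfg$durationMean / cfg$durationShape)
    new("ScanPath",
        fixations = data.frame(x_px = xy[, 1L], y_px = xy[, 2L],
                               duration_ms = dur),
        meta = list(config = cfg))
  })
}

# Gamma-step random walk; directions are resampled (rejection) so each
# step stays inside the frame, which preserves the step-length
# distribution up to boundary effects.
.stepWalk <- function(m, start, framePx, meanPx, shape) {
  out <- matrix(0, m, 2L)
  pos <- start
  for (i in seq_len(m)) {
    len <- rgamma(1L, shape = shape, scale = meanPx / shape)
    placed <- FALSE
    for (k in 1:200) {
      th <- runif(1L, 0, 2 * pi)
      cand <- pos + len * c(cos(th), sin(th))
      if (all(cand >= 0) && all(cand <= framePx - 1)) {
        pos <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      # project toward the frame centre, keeping the drawn length
      ctr <- c(framePx - 1, framePx - 1) / 2
      dir <- ctr - pos
      nrm <- sqrt(sum(dir^2))
      dir <- if (nrm > 1e-9) dir / nrm else c(1, 0)  # already at centre
      pos <- pmin(pmax(pos + len * dir, 0), framePx - 1)
    }
    out[i, ] <- pos
  }
  out
}

#' Generate a complete synthetic eye-movement experiment on disk
#'
#' Builds the stimulus set, simulates every participant x trial scanpath,
#' and writes a dataset directly readable by \code{\link{readFixations}}:
#' stimulus masks as 8-bit PNG (foreground 255), a fixation table
#' \code{fixations.csv} with header
#' \code{participant,group,trial,stimulus,fix_index,x_px,y_px,duration_ms},
#' and a plain-text \code{manifest.txt} echoing the design and seeds.
#' Partial outputs are removed if generation fails midway. Identical
#' design + seed reproduce the dataset byte for byte.
#'
#' @param design list with elements:
#'   \describe{
#'     \item{groups}{named list; each element a list with
#'       \code{nParticipants} and any \code{\link{scanPathConfig}}
#'       arguments (e.g. \code{stepMean}, \code{roiPreference},
#'       \code{nFixations}), plus optional \code{participantSdDeg}, the
#'       SD of a per-participant normal jitter on \code{stepMean}.}
#'     \item{nTrials}{trials per participant.}
#'     \item{stimuli}{named list of \code{\link{SyntheticShape-class}}
#'       objects (or family names, generated with derived seeds).}
#'     \item{targetRoi}{optional named list of \code{\link{RoiMask-class}}
#'       per stimulus, used when a group has \code{roiPreference > 0};
#'       if missing, the concave polarity mask is computed.}
#'   }
#' @param dir output directory (created).
#' @param seed master seed; every stream (stimuli, participants, trials)
#'   uses a seed derived from it.
#' @param geometry a \code{\link{viewingGeometry}}.
#' @return invisibly, a list with \code{fixationsPath}, \code{stimulusDir},
#'   \code{manifestPath} and the in-memory \code{stimuli} and
#'   \code{targetRoi} lists.
#' @export
generateExperiment <- function(design, dir, seed = 1L,
                               geometry = viewingGeometry()) {
  stopifnot(is.list(design), !is.null(design$groups),
            !is.null(design$nTrials), !is.null(design$stimuli))
  created <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(created, recursive = TRUE), add = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stimDir <- file.path(dir, "stimuli")
  dir.create(stimDir, showWarnings = FALSE)
  created <- c(created, stimDir)

  stimuli <- design$stimuli
  if (is.null(names(stimuli))) {
    names(stimuli) <- sprintf("stim%02d", seq_along(stimuli))
  }
  stimuli <- lapply(seq_along(stimuli), function(i) {
    s <- stimuli[[i]]
    if (is.character(s)) {
      generateShape(s, metricJitter = 0.1,
                    seed = .deriveSeed(seed, paste0("stim", i)),
                    familyId = s, exemplarId = names(stimuli)[i])
    } else s
  })
  names(stimuli) <- if (is.null(design$stimulusNames)) {
    vapply(stimuli, function(s) s@exemplarId, character(1))
  } else design$stimulusNames
  if (anyDuplicated(names(stimuli))) {
    names(stimuli) <- sprintf("stim%02d", seq_along(stimuli))
  }

  targetRoi <- design$targetRoi
  needRoi <- any(vapply(design$groups, function(g)
    isTRUE((g$roiPreference %||% 0) > 0), logical(1)))
  if (needRoi && is.null(targetRoi)) {
    targetRoi <- lapply(stimuli, function(s) {
      sil <- s@silhouette
      buildPolarityMasks(computeCurvature(sil), sil)$concave
    })
  }

  for (nm in names(stimuli)) {
    p <- file.path(stimDir, paste0(nm, ".png"))
    writeMaskPNG(stimuli[[nm]]@silhouette@mask, p)
    created <- c(created, p)
  }

  rows <- list()
  pid <- 0L
  for (gname in names(design$groups)) {
    g <- design$groups[[gname]]
    cfgArgs <- g[setdiff(names(g), c("nParticipants", "participantSdDeg"))]
    for (pp in seq_len(g$nParticipants)) {
      pid <- pid + 1L
      participant <- sprintf("p%02d", pid)
      pStep <- cfgArgs$stepMean
      sdp <- g$participantSdDeg %||% 0
      if (!is.null(pStep) && !is.na(pStep) && sdp > 0) {
        pStep <- .withSeed(.deriveSeed(seed, paste0("part", pid)),
                           max(0.2, rnorm(1L, pStep, sdp)))
      }
      for (tr in seq_len(design$nTrials)) {
        stimName <- names(stimuli)[((tr - 1L) %% length(stimuli)) + 1L]
        shp <- stimuli[[stimName]]
        args <- cfgArgs
        if (!is.null(pStep)) args$stepMean <- pStep
        args$seed <- .deriveSeed(seed, paste(pid, tr, sep = "-"))
        cfg <- do.call(scanPathConfig, args)
        sp <- generateScanpath(shp, targetRoi[[stimName]], cfg,
                               geometry = geometry)
        fx <- fixations(sp)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = participant, group = gname, trial = tr,
          stimulus = stimName, fix_index = seq_len(nrow(fx)),
          x_px = round(fx$x_px, 3), y_px = round(fx$y_px, 3),
          duration_ms = round(fx$duration_ms, 3))
      }
    }
  }
  tab <- do.call(rbind, rows)
  fixPath <- file.path(dir, "fixations.csv")
  utils::write.csv(tab, fixPath, row.names = FALSE, quote = FALSE)
  created <- c(created, fixPath)

  manifestPath <- file.path(dir, "manifest.txt")
  lines <- c(
    sprintf("master_seed: %d", as.integer(seed)),
    sprintf("n_trials: %d", as.integer(design$nTrials)),
    sprintf("stimuli: %s", paste(names(stimuli), collapse = ",")),
    unlist(lapply(names(design$groups), function(gname) {
      g <- design$groups[[gname]]
      vals <- vapply(g, function(v) paste(format(v), collapse = ","),
                     character(1))
      sprintf("group.%s.%s: %s", gname, names(g), vals)
    })))
  writeLines(lines, manifestPath)
  created <- c(created, manifestPath)
  ok <- TRUE
  invisible(list(fixationsPath = fixPath, stimulusDir = stimDir,
                 manifestPath = manifestPath, stimuli = stimuli,
                 targetRoi = targetRoi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
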