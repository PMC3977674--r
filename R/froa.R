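#' Fixation-region map
#'
#' Builds the union of disks of a fixed angular radius around fixation
#' centres, clipped to the frame. With \code{regionRadiusDeg = 0} each
#' fixation contributes its single pixel, which makes area overlap
#' equivalent to a (deduplicated) fixation-count overlap. The union is
#' idempotent under duplicated fixations. Default radius 1 degree, the
#' approximate foveal extent.
#'
#' @param fix a \code{\link{ScanPath-class}} or data.frame with
#'   \code{x_px}, \code{y_px} (>= 1 row).
#' @param geometry a \code{\link{viewingGeometry}}.
#' @param regionRadiusDeg disk radius in degrees (>= 0).
#' @return a \code{\link{FixationRegionMap-class}}.
#' @export
fixationRegionMap <- function(fix, geometry = viewingGeometry(),
                              regionRadiusDeg = 1) {
  if (is(fix, "ScanPath")) {
    fix <- fixations(fix)
  }
  if (nrow(fix) < 1L) {
    stop("at least one fixation is required", call. = FALSE)
  }
  if (regionRadiusDeg < 0) {
    stop("regionRadiusDeg must be >= 0", call. = FALSE)
  }
  fp <- geometry@framePx
  rpx <- regionRadiusDeg * pxPerDeg(geometry)
  canvas <- .stampDisks(c(fp, fp), fix$x_px, fix$y_px, rpx)
  new("FixationRegionMap", mask = 1L * canvas,
      nFixations = nrow(fix), regionRadiusDeg = regionRadiusDeg)
}

#' Percentage overlap between a fixation-region map and an ROI
#'
#' \eqn{O = 100 |F \cap R| / |F|} over pixel counts, where F is the
#' fixation-region mask and R the ROI mask.
#'
#' @param fixmap a \code{\link{FixationRegionMap-class}} or binary matrix.
#' @param roi a \code{\link{RoiMask-class}} or binary matrix of the same
#'   dimensions.
#' @return overlap percentage in [0, 100].
#' @export
overlapPercent <- function(fixmap, roi) {
  f <- if (is(fixmap, "FixationRegionMap")) fixmap@mask else fixmap
  r <- if (is(roi, "RoiMask")) roi@mask else roi
  if (!identical(dim(f), dim(r))) {
    stop("fixation map and ROI have different dimensions", call. = FALSE)
  }
  nf <- sum(f > 0)
  if (nf == 0L) {
    stop("fixation-region map is empty", call. = FALSE)
  }
  100 * sum(f > 0 & r > 0) / nf
}

# Normalise a null-density spec to a weight vector over pixels (NULL =
# uniform over the frame).
.nullWeights <- function(nullDensity, framePx) {
  if (is.character(nullDensity) && length(nullDensity) == 1L &&
      nullDensity == "uniform_frame") {
    return(list(w = NULL, label = "uniform_frame"))
  }
  if (is(nullDensity, "RoiMask")) {
    nullDensity <- nullDensity@mask
  }
  if (is(nullDensity, "Silhouette")) {
    nullDensity <- nullDensity@mask
  }
  if (!is.matrix(nullDensity)) {
    stop("nullDensity must be 'uniform_frame' or a weight matrix",
         call. = FALSE)
  }
  if (nrow(nullDensity) != framePx || ncol(nullDensity) != framePx) {
    stop("null density dimensions do not match the frame", call. = FALSE)
  }
  w <- as.vector(nullDensity)
  if (any(w < 0)) {
    stop("null density has negative mass", call. = FALSE)
  }
  s <- sum(w)
  if (s <= 0) {
    stop("null density has zero mass", call. = FALSE)
  }
  list(w = w / s, label = "matrix")
}

#' Monte-Carlo chance overlap distribution
#'
#' Each iteration draws \code{nFixations} fixation locations i.i.d. from
#' the null density, builds the fixation-region map at the same radius as
#' the observed data, and records its percentage overlap with the ROI.
#' The chance bound is the 95th percentile of the resulting distribution
#' (linear interpolation); with \code{ci = "two_sided"} the 97.5th
#' percentile is used instead. Draws land on pixel centres of the null
#' grid. Reproducible under a fixed seed.
#'
#' @param nFixations fixations per iteration (>= 1).
#' @param roi a \code{\link{RoiMask-class}} or binary matrix.
#' @param nullDensity \code{"uniform_frame"}, or a W x H matrix of
#'   non-negative weights (e.g. an object mask or a saliency map);
#'   normalised internally.
#' @param geometry a \code{\link{viewingGeometry}}.
#' @param regionRadiusDeg fixation-region radius (degrees).
#' @param nIterations Monte-Carlo iterations (>= 100).
#' @param seed integer seed.
#' @param ci \code{"one_sided"} (default, 95th percentile) or
#'   \code{"two_sided"} (97.5th).
#' @return a \code{\link{ChanceDistribution-class}}.
#' @export
chanceDistribution <- function(nFixations, roi,
                               nullDensity = "uniform_frame",
                               geometry = viewingGeometry(),
                               regionRadiusDeg = 1, nIterations = 1000L,
                               seed = 1L,
                               ci = c("one_sided", "two_sided")) {
  ci <- match.arg(ci)
  rois <- list(roi = roi)
  res <- .chanceMulti(nFixations, rois, nullDensity, geometry,
                      regionRadiusDeg, nIterations, seed, ci)
  res[[1L]]
}

# Shared-draw chance distributions for several ROIs at once: the same
# Monte-Carlo fixation sets are scored against each ROI. Vectorised over
# iterations in memory-bounded chunks.
#' @importFrom stats quantile runif rgamma rnorm
.chanceMulti <- function(nFixations, rois, nullDensity, geometry,
                         regionRadiusDeg, nIterations, seed,
                         ci = "one_sided") {
  if (!.isCount(nFixations) || nFixations < 1) {
    stop("nFixations must be a positive count", call. = FALSE)
  }
  if (!.isCount(nIterations) || nIterations < 100) {
    stop("nIterations must be >= 100", call. = FALSE)
  }
  fp <- geometry@framePx
  nw <- .nullWeights(nullDensity, fp)
  roiV <- lapply(rois, function(r) {
    m <- if (is(r, "RoiMask")) r@mask else r
    if (nrow(m) != fp || ncol(m) != fp) {
      stop("ROI dimensions do not match the frame", call. = FALSE)
    }
    as.vector(m > 0)
  })
  rpx <- regionRadiusDeg * pxPerDeg(geometry)
  off <- .diskOffsets(rpx)
  npx <- fp * fp
  perIter <- nFixations * nrow(off)
  chunk <- max(1L, min(nIterations, floor(4e6 / perIter)))
  overlaps <- lapply(roiV, function(r) numeric(nIterations))
  .withSeed(seed, {
    done <- 0L
    while (done < nIterations) {
      k <- min(chunk, nIterations - done)
      idx <- if (is.null(nw$w)) {
        sample.int(npx, k * nFixations, replace = TRUE)
      } else {
        sample.int(npx, k * nFixations, replace = TRUE, prob = nw$w)
      }
      cx <- (idx - 1L) %% fp
      cy <- (idx - 1L) %/% fp
      nOff <- nrow(off)
      ex <- rep(cx, each = nOff) + off[, 1L]
      ey <- rep(cy, each = nOff) + off[, 2L]
      it <- rep(seq_len(k), each = nFixations * nOff)
      ok <- ex >= 0 & ex < fp & ey >= 0 & ey < fp
      pix <- (ex[ok] + ey[ok] * fp) + 1L
      itk <- it[ok]
      key <- if (as.double(k) * npx < 2^31) {
        (itk - 1L) * npx + pix            # integer arithmetic, fast dedup
      } else {
        (itk - 1) * as.double(npx) + pix
      }
      keep <- !duplicated(key)
      pix <- pix[keep]
      itk <- itk[keep]
      tot <- tabulate(itk, nbins = k)
      for (j in seq_along(roiV)) {
        hit <- tabulate(itk[roiV[[j]][pix]], nbins = k)
        overlaps[[j]][done + seq_len(k)] <- 100 * hit / tot
      }
      done <- done + k
    }
  })
  prob <- if (ci == "one_sided") 0.95 else 0.975
  lapply(overlaps, function(o) {
    new("ChanceDistribution", overlaps = o,
        q95 = quantile(o, prob, type = 7, names = FALSE),
        nIterations = as.integer(nIterations), nullDensity = nw$label,
        seed = as.integer(seed))
  })
}

#' Model matching correspondence (MMC)
#'
#' MMC = observed overlap percentage minus the chance bound (percentage
#' points). Positive values indicate data-model correspondence above the
#' 95\% chance level; negative values, overlap below the amount expected
#' at the 95\% bound.
#'
#' @param observed observed overlap percentage (or a
#'   \code{\link{FixationRegionMap-class}} together with \code{roi}).
#' @param chance a \code{\link{ChanceDistribution-class}}.
#' @param roi optional ROI when \code{observed} is a fixation map.
#' @return an \code{\link{OverlapResult-class}}.
#' @export
mmcStatistic <- function(observed, chance, roi = NULL) {
  if (is(observed, "FixationRegionMap")) {
    if (is.null(roi)) {
      stop("roi required when observed is a fixation-region map",
           call. = FALSE)
    }
    observed <- overlapPercent(observed, roi)
  }
  stopifnot(is(chance, "ChanceDistribution"))
  new("OverlapResult", observed = observed, chance = chance,
      mmc = observed - chance@q95)
}

#' Run the full FROA analysis over a fixation table
#'
#' For each participant x stimulus, fixations are pooled across trials,
#' the observed overlap with every ROI model is computed, and a
#' Monte-Carlo chance distribution with the same number of fixations is
#' drawn from the null density (shared draws across the models of one
#' stimulus; cached per stimulus and fixation count). Per-participant MMC
#' is the mean over stimuli of the per-stimulus MMC.
#'
#' @param records preprocessed fixation records (see
#'   \code{\link{preprocessFixations}}).
#' @param stimuli named list of \code{\link{Silhouette-class}} objects (or
#'   binary masks), keyed by stimulus id; used for the
#'   \code{uniform_object} null.
#' @param roiModels named list: \code{roiModels[[stimulus]]} is a named
#'   list of \code{\link{RoiMask-class}} objects (e.g. concave, convex,
#'   part_boundary).
#' @param geometry a \code{\link{viewingGeometry}}.
#' @param regionRadiusDeg fixation-region radius (degrees).
#' @param nullDensity \code{"uniform_object"} (default),
#'   \code{"uniform_frame"}, or a named list of density matrices per
#'   stimulus (e.g. saliency maps).
#' @param nIterations Monte-Carlo iterations per chance distribution.
#' @param seed master seed; per-stimulus streams are derived from it.
#' @param ci chance-bound sidedness, see \code{\link{chanceDistribution}}.
#' @return long-format data.frame \code{participant, group, model, mmc},
#'   one row per participant x model.
#' @export
runFroa <- function(records, stimuli, roiModels,
                    geometry = viewingGeometry(), regionRadiusDeg = 1,
                    nullDensity = "uniform_object", nIterations = 1000L,
                    seed = 1L, ci = c("one_sided", "two_sided")) {
  ci <- match.arg(ci)
  used <- unique(records$stimulus)
  missingRoi <- setdiff(used, names(roiModels))
  if (length(missingRoi) > 0L) {
    stop("no ROI models for stimuli: ",
         paste(missingRoi, collapse = ", "), call. = FALSE)
  }
  getMask <- function(s) {
    m <- stimuli[[s]]
    if (is(m, "SyntheticShape")) m <- m@silhouette
    if (is(m, "Silhouette")) m <- m@mask
    m
  }
  nullFor <- function(s) {
    if (is.list(nullDensity) && !is.matrix(nullDensity)) {
      nd <- nullDensity[[s]]
      if (is.null(nd)) {
        stop("no null density for stimulus ", s, call. = FALSE)
      }
      nd
    } else if (identical(nullDensity, "uniform_object")) {
      m <- getMask(s)
      if (is.null(m)) {
        stop("no stimulus mask for ", s,
             " (needed for the uniform_object null)", call. = FALSE)
      }
      m
    } else {
      nullDensity
    }
  }
  cache <- new.env(parent = emptyenv())
  perStim <- list()
  for (p in unique(records$participant)) {
    psub <- records[records$participant == p, , drop = FALSE]
    for (s in unique(psub$stimulus)) {
      fx <- psub[psub$stimulus == s, , drop = FALSE]
      if (nrow(fx) == 0L) next
      fmap <- fixationRegionMap(fx, geometry, regionRadiusDeg)
      key <- paste(s, nrow(fx), sep = "#")
      if (!exists(key, envir = cache)) {
        assign(key,
               .chanceMulti(nrow(fx), roiModels[[s]], nullFor(s), geometry,
                            regionRadiusDeg, nIterations,
                            .deriveSeed(seed, key), ci),
               envir = cache)
      }
      chances <- get(key, envir = cache)
      for (mod in names(roiModels[[s]])) {
        o <- overlapPercent(fmap, roiModels[[s]][[mod]])
        perStim[[length(perStim) + 1L]] <- data.frame(
          participant = p, group = fx$group[1L], stimulus = s,
          model = mod, mmc = o - chances[[mod]]@q95)
      }
    }
  }
  long <- do.call(rbind, perStim)
  agg <- aggregate(mmc ~ participant + group + model, data = long,
                   FUN = mean)
  agg[order(agg$participant, agg$model), ]
}

#' @importFrom stats aggregate approx
NULL
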