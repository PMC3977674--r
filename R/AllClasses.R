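#' @import methods
NULL

#' Viewing geometry of the display
#'
#' Maps pixels to degrees of visual angle for a square stimulus frame.
#' The default frame is 800 px subtending 18 degrees horizontally
#' (44.44 px per degree); a single linear conversion factor is used, which
#' is accurate to well under 2\% at these eccentricities.
#'
#' @slot framePx integer, frame side length in pixels.
#' @slot frameDeg numeric, visual angle subtended by the frame (degrees).
#' @export
setClass("ViewingGeometry",
  representation(framePx = "integer", frameDeg = "numeric"),
  prototype(framePx = 800L, frameDeg = 18)
)

setValidity("ViewingGeometry", function(object) {
  if (length(object@framePx) != 1L || object@framePx < 1L) {
    return("framePx must be a single positive integer")
  }
  if (length(object@frameDeg) != 1L || !is.finite(object@frameDeg) ||
      object@frameDeg <= 0) {
    return("frameDeg must be a single positive number")
  }
  TRUE
})

#' @param framePx frame side (px)
#' @param frameDeg subtended visual angle (degrees)
#' @rdname ViewingGeometry-class
#' @export
viewingGeometry <- function(framePx = 800L, frameDeg = 18) {
  new("ViewingGeometry", framePx = as.integer(framePx),
      frameDeg = as.numeric(frameDeg))
}

#' Object silhouette: binary mask plus its bounding contour
#'
#' The mask is a \code{W x H} binary matrix indexed \code{mask[x+1, y+1]}
#' (0-based pixel coordinates, origin top-left, y downward). The contour is
#' an \code{n x 2} matrix of subpixel boundary points at uniform ~1 px
#' arc-length spacing, closed (last point adjacent to first), and in
#' canonical orientation: the interior lies on the left when the contour is
#' traversed in a y-up frame, i.e. the signed y-up polygon area is positive.
#'
#' @slot mask binary matrix, dim \code{c(W, H)}.
#' @slot contour numeric matrix, columns \code{x}, \code{y} (0-based px).
#' @export
setClass("Silhouette",
  representation(mask = "matrix", contour = "matrix")
)

setValidity("Silhouette", function(object) {
  m <- object@mask
  ct <- object@contour
  if (!is.numeric(m) && !is.logical(m)) {
    return("mask must be numeric or logical")
  }
  if (any(m != 0 & m != 1)) {
    return("mask must be binary")
  }
  if (ncol(ct) != 2L) {
    return("contour must have two columns (x, y)")
  }
  if (nrow(ct) < 4L) {
    return("contour must have at least 4 points")
  }
  steps <- sqrt(rowSums((ct[c(2:nrow(ct), 1L), ] - ct)^2))
  if (max(steps) > 2) {
    return("contour is not closed at ~1 px spacing")
  }
  if (.signedAreaYUp(ct, nrow(m)) <= 0) {
    return("contour is not in canonical (positive y-up area) orientation")
  }
  TRUE
})

#' Signed curvature along a silhouette contour
#'
#' One signed curvature value per contour sample, units px^-1. The sign
#' convention is kappa > 0 convex (bulging outward), kappa < 0 concave
#' (indenting inward); for a circle of radius r, kappa ~ +1/r everywhere.
#'
#' @slot kappa numeric vector, length = number of contour samples.
#' @slot smoothingSigma numeric, contour smoothing scale (samples).
#' @export
setClass("CurvatureMap",
  representation(kappa = "numeric", smoothingSigma = "numeric")
)

setValidity("CurvatureMap", function(object) {
  if (anyNA(object@kappa)) {
    return("kappa contains NA")
  }
  if (object@smoothingSigma < 0) {
    return("smoothingSigma must be >= 0")
  }
  TRUE
})

.ROI_LABELS <- c("concave", "convex", "part_boundary", "custom")

#' Region-of-interest mask
#'
#' A binary pixel mask over the stimulus frame labelled by the shape model
#' that produced it.
#'
#' @slot mask binary matrix, dim \code{c(W, H)}.
#' @slot label one of \code{"concave"}, \code{"convex"},
#'   \code{"part_boundary"}, \code{"custom"}.
#' @export
setClass("RoiMask",
  representation(mask = "matrix", label = "character")
)

setValidity("RoiMask", function(object) {
  if (any(object@mask != 0 & object@mask != 1)) {
    return("mask must be binary")
  }
  if (length(object@label) != 1L || !object@label %in% .ROI_LABELS) {
    return(paste("label must be one of:", paste(.ROI_LABELS, collapse = ", ")))
  }
  TRUE
})

#' @param mask binary matrix
#' @param label ROI label
#' @rdname RoiMask-class
#' @export
roiMask <- function(mask, label = "custom") {
  .assertMask(mask, "ROI mask")
  new("RoiMask", mask = 1L * (mask > 0), label = label)
}

#' Synthetic multi-part silhouette with ground-truth junction chords
#'
#' @slot silhouette a \code{\link{Silhouette-class}} object.
#' @slot parts list of part primitives (kind, center, size, angle).
#' @slot trueCuts numeric matrix, columns \code{x1,y1,x2,y2}: one chord per
#'   adjacent primitive pair, each lying entirely inside the mask.
#' @slot familyId character family identifier.
#' @slot exemplarId character exemplar identifier.
#' @export
setClass("SyntheticShape",
  representation(silhouette = "Silhouette", parts = "list",
                 trueCuts = "matrix", familyId = "character",
                 exemplarId = "character")
)

setValidity("SyntheticShape", function(object) {
  tc <- object@trueCuts
  if (nrow(tc) > 0 && ncol(tc) != 4L) {
    return("trueCuts must have columns x1,y1,x2,y2")
  }
  m <- object@silhouette@mask
  for (i in seq_len(nrow(tc))) {
    # open interior: endpoints sit on the boundary and may round outward
    tt <- seq(0.04, 0.96, length.out = 24)
    xs <- tc[i, 1L] + tt * (tc[i, 3L] - tc[i, 1L])
    ys <- tc[i, 2L] + tt * (tc[i, 4L] - tc[i, 2L])
    if (!all(.insideMask(m, xs, ys))) {
      return(sprintf("true cut %d leaves the silhouette mask", i))
    }
  }
  TRUE
})

#' Scanpath: ordered fixations for one participant x trial x stimulus
#'
#' @slot fixations data.frame with columns \code{x_px}, \code{y_px},
#'   \code{duration_ms}; row order is fixation order.
#' @slot meta named list (participant, trial, stimulus, ...).
#' @export
setClass("ScanPath",
  representation(fixations = "data.frame", meta = "list")
)

setValidity("ScanPath", function(object) {
  fx <- object@fixations
  need <- c("x_px", "y_px", "duration_ms")
  if (!all(need %in% names(fx))) {
    return("fixations needs columns x_px, y_px, duration_ms")
  }
  if (nrow(fx) > 0 && any(fx$duration_ms <= 0)) {
    return("durations must be positive")
  }
  TRUE
})

#' Fixation-region map
#'
#' Union of disks of a fixed angular radius centred on retained fixations,
#' clipped to the stimulus frame.
#'
#' @slot mask binary matrix, dim \code{c(W, H)}.
#' @slot nFixations number of fixations the map was built from.
#' @slot regionRadiusDeg disk radius in degrees of visual angle.
#' @export
setClass("FixationRegionMap",
  representation(mask = "matrix", nFixations = "integer",
                 regionRadiusDeg = "numeric")
)

setValidity("FixationRegionMap", function(object) {
  if (any(object@mask != 0 & object@mask != 1)) {
    return("mask must be binary")
  }
  if (object@nFixations < 1L) {
    return("nFixations must be >= 1")
  }
  if (object@regionRadiusDeg < 0) {
    return("regionRadiusDeg must be >= 0")
  }
  TRUE
})

#' Monte-Carlo chance overlap distribution
#'
#' @slot overlaps numeric vector of overlap percentages, one per iteration.
#' @slot q95 the 95th percentile of \code{overlaps} (linear interpolation).
#' @slot nIterations number of Monte-Carlo iterations.
#' @slot nullDensity label of the null sampling density.
#' @slot seed seed used for the draws.
#' @export
setClass("ChanceDistribution",
  representation(overlaps = "numeric", q95 = "numeric",
                 nIterations = "integer", nullDensity = "character",
                 seed = "integer")
)

setValidity("ChanceDistribution", function(object) {
  o <- object@overlaps
  if (length(o) < 1L || any(o < 0 | o > 100)) {
    return("overlaps must lie in [0, 100]")
  }
  if (object@q95 < min(o) - 1e-9 || object@q95 > max(o) + 1e-9) {
    return("q95 must lie within the range of overlaps")
  }
  TRUE
})

#' FROA overlap result
#'
#' Observed overlap percentage, its Monte-Carlo chance distribution, and the
#' model matching correspondence MMC = observed - q95 (percentage points).
#' MMC > 0 means the observed overlap exceeds the one-sided 95\% chance
#' bound.
#'
#' @slot observed observed overlap percentage in [0, 100].
#' @slot chance a \code{\link{ChanceDistribution-class}} object.
#' @slot mmc numeric, \code{observed - chance@q95}.
#' @export
setClass("OverlapResult",
  representation(observed = "numeric", chance = "ChanceDistribution",
                 mmc = "numeric")
)

setValidity("OverlapResult", function(object) {
  if (object@observed < 0 || object@observed > 100) {
    return("observed must be in [0, 100]")
  }
  if (abs(object@mmc - (object@observed - object@chance@q95)) > 1e-9) {
    return("mmc must equal observed - q95 exactly")
  }
  TRUE
})
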