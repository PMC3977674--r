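#' Accessors for froa classes
#'
#' Slot access for the package's S4 containers. \code{maskMatrix} returns
#' the binary pixel matrix of any mask-bearing object; \code{contourPoints}
#' the ordered boundary samples of a silhouette; \code{curvatureValues} the
#' signed curvature vector; \code{roiArea} the ROI pixel count;
#' \code{fixations} the fixation table of a scanpath; \code{observedOverlap},
#' \code{chanceBound} and \code{mmcValue} the components of an overlap
#' result.
#'
#' @param x an object of the appropriate class.
#' @return See details per generic.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname accessors
#' @export
setGeneric("contourPoints", function(x) standardGeneric("contourPoints"))

#' @rdname accessors
#' @export
setGeneric("curvatureValues", function(x) standardGeneric("curvatureValues"))

#' @rdname accessors
#' @export
setGeneric("roiLabel", function(x) standardGeneric("roiLabel"))

#' @rdname accessors
#' @export
setGeneric("roiArea", function(x) standardGeneric("roiArea"))

#' @rdname accessors
#' @export
setGeneric("fixations", function(x) standardGeneric("fixations"))

#' @rdname accessors
#' @export
setGeneric("trueCuts", function(x) standardGeneric("trueCuts"))

#' @rdname accessors
#' @export
setGeneric("silhouette", function(x) standardGeneric("silhouette"))

#' @rdname accessors
#' @export
setGeneric("pxPerDeg", function(x) standardGeneric("pxPerDeg"))

#' @rdname accessors
#' @export
setGeneric("observedOverlap", function(x) standardGeneric("observedOverlap"))

#' @rdname accessors
#' @export
setGeneric("chanceOverlaps", function(x) standardGeneric("chanceOverlaps"))

#' @rdname accessors
#' @export
setGeneric("chanceBound", function(x) standardGeneric("chanceBound"))

#' @rdname accessors
#' @export
setGeneric("mmcValue", function(x) standardGeneric("mmcValue"))

#' @rdname accessors
#' @export
setMethod("maskMatrix", "Silhouette", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("maskMatrix", "RoiMask", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("maskMatrix", "FixationRegionMap", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("maskMatrix", "SyntheticShape", function(x) x@silhouette@mask)

#' @rdname accessors
#' @export
setMethod("contourPoints", "Silhouette", function(x) x@contour)

#' @rdname accessors
#' @export
setMethod("curvatureValues", "CurvatureMap", function(x) x@kappa)

#' @rdname accessors
#' @export
setMethod("roiLabel", "RoiMask", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("roiArea", "RoiMask", function(x) sum(x@mask > 0))

#' @rdname accessors
#' @export
setMethod("fixations", "ScanPath", function(x) x@fixations)

#' @rdname accessors
#' @export
setMethod("trueCuts", "SyntheticShape", function(x) x@trueCuts)

#' @rdname accessors
#' @export
setMethod("silhouette", "SyntheticShape", function(x) x@silhouette)

#' @rdname accessors
#' @export
setMethod("pxPerDeg", "ViewingGeometry",
          function(x) x@framePx / x@frameDeg)

#' @rdname accessors
#' @export
setMethod("observedOverlap", "OverlapResult", function(x) x@observed)

#' @rdname accessors
#' @export
setMethod("chanceOverlaps", "ChanceDistribution", function(x) x@overlaps)

#' @rdname accessors
#' @export
setMethod("chanceOverlaps", "OverlapResult", function(x) x@chance@overlaps)

#' @rdname accessors
#' @export
setMethod("chanceBound", "ChanceDistribution", function(x) x@q95)

#' @rdname accessors
#' @export
setMethod("chanceBound", "OverlapResult", function(x) x@chance@q95)

#' @rdname accessors
#' @export
setMethod("mmcValue", "OverlapResult", function(x) x@mmc)

setMethod("show", "ViewingGeometry", function(object) {
  cat(sprintf("ViewingGeometry: %d px frame, %.2f deg (%.2f px/deg)\n",
              object@framePx, object@frameDeg,
              object@framePx / object@frameDeg))
})

setMethod("show", "Silhouette", function(object) {
  cat(sprintf("Silhouette: %d x %d px mask, area %d px, contour %d samples\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask > 0),
              nrow(object@contour)))
})

setMethod("show", "CurvatureMap", function(object) {
  k <- object@kappa
  cat(sprintf(
    "CurvatureMap: %d samples, kappa in [%.4f, %.4f] px^-1 (sigma = %g)\n",
    length(k), min(k), max(k), object@smoothingSigma))
})

setMethod("show", "RoiMask", function(object) {
  cat(sprintf("RoiMask <%s>: %d x %d px, area %d px\n", object@label,
              nrow(object@mask), ncol(object@mask), sum(object@mask > 0)))
})

setMethod("show", "SyntheticShape", function(object) {
  cat(sprintf(
    "SyntheticShape %s/%s: %d parts, %d true cuts, mask area %d px\n",
    object@familyId, object@exemplarId, length(object@parts),
    nrow(object@trueCuts), sum(object@silhouette@mask > 0)))
})

setMethod("show", "ScanPath", function(object) {
  cat(sprintf("ScanPath: %d fixations, total dwell %.0f ms\n",
              nrow(object@fixations), sum(object@fixations$duration_ms)))
})

setMethod("show", "FixationRegionMap", function(object) {
  cat(sprintf(
    "FixationRegionMap: %d fixations, radius %.2f deg, area %d px\n",
    object@nFixations, object@regionRadiusDeg, sum(object@mask > 0)))
})

setMethod("show", "ChanceDistribution", function(object) {
  cat(sprintf(
    "ChanceDistribution <%s>: %d iterations, mean %.2f%%, q95 %.2f%%\n",
    object@nullDensity, object@nIterations, mean(object@overlaps),
    object@q95))
})

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("OverlapResult: observed %.2f%%, q95 %.2f%%, MMC %.2f\n",
              object@observed, object@chance@q95, object@mmc))
})
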