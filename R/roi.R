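#' Build concave and convex curvature-polarity ROI masks
#'
#' Every contour sample whose curvature magnitude exceeds \code{kappaMin}
#' contributes a filled disk centred at the sample, accumulated into the
#' mask matching its polarity (kappa < 0 concave, kappa > 0 convex). The
#' disk radius grows linearly with curvature magnitude,
#' \code{r = rMin + (rMax - rMin) * min(|kappa| / kappaSat, 1)},
#' so sharper features receive proportionally larger disks.
#'
#' Defaults (2-20 px disks, kappaMin 0.005 px^-1, saturation at
#' 0.1 px^-1) are tuned to an 800 px frame; all four constants are
#' exposed. The two polarity masks are built independently and may
#' overlap.
#'
#' @param curv a \code{\link{CurvatureMap-class}}.
#' @param sil the source \code{\link{Silhouette-class}}.
#' @param kappaMin curvature magnitude threshold (px^-1).
#' @param rMin,rMax disk radius bounds (px), \code{rMin <= rMax}.
#' @param kappaSat curvature magnitude at which the radius saturates.
#' @return list with elements \code{concave} and \code{convex}, each a
#'   \code{\link{RoiMask-class}}.
#' @examples
#' sil <- extractContour(discMask(256, c(127, 127), 80))
#' pm <- buildPolarityMasks(computeCurvature(sil), sil)
#' roiArea(pm$concave)  # 0: a disc has no concavities
#' @export
buildPolarityMasks <- function(curv, sil, kappaMin = 0.005,
                               rMin = 2, rMax = 20, kappaSat = 0.1) {
  stopifnot(is(curv, "CurvatureMap"), is(sil, "Silhouette"))
  if (kappaMin <= 0 || rMin <= 0 || kappaSat <= 0) {
    stop("kappaMin, rMin and kappaSat must be positive", call. = FALSE)
  }
  if (rMin > rMax) {
    stop("rMin must be <= rMax", call. = FALSE)
  }
  k <- curv@kappa
  ct <- sil@contour
  if (length(k) != nrow(ct)) {
    stop("curvature map does not match the contour length", call. = FALSE)
  }
  dims <- dim(sil@mask)
  radius <- rMin + (rMax - rMin) * pmin(abs(k) / kappaSat, 1)
  sel <- abs(k) >= kappaMin
  mk <- function(polarity) {
    idx <- sel & (if (polarity == "concave") k < 0 else k > 0)
    canvas <- .stampDisks(dims, ct[idx, 1L], ct[idx, 2L], radius[idx])
    new("RoiMask", mask = 1L * canvas, label = polarity)
  }
  list(concave = mk("concave"), convex = mk("convex"))
}

#' Detect concavity extrema (negative curvature minima) along a contour
#'
#' Local minima of the signed curvature with kappa < 0 whose topographic
#' prominence (computed on the circular curvature profile) meets the
#' threshold. These are the candidate part-boundary anchors of the minima
#' rule.
#'
#' @param curv a \code{\link{CurvatureMap-class}}.
#' @param prominence minimum prominence of a minimum, in px^-1 (> 0).
#' @param minSeparation non-maximum-suppression window (samples): within
#'   any window of this arc radius only the deepest minimum survives,
#'   which removes the satellite minima that multi-scale smoothing leaves
#'   on the flanks of a sharp corner.
#' @return integer vector of 1-based contour sample indices, in contour
#'   order.
#' @export
detectConcavityExtrema <- function(curv, prominence = 0.005,
                                   minSeparation = 25L) {
  stopifnot(is(curv, "CurvatureMap"))
  if (prominence <= 0) {
    stop("prominence must be > 0", call. = FALSE)
  }
  k <- curv@kappa
  n <- length(k)
  if (n < 3L) {
    return(integer(0))
  }
  prv <- k[c(n, 1:(n - 1L))]
  nxt <- k[c(2:n, 1L)]
  # strict on one side so plateaus yield a single index
  cand <- which(k < 0 & k < prv & k <= nxt)
  keep <- vapply(cand, function(i) .circularProminence(k, i) >= prominence,
                 logical(1))
  cand <- cand[keep]
  if (length(cand) > 1L && minSeparation > 0) {
    accepted <- integer(0)
    for (i in cand[order(k[cand])]) {
      darc <- abs(accepted - i)
      if (all(pmin(darc, n - darc) > minSeparation)) {
        accepted <- c(accepted, i)
      }
    }
    cand <- accepted
  }
  sort(cand)
}

# Topographic prominence of a local minimum on a circular profile: walk
# left and right from i until a strictly lower value appears (or the walk
# wraps); the prominence is the smaller of the two maximal rises.
.circularProminence <- function(k, i) {
  n <- length(k)
  rise <- function(step) {
    top <- -Inf
    j <- i
    for (s in seq_len(n - 1L)) {
      j <- ((j - 1L + step) %% n) + 1L
      if (k[j] < k[i]) break
      top <- max(top, k[j])
    }
    if (is.finite(top)) top - k[i] else Inf
  }
  min(rise(1L), rise(-1L))
}

#' Part cuts by the minima/short-cut rule
#'
#' Pairs concavity extrema with straight chords: every extrema pair whose
#' connecting chord lies entirely inside the silhouette is a candidate;
#' candidates are accepted greedily in order of increasing chord length
#' (ties broken by lower contour index), each extremum used at most once,
#' and a chord is only accepted if it is shorter than both contour arcs it
#' separates (the short-cut condition).
#'
#' @param sil a \code{\link{Silhouette-class}}.
#' @param extrema integer contour indices from
#'   \code{\link{detectConcavityExtrema}}.
#' @return data.frame with one row per accepted cut: \code{cut_id},
#'   \code{x1, y1, x2, y2}, \code{length_px}, \code{i1, i2} (contour
#'   indices). Zero rows when no cut is admissible.
#' @export
computePartCuts <- function(sil, extrema) {
  stopifnot(is(sil, "Silhouette"))
  empty <- data.frame(cut_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0),
                      length_px = numeric(0), i1 = integer(0),
                      i2 = integer(0))
  extrema <- sort(unique(as.integer(extrema)))
  if (length(extrema) < 2L) {
    return(empty)
  }
  ct <- sil@contour
  n <- nrow(ct)
  pairs <- t(combn(extrema, 2L))
  p1 <- ct[pairs[, 1L], , drop = FALSE]
  p2 <- ct[pairs[, 2L], , drop = FALSE]
  len <- sqrt(rowSums((p2 - p1)^2))
  arc <- abs(pairs[, 2L] - pairs[, 1L])      # samples ~ px
  arc <- pmin(arc, n - arc)
  arcOther <- n - arc
  ok <- len < arc & len < arcOther           # short-cut condition
  ok <- ok & vapply(seq_len(nrow(pairs)), function(j) {
    ok[j] && .chordInside(sil@mask, p1[j, ], p2[j, ])
  }, logical(1))
  cand <- which(ok)
  if (length(cand) == 0L) {
    return(empty)
  }
  cand <- cand[order(len[cand], pairs[cand, 1L], pairs[cand, 2L])]
  used <- integer(0)
  rows <- list()
  for (j in cand) {
    a <- pairs[j, 1L]
    b <- pairs[j, 2L]
    if (a %in% used || b %in% used) next
    used <- c(used, a, b)
    rows[[length(rows) + 1L]] <- data.frame(
      cut_id = length(rows) + 1L,
      x1 = p1[j, 1L], y1 = p1[j, 2L], x2 = p2[j, 1L], y2 = p2[j, 2L],
      length_px = len[j], i1 = a, i2 = b)
  }
  do.call(rbind, rows)
}

# A chord is inside if every 0.5 px sample along it (excluding the contour
# endpoints themselves, which sit on the boundary) is foreground.
.chordInside <- function(mask, a, b) {
  len <- sqrt(sum((b - a)^2))
  if (len < 1) {
    return(FALSE)
  }
  tt <- seq(0, 1, length.out = max(5L, ceiling(len * 2)))
  tt <- tt[tt > 0.02 & tt < 0.98]
  xs <- a[1L] + tt * (b[1L] - a[1L])
  ys <- a[2L] + tt * (b[2L] - a[2L])
  all(.insideMask(mask, xs, ys))
}

#' Internal part-boundary ROI mask
#'
#' Union of rectangular bands of half-width \code{bandPx} around each part
#' cut chord, clipped to the silhouette interior.
#'
#' @param sil a \code{\link{Silhouette-class}}.
#' @param cuts cut table from \code{\link{computePartCuts}} (or any
#'   data.frame with \code{x1, y1, x2, y2}).
#' @param bandPx band half-width in px (>= 1). Default 10 px (~0.22 deg on
#'   the standard 800 px / 18 deg frame).
#' @return a \code{\link{RoiMask-class}} labelled \code{part_boundary}.
#' @export
buildPartBoundaryMask <- function(sil, cuts, bandPx = 10) {
  stopifnot(is(sil, "Silhouette"))
  if (bandPx < 1) {
    stop("bandPx must be >= 1", call. = FALSE)
  }
  dims <- dim(sil@mask)
  canvas <- matrix(FALSE, dims[1L], dims[2L])
  for (i in seq_len(NROW(cuts))) {
    a <- c(cuts$x1[i], cuts$y1[i])
    b <- c(cuts$x2[i], cuts$y2[i])
    lo <- pmax(floor(pmin(a, b)) - ceiling(bandPx), 0)
    hi <- pmin(ceiling(pmax(a, b)) + ceiling(bandPx), dims - 1L)
    if (any(hi < lo)) next
    gx <- seq.int(lo[1L], hi[1L])
    gy <- seq.int(lo[2L], hi[2L])
    px <- rep(gx, times = length(gy))
    py <- rep(gy, each = length(gx))
    d <- b - a
    l2 <- sum(d^2)
    tt <- ((px - a[1L]) * d[1L] + (py - a[2L]) * d[2L]) / l2
    inband <- tt >= 0 & tt <= 1
    dist2 <- (px - (a[1L] + tt * d[1L]))^2 + (py - (a[2L] + tt * d[2L]))^2
    inband <- inband & dist2 <= bandPx^2
    canvas[cbind(px[inband] + 1L, py[inband] + 1L)] <- TRUE
  }
  canvas <- canvas & (sil@mask > 0)
  new("RoiMask", mask = 1L * canvas, label = "part_boundary")
}

#' Write a part-cut table as CSV
#'
#' Columns \code{cut_id, x1, y1, x2, y2, length_px}.
#'
#' @param cuts cut table from \code{\link{computePartCuts}}.
#' @param path output CSV path.
#' @export
writeCutsCSV <- function(cuts, path) {
  utils::write.csv(cuts[, c("cut_id", "x1", "y1", "x2", "y2", "length_px")],
                   path, row.names = FALSE)
  invisible(path)
}
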