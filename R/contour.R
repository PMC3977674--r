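#' Extract the bounding contour of a binary silhouette mask
#'
#' Traces a subpixel boundary of the single foreground component as the
#' iso-level curve of the lightly blurred mask (Gaussian, sigma 0.6 px;
#' the level is chosen so a straight edge is traced through its boundary
#' pixel centres), resamples it to uniform ~1 px arc-length spacing, and
#' enforces canonical orientation (interior on the left in a y-up frame,
#' i.e. positive signed y-up area). Level-set tracing interpolates between
#' pixels and so avoids most of the staircase bias of a raw pixel chain.
#'
#' @param mask binary matrix, dim \code{c(W, H)}, indexed
#'   \code{mask[x+1, y+1]} with 0-based pixel coordinates (origin top-left,
#'   y downward). Exactly one 4-connected foreground component of area
#'   >= 100 px and no holes.
#' @return a \code{\link{Silhouette-class}} object.
#' @examples
#' m <- discMask(64, c(31, 31), 20)
#' sil <- extractContour(m)
#' nrow(contourPoints(sil))  # ~ 2 * pi * 20
#' @importFrom grDevices contourLines
#' @importFrom stats pnorm
#' @export
extractContour <- function(mask) {
  .assertMask(mask)
  mask <- 1L * (mask > 0)
  if (sum(mask) < 100) {
    stop("foreground area must be >= 100 px", call. = FALSE)
  }
  lab <- EBImage::bwlabel(mask)
  ncomp <- max(lab)
  if (ncomp != 1L) {
    stop("mask must have exactly one 4-connected foreground component, ",
         "found ", ncomp, call. = FALSE)
  }
  # hole check: background components not touching the frame border
  bglab <- EBImage::bwlabel(1L - mask)
  border <- unique(c(bglab[1L, ], bglab[nrow(bglab), ],
                     bglab[, 1L], bglab[, ncol(bglab)]))
  inner <- setdiff(unique(as.vector(bglab)), c(0L, border))
  if (length(inner) > 0L) {
    stop("mask contains ", length(inner), " hole(s); fill holes first",
         call. = FALSE)
  }
  ct <- .levelSetBoundary(mask)
  if (is.null(ct)) {  # degenerate level curve: fall back to pixel chain
    ct <- EBImage::ocontour(lab)[[1L]]
  }
  if (nrow(ct) < 8L) {
    stop("boundary too short to trace", call. = FALSE)
  }
  ct <- .resampleClosed(ct)
  if (.signedAreaYUp(ct, ncol(mask)) < 0) {
    ct <- ct[rev(seq_len(nrow(ct))), , drop = FALSE]
  }
  new("Silhouette", mask = mask, contour = ct)
}

# Subpixel boundary polygon: iso-contour of the Gaussian-blurred mask at
# the level a blurred straight edge attains half a pixel inside, so the
# curve passes through boundary pixel centres on straight runs. The mask
# is zero-padded so shapes near the frame edge still close.
.levelSetBoundary <- function(mask, sigmaImg = 0.6) {
  dims <- dim(mask)
  pad <- 8L
  z <- matrix(0, dims[1L] + 2L * pad, dims[2L] + 2L * pad)
  z[pad + seq_len(dims[1L]), pad + seq_len(dims[2L])] <- mask
  zb <- .gaussBlur(z, sigmaImg)
  cl <- contourLines(x = seq(-pad, dims[1L] - 1L + pad),
                     y = seq(-pad, dims[2L] - 1L + pad),
                     z = zb, levels = pnorm(0.5 / sigmaImg))
  if (length(cl) == 0L) {
    return(NULL)
  }
  s <- cl[[which.max(vapply(cl, function(s) length(s$x), numeric(1)))]]
  p <- cbind(s$x, s$y)
  if (nrow(p) < 8L) {
    return(NULL)
  }
  gap <- sqrt(rowSums((p[c(2:nrow(p), 1L), , drop = FALSE] - p)^2))
  p[gap > 1e-9, , drop = FALSE]  # drop duplicated vertices (incl. closure)
}

# Resample a closed polyline to uniform arc-length spacing of ~1 px.
.resampleClosed <- function(pts) {
  n <- nrow(pts)
  nxt <- pts[c(2:n, 1L), , drop = FALSE]
  seg <- sqrt(rowSums((nxt - pts)^2))
  per <- sum(seg)
  m <- max(8L, round(per))
  s <- c(0, cumsum(seg))
  target <- seq(0, per, length.out = m + 1L)[-(m + 1L)]
  px <- c(pts[, 1L], pts[1L, 1L])
  py <- c(pts[, 2L], pts[1L, 2L])
  cbind(x = approx(s, px, xout = target)$y,
        y = approx(s, py, xout = target)$y)
}

#' Signed curvature along a silhouette contour
#'
#' The contour coordinates are smoothed with a periodic Gaussian, then the
#' signed curvature
#' \deqn{\kappa = (x' y'' - y' x'') / (x'^2 + y'^2)^{3/2}}
#' is evaluated from periodic central differences in a y-up frame, so that
#' \eqn{\kappa > 0} marks convex and \eqn{\kappa < 0} concave boundary.
#' For a circle of radius r the result is ~ +1/r at every sample.
#'
#' A contour traced from a binary mask carries a ~0.5 px digitisation
#' band, which limits how small a curvature can be resolved over a window
#' of a given length (roughly \eqn{\delta\kappa \approx 2/\sigma^2} at
#' smoothing scale sigma). With \code{adaptive = TRUE} (default) the
#' estimator therefore works on a ladder of scales starting at
#' \code{smoothingSigma} (ratio 1.6, capped at an eighth of the contour
#' length): each sample reports the smallest scale at which the measured
#' magnitude clears that scale's noise floor, so sharp part-junction
#' corners keep the base-scale localisation while broad low-curvature
#' arcs are measured at the scale they need. With \code{adaptive = FALSE}
#' the single base scale is used throughout.
#'
#' @param sil a \code{\link{Silhouette-class}} object.
#' @param smoothingSigma base Gaussian smoothing scale in contour samples
#'   (>= 1). Default 5, which suppresses pixel-quantisation noise at the
#'   800 px frame scale.
#' @param adaptive use the multi-scale ladder (default) or a single scale.
#' @return a \code{\link{CurvatureMap-class}} object.
#' @examples
#' sil <- extractContour(discMask(256, c(127, 127), 100))
#' summary(curvatureValues(computeCurvature(sil)))  # ~ 0.01 px^-1
#' @export
computeCurvature <- function(sil, smoothingSigma = 5, adaptive = TRUE) {
  stopifnot(is(sil, "Silhouette"))
  ct <- sil@contour
  n <- nrow(ct)
  if (n < 20L) {
    stop("contour has fewer than 20 samples", call. = FALSE)
  }
  if (smoothingSigma < 1) {
    stop("smoothingSigma must be >= 1", call. = FALSE)
  }
  h <- ncol(sil@mask)
  x0 <- ct[, 1L]
  y0 <- (h - 1) - ct[, 2L]  # y-up
  oneScale <- function(sg) {
    x <- .circularSmooth(x0, sg)
    y <- .circularSmooth(y0, sg)
    x1 <- .circularDiff(x)
    y1 <- .circularDiff(y)
    denom <- (x1^2 + y1^2)^1.5
    ifelse(denom > 1e-12,
           (x1 * .circularDiff2(y) - y1 * .circularDiff2(x)) / denom, 0)
  }
  if (!adaptive) {
    kappa <- oneScale(smoothingSigma)
  } else {
    sigmas <- smoothingSigma * 1.6^(0:4)
    sigmas <- unique(pmin(sigmas, max(smoothingSigma, n / 8)))
    ks <- vapply(sigmas, oneScale, numeric(n))
    ks <- matrix(ks, nrow = n)
    kappa <- ks[, ncol(ks)]
    for (j in rev(seq_len(ncol(ks) - 1L))) {
      ok <- abs(ks[, j]) >= 2 / sigmas[j]^2
      kappa[ok] <- ks[ok, j]
    }
  }
  new("CurvatureMap", kappa = as.numeric(kappa),
      smoothingSigma = smoothingSigma)
}

#' Read / write binary masks as PNG
#'
#' Masks are stored as 8-bit grayscale PNG with foreground 255 and
#' background 0. \code{readMaskPNG} returns the package's \code{c(W, H)}
#' x-major matrix convention.
#'
#' @param path PNG file path.
#' @return \code{readMaskPNG}: binary matrix; \code{writeMaskPNG}:
#'   invisibly, the path.
#' @export
readMaskPNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    img <- img[, , 1L]
  }
  t(1L * (img > 0.5))  # png is [y, x]; transpose to [x, y]
}

#' @param mask binary matrix, dim \code{c(W, H)}.
#' @rdname readMaskPNG
#' @export
writeMaskPNG <- function(mask, path) {
  .assertMask(mask)
  png::writePNG(t(mask * 1.0), path)
  invisible(path)
}
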