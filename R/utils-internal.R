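# Internal helpers shared across modules.
#
# Mask convention: a mask is an integer/logical matrix of dim c(W, H)
# indexed mask[x + 1, y + 1] with 0-based pixel coordinates, origin at the
# top-left of the image, x rightward, y downward. This matches EBImage's
# (x, y) layout so its labelling and tracing routines apply directly.

#' @importFrom withr with_seed
.withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministic 31-bit stream seed derived from a master seed and a label,
# so every random stage of a dataset gets its own reproducible substream.
.deriveSeed <- function(master, stream) {
  bytes <- utf8ToInt(paste0("s", stream))
  h <- as.double(master) %% 2147483647
  for (b in bytes) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h %% 2147483646L + 1L)
}

.assertMask <- function(mask, what = "mask") {
  if (!is.matrix(mask)) {
    stop(what, " must be a matrix", call. = FALSE)
  }
  v <- as.vector(mask)
  if (anyNA(v) || any(v != 0 & v != 1)) {
    stop(what, " must be binary (0/1)", call. = FALSE)
  }
  invisible(TRUE)
}

# Periodic (circular) Gaussian smoothing of a closed-contour signal.
# sigma in samples; kernel truncated at 4 sigma. Uses base stats::filter
# with circular = TRUE for the periodic convolution.
#' @importFrom stats filter dnorm
.circularSmooth <- function(x, sigma) {
  if (sigma <= 0) {
    return(x)
  }
  half <- max(1L, ceiling(4 * sigma))
  if (2L * half + 1L >= length(x)) {
    half <- max(1L, floor((length(x) - 1L) / 2L))
  }
  w <- dnorm(seq(-half, half), sd = sigma)
  w <- w / sum(w)
  as.numeric(stats::filter(x, w, method = "convolution",
                           sides = 2, circular = TRUE))
}

# Periodic central differences with unit sample spacing.
.circularDiff <- function(x) {
  n <- length(x)
  (x[c(2:n, 1L)] - x[c(n, 1:(n - 1L))]) / 2
}

.circularDiff2 <- function(x) {
  n <- length(x)
  x[c(2:n, 1L)] - 2 * x + x[c(n, 1:(n - 1L))]
}

# Integer pixel offsets covering a filled disk of radius r (px).
.diskOffsets <- function(r) {
  ri <- max(0L, floor(r))
  g <- seq.int(-ri, ri)
  dx <- rep(g, times = length(g))
  dy <- rep(g, each = length(g))
  keep <- dx * dx + dy * dy <= r * r
  cbind(dx = dx[keep], dy = dy[keep])
}

# Stamp filled disks (0-based centers, per-center radii) into a W x H
# logical canvas, clipped to the frame. Offsets are cached per rounded
# radius so repeated stamping along a contour stays cheap.
.stampDisks <- function(dims, cx, cy, radius) {
  canvas <- matrix(FALSE, dims[1], dims[2])
  if (length(cx) == 0L) {
    return(canvas)
  }
  radius <- rep_len(radius, length(cx))
  rkey <- round(radius, 1)
  for (r in unique(rkey)) {
    off <- .diskOffsets(r)
    sel <- which(rkey == r)
    px <- rep(round(cx[sel]), each = nrow(off)) + off[, 1L]
    py <- rep(round(cy[sel]), each = nrow(off)) + off[, 2L]
    ok <- px >= 0 & px < dims[1] & py >= 0 & py < dims[2]
    canvas[cbind(px[ok] + 1L, py[ok] + 1L)] <- TRUE
  }
  canvas
}

# TRUE for each 0-based point that falls on a foreground pixel.
.insideMask <- function(mask, x, y) {
  dims <- dim(mask)
  xi <- round(x)
  yi <- round(y)
  ok <- xi >= 0 & xi < dims[1] & yi >= 0 & yi < dims[2]
  res <- logical(length(x))
  res[ok] <- mask[cbind(xi[ok] + 1L, yi[ok] + 1L)] > 0
  res
}

# Signed polygon area of an (x, y) point matrix in a y-up frame, given
# points stored in image (y-down) coordinates with frame height h.
.signedAreaYUp <- function(pts, h) {
  x <- pts[, 1L]
  y <- (h - 1) - pts[, 2L]
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

.isCount <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x >= 0
}

#' @importFrom utils combn unstack read.csv write.csv packageVersion
#' @importFrom stats cov setNames
NULL
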