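#' Low-level saliency map as a Monte-Carlo null density
#'
#' A lightweight multi-scale conspicuity map built from centre-surround
#' intensity contrast (difference of Gaussians, surround at twice the
#' centre scale) and orientation energy (gradient magnitude of the
#' centre-scale-smoothed image at four orientations). Channel maps are
#' normalised, combined with the given weights, and mixed with a small
#' uniform floor so the density has full support (a requirement for a
#' well-behaved Monte-Carlo null). The result is non-negative and sums to
#' one; it is pluggable anywhere a null density matrix is accepted. A
#' contrast-free image yields a uniform density.
#'
#' @param image numeric W x H matrix in [0, 1] (x-major, as masks), or a
#'   PNG path. An all-zero explicit density is rejected; a constant image
#'   is fine (uniform output).
#' @param scales Gaussian centre scales in px.
#' @param weights named numeric weights for the \code{intensity} and
#'   \code{orientation} channels.
#' @param uniformFloor fraction of mass assigned to the uniform component.
#' @return W x H density matrix, non-negative, summing to 1.
#' @export
saliencyMap <- function(image, scales = c(2, 4, 8),
                        weights = c(intensity = 1, orientation = 1),
                        uniformFloor = 0.05) {
  if (is.character(image)) {
    img <- png::readPNG(image)
    if (length(dim(img)) == 3L) {
      img <- img[, , 1L]
    }
    image <- t(img)
  }
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix or a PNG path", call. = FALSE)
  }
  if (all(image == 0) && uniformFloor <= 0) {
    stop("all-zero map with no uniform floor", call. = FALSE)
  }
  dims <- dim(image)
  intens <- matrix(0, dims[1L], dims[2L])
  orient <- matrix(0, dims[1L], dims[2L])
  for (s in scales) {
    gc <- .gaussBlur(image, s)
    gs <- .gaussBlur(image, 2 * s)
    intens <- intens + abs(gc - gs)
    gx <- (gc[c(2:dims[1L], dims[1L]), ] - gc[c(1L, 1:(dims[1L] - 1L)), ]) / 2
    gy <- (gc[, c(2:dims[2L], dims[2L])] - gc[, c(1L, 1:(dims[2L] - 1L))]) / 2
    for (th in c(0, pi / 4, pi / 2, 3 * pi / 4)) {
      orient <- orient + abs(cos(th) * gx + sin(th) * gy)
    }
  }
  combined <- matrix(0, dims[1L], dims[2L])
  for (ch in names(weights)) {
    m <- switch(ch, intensity = intens, orientation = orient,
                stop("unknown channel '", ch, "'", call. = FALSE))
    if (sum(m) > 1e-12) {
      combined <- combined + weights[[ch]] * m / sum(m)
    }
  }
  u <- 1 / prod(dims)
  if (sum(combined) <= 1e-12) {
    return(matrix(u, dims[1L], dims[2L]))
  }
  d <- (1 - uniformFloor) * combined / sum(combined) + uniformFloor * u
  d / sum(d)
}

# 2D Gaussian blur via EBImage::filter2 (circular boundary), kernel
# truncated at 3 sigma and capped below the image size.
.gaussBlur <- function(m, sigma) {
  half <- ceiling(3 * sigma)
  half <- min(half, (min(dim(m)) - 1L) %/% 2L)
  if (half < 1L) {
    return(m)
  }
  g <- dnorm(seq(-half, half), sd = sigma)
  k <- outer(g, g)
  k <- k / sum(k)
  as.matrix(EBImage::filter2(m, k))
}
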