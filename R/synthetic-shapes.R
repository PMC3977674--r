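#' Part primitives for synthetic silhouettes
#'
#' A primitive is a convex 2D solid: an ellipse (semi-axes \code{size}),
#' a capsule (core segment half-length \code{size[1]} with cap radius
#' \code{size[2]}), or a rectangle (half-extents \code{size}), placed at
#' \code{center} (0-based px) and rotated by \code{angle} degrees
#' (counter-clockwise in image coordinates).
#'
#' @param kind one of \code{"ellipse"}, \code{"capsule"},
#'   \code{"rectangle"}.
#' @param center numeric length-2, px.
#' @param size numeric length-2, px, both > 0.
#' @param angle rotation in degrees.
#' @return a list of class \code{PartPrimitive}.
#' @export
partPrimitive <- function(kind = c("ellipse", "capsule", "rectangle"),
                          center, size, angle = 0) {
  kind <- match.arg(kind)
  if (length(center) != 2L || length(size) != 2L || any(size <= 0)) {
    stop("center and size must be length-2; sizes must be > 0",
         call. = FALSE)
  }
  structure(list(kind = kind, center = as.numeric(center),
                 size = as.numeric(size), angle = as.numeric(angle)),
            class = "PartPrimitive")
}

# Rotate points into a primitive's local frame.
.toLocal <- function(p, x, y) {
  a <- -p$angle * pi / 180
  dx <- x - p$center[1L]
  dy <- y - p$center[2L]
  list(u = dx * cos(a) - dy * sin(a), v = dx * sin(a) + dy * cos(a))
}

# Vectorised point-in-primitive test (0-based px coordinates).
.insidePrimitive <- function(p, x, y) {
  l <- .toLocal(p, x, y)
  switch(p$kind,
    ellipse = (l$u / p$size[1L])^2 + (l$v / p$size[2L])^2 <= 1,
    rectangle = abs(l$u) <= p$size[1L] & abs(l$v) <= p$size[2L],
    capsule = {
      uu <- pmin(pmax(l$u, -p$size[1L]), p$size[1L])
      (l$u - uu)^2 + l$v^2 <= p$size[2L]^2
    })
}

# Closed boundary polyline of a primitive, n points, 0-based px.
.primitiveBoundary <- function(p, n = 1024L) {
  t0 <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  loc <- switch(p$kind,
    ellipse = cbind(p$size[1L] * cos(t0), p$size[2L] * sin(t0)),
    rectangle = {
      w <- p$size[1L]; h <- p$size[2L]
      per <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
      s <- per * 4
      u <- v <- numeric(n)
      a1 <- s < 1; a2 <- s >= 1 & s < 2; a3 <- s >= 2 & s < 3; a4 <- s >= 3
      u[a1] <- -w + 2 * w * s[a1];        v[a1] <- -h
      u[a2] <- w;                         v[a2] <- -h + 2 * h * (s[a2] - 1)
      u[a3] <- w - 2 * w * (s[a3] - 2);   v[a3] <- h
      u[a4] <- -w;                        v[a4] <- h - 2 * h * (s[a4] - 3)
      cbind(u, v)
    },
    capsule = {
      hl <- p$size[1L]; r <- p$size[2L]
      nn <- max(16L, n %/% 4L)
      th1 <- seq(-pi / 2, pi / 2, length.out = nn)
      th2 <- seq(pi / 2, 3 * pi / 2, length.out = nn)
      xs <- seq(hl, -hl, length.out = nn)
      rbind(cbind(hl + r * cos(th1), r * sin(th1)),
            cbind(xs, rep(r, nn)),
            cbind(-hl + r * cos(th2), r * sin(th2)),
            cbind(-xs, rep(-r, nn)))
    })
  a <- p$angle * pi / 180
  cbind(p$center[1L] + loc[, 1L] * cos(a) - loc[, 2L] * sin(a),
        p$center[2L] + loc[, 1L] * sin(a) + loc[, 2L] * cos(a))
}

# Rasterise a primitive into an existing logical canvas (bounding-box
# restricted for speed).
.rasterPrimitive <- function(canvas, p) {
  dims <- dim(canvas)
  bb <- .primitiveBoundary(p, 256L)
  lo <- pmax(floor(apply(bb, 2L, min)) - 1L, 0)
  hi <- pmin(ceiling(apply(bb, 2L, max)) + 1L, dims - 1L)
  gx <- seq.int(lo[1L], hi[1L])
  gy <- seq.int(lo[2L], hi[2L])
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  hit <- .insidePrimitive(p, px, py)
  canvas[cbind(px[hit] + 1L, py[hit] + 1L)] <- TRUE
  canvas
}

#' Rasterised disc mask
#'
#' Convenience constructor for a square binary mask containing one filled
#' disc; useful for building test shapes.
#'
#' @param framePx frame side (px).
#' @param center disc centre, 0-based px.
#' @param r radius (px).
#' @return binary matrix, dim \code{c(framePx, framePx)}.
#' @export
discMask <- function(framePx, center, r) {
  canvas <- matrix(FALSE, framePx, framePx)
  p <- partPrimitive("ellipse", center, c(r, r))
  1L * .rasterPrimitive(canvas, p)
}

# Intersection points of the boundaries of primitives a and b, found as
# inside/outside transitions while walking a's boundary, refined by
# bisection. Returns a k x 2 matrix.
.junctionPoints <- function(a, b, n = 2048L) {
  bd <- .primitiveBoundary(a, n)
  inb <- .insidePrimitive(b, bd[, 1L], bd[, 2L])
  trans <- which(inb != inb[c(2:n, 1L)])
  if (length(trans) == 0L) {
    return(matrix(numeric(0), 0L, 2L))
  }
  pts <- t(vapply(trans, function(i) {
    j <- if (i == n) 1L else i + 1L
    p0 <- bd[i, ]; p1 <- bd[j, ]
    s0 <- inb[i]
    for (k in 1:25) {
      mid <- (p0 + p1) / 2
      if (.insidePrimitive(b, mid[1L], mid[2L]) == s0) p0 <- mid else p1 <- mid
    }
    (p0 + p1) / 2
  }, numeric(2)))
  pts
}

# Built-in shape families: chains of overlapping primitives whose junction
# concavities the minima/short-cut rule should cut. Six families, echoing
# a stimulus set organised into classes by part structure.
.shapeFamilies <- function() {
  pp <- partPrimitive
  list(
    dumbbell = list(pp("ellipse", c(330, 400), c(90, 90)),
                    pp("ellipse", c(470, 400), c(90, 90))),
    chain3 = list(pp("ellipse", c(270, 400), c(80, 80)),
                  pp("ellipse", c(400, 400), c(80, 80)),
                  pp("ellipse", c(530, 400), c(80, 80))),
    arc4 = list(pp("ellipse", c(250, 500), c(70, 70)),
                pp("ellipse", c(330, 410), c(70, 70)),
                pp("ellipse", c(440, 390), c(70, 70)),
                pp("ellipse", c(550, 460), c(70, 70))),
    barbell = list(pp("capsule", c(400, 400), c(130, 45)),
                   pp("ellipse", c(250, 400), c(75, 75)),
                   pp("ellipse", c(550, 400), c(75, 75))),
    snowman = list(pp("ellipse", c(400, 290), c(120, 100)),
                   pp("ellipse", c(400, 440), c(100, 85))),
    tee = list(pp("rectangle", c(400, 480), c(50, 130)),
               pp("capsule", c(400, 300), c(150, 60)))
  )
}

#' Names of the built-in shape families
#' @return character vector of family names usable in
#'   \code{\link{generateShape}}.
#' @export
shapeFamilies <- function() {
  names(.shapeFamilies())
}

#' Generate a synthetic multi-part silhouette with known junction chords
#'
#' Places a family of overlapping convex primitives, rasterises their
#' union, and records the ground-truth junction chord (the segment joining
#' the two boundary-intersection points) for every adjacent primitive
#' pair. Metric jitter multiplies each primitive size component by an
#' independent log-uniform factor, emulating within-family metric
#' variants. Placement is retried with fresh jitter draws when the union
#' is disconnected, a primitive leaves the frame, or a junction is not a
#' clean two-point crossing; persistent failure raises an error rather
#' than returning a defective mask.
#'
#' @param familySpec a family name from \code{\link{shapeFamilies}} or a
#'   list of \code{\link{partPrimitive}} objects (>= 1).
#' @param metricJitter nonnegative jitter amplitude; size factors are
#'   drawn log-uniformly from \code{[1/(1+metricJitter), 1+metricJitter]}
#'   and must stay within (0.5, 2), so \code{metricJitter < 1}.
#' @param seed integer seed; the result is deterministic given
#'   (familySpec, metricJitter, seed).
#' @param framePx frame side (px), default 800.
#' @param familyId,exemplarId identifiers stored on the result.
#' @param maxTries placement retries before failing.
#' @return a \code{\link{SyntheticShape-class}} object.
#' @examples
#' shp <- generateShape("dumbbell", metricJitter = 0.1, seed = 7)
#' nrow(trueCuts(shp))  # one junction chord
#' @export
generateShape <- function(familySpec, metricJitter = 0, seed = 1L,
                          framePx = 800L, familyId = NULL,
                          exemplarId = "e1", maxTries = 40L) {
  if (is.character(familySpec) && length(familySpec) == 1L) {
    fam <- .shapeFamilies()
    if (!familySpec %in% names(fam)) {
      stop("unknown family '", familySpec, "'; see shapeFamilies()",
           call. = FALSE)
    }
    if (is.null(familyId)) familyId <- familySpec
    familySpec <- fam[[familySpec]]
  }
  if (!is.list(familySpec) || length(familySpec) < 1L ||
      !all(vapply(familySpec, inherits, logical(1), "PartPrimitive"))) {
    stop("familySpec must name a family or list >= 1 partPrimitive",
         call. = FALSE)
  }
  if (metricJitter < 0 || metricJitter >= 1) {
    stop("metricJitter must be in [0, 1) so size factors stay in (0.5, 2)",
         call. = FALSE)
  }
  if (is.null(familyId)) familyId <- "custom"
  .withSeed(seed, {
    for (try in seq_len(maxTries)) {
      parts <- lapply(familySpec, function(p) {
        f <- exp(runif(2L, -log1p(metricJitter), log1p(metricJitter)))
        partPrimitive(p$kind, p$center, p$size * f, p$angle)
      })
      shp <- .assembleShape(parts, framePx, familyId, exemplarId)
      if (!is.null(shp)) {
        return(shp)
      }
    }
  })
  stop("shape generation failed after ", maxTries,
       " attempts (disconnected union or degenerate junction)",
       call. = FALSE)
}

# One assembly attempt; NULL signals "retry".
.assembleShape <- function(parts, framePx, familyId, exemplarId) {
  dims <- c(framePx, framePx)
  canvas <- matrix(FALSE, framePx, framePx)
  for (p in parts) {
    bb <- .primitiveBoundary(p, 256L)
    if (min(bb) < 1 || max(bb) > framePx - 2) {
      return(NULL)  # primitive leaves the frame
    }
    canvas <- .rasterPrimitive(canvas, p)
  }
  mask <- 1L * canvas
  lab <- EBImage::bwlabel(mask)
  if (max(lab) != 1L) {
    return(NULL)
  }
  cuts <- NULL
  np <- length(parts)
  if (np > 1L) {
    for (i in seq_len(np - 1L)) {
      for (j in seq.int(i + 1L, np)) {
        jp <- .junctionPoints(parts[[i]], parts[[j]])
        if (nrow(jp) == 0L) next            # not adjacent
        others <- parts[-c(i, j)]
        covered <- vapply(seq_len(nrow(jp)), function(r) {
          any(vapply(others, .insidePrimitive, logical(1),
                     jp[r, 1L], jp[r, 2L]))
        }, logical(1))
        jp <- jp[!covered, , drop = FALSE]
        if (nrow(jp) == 0L) next            # junction swallowed by a third part
        if (nrow(jp) != 2L) {
          return(NULL)                      # not a clean crossing
        }
        if (sqrt(sum((jp[1L, ] - jp[2L, ])^2)) < 4) {
          return(NULL)                      # tangency
        }
        cuts <- rbind(cuts, c(jp[1L, ], jp[2L, ]))
      }
    }
  }
  if (is.null(cuts)) {
    cuts <- matrix(numeric(0), 0L, 4L)
  }
  colnames(cuts) <- c("x1", "y1", "x2", "y2")
  sil <- tryCatch(extractContour(mask), error = function(e) NULL)
  if (is.null(sil)) {
    return(NULL)
  }
  obj <- tryCatch(
    new("SyntheticShape", silhouette = sil, parts = parts, trueCuts = cuts,
        familyId = familyId, exemplarId = exemplarId),
    error = function(e) NULL)
  obj
}
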