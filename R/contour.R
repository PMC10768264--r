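#' Planar contour of a nodule cross-section
#'
#' A `planar_contour` is a closed simple polygon, in physical millimetres, on
#' one of the three orthogonal CT reformation planes. It is the substrate on
#' which all shape descriptors (MA, LD, PD, vertex angles) are measured.
#'
#' @param vertices Numeric matrix with two columns (x, y) in mm, one row per
#'   vertex, vertex order following the boundary. The polygon is implicitly
#'   closed; a duplicated final vertex is dropped.
#' @param plane One of `"axial"`, `"coronal"`, `"sagittal"`.
#' @param slice_index Integer slice index the contour was taken from
#'   (1-based; `1L` for free-standing 2D contours).
#'
#' @return An object of class `planar_contour`: the vertex matrix with
#'   `plane` and `slice_index` attributes.
#' @examples
#' sq <- planar_contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' polygon_area(sq)
#' @export
planar_contour <- function(vertices, plane = "axial", slice_index = 1L) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2) {
    stop("`vertices` must be a numeric matrix with 2 columns (x, y) in mm",
         call. = FALSE)
  }
  if (nrow(vertices) >= 2 &&
      isTRUE(all(vertices[1, ] == vertices[nrow(vertices), ]))) {
    vertices <- vertices[-nrow(vertices), , drop = FALSE]
  }
  if (nrow(vertices) < 3) {
    stop("a closed polygon needs at least 3 distinct vertices", call. = FALSE)
  }
  if (anyNA(vertices)) stop("contour vertices contain NA", call. = FALSE)
  plane <- match.arg(plane, c("axial", "coronal", "sagittal"))
  if (abs(signed_area(vertices)) <= .Machine$double.eps) {
    stop("degenerate contour: polygon has zero area", call. = FALSE)
  }
  structure(vertices,
            plane = plane,
            slice_index = as.integer(slice_index),
            class = c("planar_contour", "matrix", "array"))
}

#' @export
print.planar_contour <- function(x, ...) {
  cat(sprintf("<planar_contour> %d vertices on %s slice %d, area %.3f mm^2\n",
              nrow(x), attr(x, "plane"), attr(x, "slice_index"),
              polygon_area(x)))
  invisible(x)
}

contour_vertices <- function(contour) {
  v <- unclass(contour)
  attributes(v) <- list(dim = dim(v))
  v
}

# shoelace formula, signed (positive = counter-clockwise)
signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (MA)
#'
#' Absolute shoelace area of a closed polygon, in mm^2. Orientation
#' independent. This is the maximal cross-sectional area (MA) when applied to
#' the contour returned by [extract_max_cross_section()].
#'
#' @param contour A [planar_contour()] or a 2-column vertex matrix.
#' @return Area in mm^2 (a single non-negative number).
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' @export
polygon_area <- function(contour) {
  v <- as.matrix(contour)
  if (nrow(v) < 3) stop("polygon area needs at least 3 vertices", call. = FALSE)
  abs(signed_area(v))
}

#' Resample a contour to arc-length-uniform vertices
#'
#' Chord searches are exhaustive over vertices, so rasterized contours are
#' resampled to a bounded, arc-length-uniform vertex set before measurement.
#' Resampling starts at the first vertex and walks the closed boundary at
#' constant arc-length steps.
#'
#' @param contour A [planar_contour()].
#' @param n Number of output vertices. Default: the current vertex count
#'   clamped to `bounds`.
#' @param bounds Length-2 integer vector, the (min, max) vertex count used
#'   when `n` is `NULL`.
#' @return A [planar_contour()] with `n` vertices.
#' @export
resample_contour <- function(contour, n = NULL, bounds = c(360L, 2000L)) {
  v <- as.matrix(contour)
  if (is.null(n)) n <- min(max(nrow(v), bounds[1]), bounds[2])
  n <- as.integer(n)
  if (n < 3) stop("cannot resample to fewer than 3 vertices", call. = FALSE)
  vc <- rbind(v, v[1, ])
  seg <- sqrt(rowSums(diff(vc)^2))
  s <- c(0, cumsum(seg))
  per <- s[length(s)]
  if (per <= 0) stop("degenerate contour: zero perimeter", call. = FALSE)
  keep <- !duplicated(s)          # drop zero-length segments
  s <- s[keep]
  vc <- vc[keep, , drop = FALSE]
  target <- seq(0, per, length.out = n + 1)[-(n + 1)]
  out <- cbind(stats::approx(s, vc[, 1], xout = target)$y,
               stats::approx(s, vc[, 2], xout = target)$y)
  planar_contour(out, attr(contour, "plane") %||% "axial",
                 attr(contour, "slice_index") %||% 1L)
}

#' Smooth a contour with a circular moving average
#'
#' Raster-derived boundaries carry half-voxel staircase wiggle that makes
#' near-tied chords (and hence the LD/PD endpoints) wander. A short
#' periodic moving average over arc-length-uniform vertices suppresses that
#' wiggle; for a boundary of curvature radius rho the induced inward bias
#' is about `window_mm^2 / (24 rho)` — negligible at the default window.
#' Analytic contours should not be smoothed (`window_mm = 0` is the
#' identity).
#'
#' @param contour A [planar_contour()] with (approximately) uniform vertex
#'   spacing, e.g. from [resample_contour()].
#' @param window_mm Full smoothing window along the boundary, mm.
#' @return A [planar_contour()].
#' @export
smooth_contour <- function(contour, window_mm = 0.3) {
  if (window_mm <= 0) return(contour)
  v <- as.matrix(contour)
  n <- nrow(v)
  per <- sum(sqrt(rowSums((rbind(v, v[1, ])[-1, ] - rbind(v, v[1, ])[-(n + 1), ])^2)))
  half <- round(window_mm / 2 / (per / n))
  if (half < 1) return(contour)
  k <- 2L * as.integer(half) + 1L
  wrap <- rbind(v[(n - half + 1):n, , drop = FALSE], v,
                v[1:half, , drop = FALSE])
  sm <- cbind(stats::filter(wrap[, 1], rep(1 / k, k)),
              stats::filter(wrap[, 2], rep(1 / k, k)))
  sm <- sm[(half + 1):(half + n), , drop = FALSE]
  planar_contour(sm, attr(contour, "plane") %||% "axial",
                 attr(contour, "slice_index") %||% 1L)
}
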