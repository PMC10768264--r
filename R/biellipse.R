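#' Bi-ellipse nodule cross-section parameters
#'
#' The synthetic nodule family is a "bi-ellipse": a left half-ellipse with
#' semi-axes (`a1`, `c`) joined to a right half-ellipse (`a2`, `c`) on their
#' shared minor axis. It is the minimal shape family for which every
#' descriptor this package measures has a closed form: the longest diameter
#' is the joined major axis (`a1 + a2`), the perpendicular diameter the
#' shared minor axis (`2c`), and the two LD-endpoint angles are
#' `2 atan(c/a1)` and `2 atan(c/a2)`. Unequal `a1`, `a2` emulates a mass
#' growing asymmetrically about the chord intersection, which is exactly
#' what the BiA/SmA ratio quantifies.
#'
#' @param a1 Left semi-major axis, mm.
#' @param a2 Right semi-major axis, mm; `a1 >= a2 >= c` so LD is the major
#'   axis and PD the minor axis.
#' @param c Shared semi-minor axis, mm (> 0).
#' @param rotation In-plane rotation, degrees.
#' @param translation Length-2 offset (x, y), mm.
#' @param noise_sd SD of radial boundary jitter, mm (>= 0).
#' @return A `biellipse_params` list.
#' @examples
#' biellipse_params(6, 4, 3)
#' @export
biellipse_params <- function(a1, a2, c, rotation = 0, translation = c(0, 0),
                             noise_sd = 0) {
  if (!(a1 >= a2 && a2 >= c && c > 0)) {
    stop("bi-ellipse parameters require a1 >= a2 >= c > 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(a1 = a1, a2 = a2, c = c, rotation = rotation,
                 translation = as.numeric(translation), noise_sd = noise_sd),
            class = "biellipse_params")
}

#' Closed-form ground truth of a bi-ellipse
#'
#' All descriptors of the noise-free shape: `LD = a1 + a2`, `PD = 2c`,
#' angle at the far LD endpoint `2 atan(c/a1)`, angle at the near endpoint
#' `2 atan(c/a2)` (the larger of the two, since the endpoint nearer the
#' chord intersection carries the bigger angle), and
#' `MA = pi * c * (a1 + a2) / 2`.
#'
#' @param params A [biellipse_params()].
#' @return One-row tibble: `LD_mm`, `PD_mm`, `BiA_deg`, `SmA_deg`, `LD_PD`,
#'   `BiA_SmA`, `MA_mm2`.
#' @export
biellipse_truth <- function(params) {
  p <- params
  angle_far <- 2 * atan(p$c / p$a1) * 180 / pi
  angle_near <- 2 * atan(p$c / p$a2) * 180 / pi
  tibble::tibble(
    LD_mm = p$a1 + p$a2,
    PD_mm = 2 * p$c,
    BiA_deg = max(angle_far, angle_near),
    SmA_deg = min(angle_far, angle_near),
    LD_PD = (p$a1 + p$a2) / (2 * p$c),
    BiA_SmA = max(angle_far, angle_near) / min(angle_far, angle_near),
    MA_mm2 = pi * p$c * (p$a1 + p$a2) / 2
  )
}

# dense boundary of the canonical (unrotated, origin-centred) bi-ellipse,
# starting at (a2, 0), counter-clockwise
biellipse_boundary <- function(p, n_dense = 4096L) {
  t_right <- seq(-pi / 2, pi / 2, length.out = n_dense %/% 2)
  t_left <- seq(pi / 2, 3 * pi / 2, length.out = n_dense %/% 2)
  x <- c(p$a2 * cos(t_right), p$a1 * cos(t_left))
  y <- c(p$c * sin(t_right), p$c * sin(t_left))
  # rotate so the path starts on the positive x axis and stays simple
  keep <- !duplicated(cbind(x, y))
  cbind(x, y)[keep, , drop = FALSE]
}

#' Generate a bi-ellipse polygon with its ground truth
#'
#' Builds the bi-ellipse boundary with arc-length-uniform vertices, then
#' applies radial jitter (seeded by the caller via [set.seed()]), rotation
#' and translation. Ground truth is computed from the parameters before
#' noise.
#'
#' @param params A [biellipse_params()].
#' @param n_vertices Number of polygon vertices (>= 64).
#' @return List with `contour` (a [planar_contour()]) and `truth` (the
#'   [biellipse_truth()] tibble).
#' @examples
#' make_biellipse_polygon(biellipse_params(6, 4, 3), n_vertices = 360)$truth
#' @export
make_biellipse_polygon <- function(params, n_vertices = 720L) {
  stopifnot(inherits(params, "biellipse_params"))
  if (n_vertices < 64) stop("n_vertices must be >= 64", call. = FALSE)
  v <- biellipse_boundary(params, n_dense = max(4096L, 8L * n_vertices))
  v <- as.matrix(resample_contour(planar_contour(v), n = n_vertices))
  if (params$noise_sd > 0) {
    r <- sqrt(rowSums(v^2))
    theta <- atan2(v[, 2], v[, 1])
    r <- pmax(r + stats::rnorm(nrow(v), 0, params$noise_sd), 1e-6)
    v <- cbind(r * cos(theta), r * sin(theta))
  }
  phi <- params$rotation * pi / 180
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  v <- v %*% t(rot)
  v <- sweep(v, 2, params$translation, "+")
  list(contour = planar_contour(v), truth = biellipse_truth(params))
}

#' Extrude a bi-ellipse into a 3D mask
#'
#' Builds a volume whose axial slices are scaled copies of the bi-ellipse
#' cross-section under a strictly peaked extrusion profile, so the central
#' slice is the unique maximal cross-section. The slice grid is symmetric
#' about z = 0 with an odd slice count, placing one slice exactly at the
#' peak. Voxels are classified by the star-shaped boundary-radius function
#' of the (possibly jittered, rotated, translated) polygon.
#'
#' @param params A [biellipse_params()].
#' @param spacing Voxel spacing (dx, dy, dz) mm; a scalar is recycled.
#' @param extrusion_profile Function of normalized height `u` in \[-1, 1\]
#'   returning the in-plane scale factor; default `sqrt(1 - u^2)`
#'   (ellipsoid-like). Must peak at `u = 0` with value 1.
#' @param half_height Extrusion half-height, mm; default `c` (so the default
#'   solid is an ellipsoid when `a1 = a2`).
#' @param n_vertices Boundary vertices used for rasterization.
#' @return A [volume_mask()]. If the minor axis spans fewer than 4 voxels
#'   (`c / min in-plane spacing < 4`), a warning flags the coarse raster.
#' @export
make_biellipse_volume <- function(params, spacing = 0.2,
                                  extrusion_profile = function(u) sqrt(pmax(0, 1 - u^2)),
                                  half_height = NULL, n_vertices = 1024L) {
  stopifnot(inherits(params, "biellipse_params"))
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("spacing must be > 0", call. = FALSE)
  if (params$c / min(spacing[1:2]) < 4) {
    warning("spacing too coarse to represent the minor axis (c/spacing < 4)")
  }
  v <- as.matrix(make_biellipse_polygon(params, n_vertices)$contour)
  ctr <- params$translation
  rel <- sweep(v, 2, ctr)
  theta_b <- atan2(rel[, 2], rel[, 1])
  r_b <- sqrt(rowSums(rel^2))
  ord <- order(theta_b)
  theta_b <- theta_b[ord]; r_b <- r_b[ord]
  keep <- !duplicated(theta_b)
  theta_b <- theta_b[keep]; r_b <- r_b[keep]
  # periodic padding for interpolation across the -pi/pi seam
  th <- c(theta_b[length(theta_b)] - 2 * pi, theta_b, theta_b[1] + 2 * pi)
  rr <- c(r_b[length(r_b)], r_b, r_b[1])
  radius_at <- function(theta) stats::approx(th, rr, xout = theta)$y

  rmax <- max(r_b)
  h <- half_height %||% params$c
  nx <- ceiling(2 * (rmax + spacing[1]) / spacing[1])
  ny <- ceiling(2 * (rmax + spacing[2]) / spacing[2])
  nz <- ceiling(2 * h / spacing[3])
  if (nz %% 2 == 0) nz <- nz + 1L        # odd count puts a slice at z = 0
  xs <- (seq_len(nx) - (nx + 1) / 2) * spacing[1] + ctr[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * spacing[2] + ctr[2]
  zs <- (seq_len(nz) - (nz + 1) / 2) * spacing[3]

  gx <- rep(xs, times = ny) - ctr[1]
  gy <- rep(ys, each = nx) - ctr[2]
  g_theta <- atan2(gy, gx)
  g_r <- sqrt(gx^2 + gy^2)
  r_bound <- radius_at(g_theta)

  vox <- array(0L, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    s <- extrusion_profile(zs[k] / h)
    if (s <= 0) next
    vox[, , k] <- as.integer(g_r <= s * r_bound)
  }
  volume_mask(vox, spacing)
}

#' Solve bi-ellipse parameters from target descriptors
#'
#' Inverse of the closed-form ground truth: given targets for LD, LD/PD and
#' BiA/SmA, finds `(a1, a2, c)` with `a1 + a2 = LD`, `2c = LD / (LD/PD)` and
#' `atan(c/a2) / atan(c/a1) = BiA/SmA` by monotone 1-D root finding on
#' `a2 in [c, LD/2]`. Used to hit prescribed cohort feature distributions
#' exactly.
#'
#' @param ld Target longest diameter, mm (> 0).
#' @param ld_pd Target LD/PD ratio (>= 1).
#' @param bia_sma Target BiA/SmA ratio (>= 1). Feasibility requires
#'   `bia_sma <= atan(1) / atan(c / (ld - c))`, the value attained at the
#'   `a2 = c` boundary; infeasible targets raise an error stating the bound.
#' @param ... Passed to [biellipse_params()] (rotation, translation,
#'   noise_sd).
#' @return A [biellipse_params()] whose [biellipse_truth()] reproduces the
#'   targets to ~1e-9.
#' @examples
#' p <- params_from_targets(10, 10 / 6, 73.7398 / 53.1301)
#' c(p$a1, p$a2, p$c)
#' @export
params_from_targets <- function(ld, ld_pd, bia_sma, ...) {
  if (ld <= 0) stop("ld must be > 0", call. = FALSE)
  if (ld_pd < 1) stop("ld_pd must be >= 1", call. = FALSE)
  if (bia_sma < 1) stop("bia_sma must be >= 1", call. = FALSE)
  cc <- ld / (2 * ld_pd)
  ratio_at <- function(a2) atan(cc / a2) / atan(cc / (ld - a2))
  if (abs(ld_pd - 1) < 1e-12) {
    if (bia_sma > 1 + 1e-9) {
      stop("infeasible targets: ld_pd = 1 forces a circle, so bia_sma must be 1",
           call. = FALSE)
    }
    return(biellipse_params(cc, cc, cc, ...))
  }
  rmax <- ratio_at(cc)
  if (bia_sma > rmax + 1e-12) {
    stop(sprintf(
      "infeasible targets: bia_sma = %.6g exceeds the maximum %.6g attainable at a2 = c (= %.6g mm) for ld = %.6g, ld_pd = %.6g",
      bia_sma, rmax, cc, ld, ld_pd), call. = FALSE)
  }
  if (abs(bia_sma - 1) < 1e-12) {
    a2 <- ld / 2
  } else if (abs(bia_sma - rmax) < 1e-12) {
    a2 <- cc
  } else {
    a2 <- stats::uniroot(function(a2) ratio_at(a2) - bia_sma,
                         lower = cc, upper = ld / 2, tol = 1e-13)$root
  }
  biellipse_params(ld - a2, a2, cc, ...)
}
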