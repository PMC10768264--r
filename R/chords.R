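#' Longest diameter (LD) of a contour
#'
#' The longest diameter is the longest chord of the maximal cross-section:
#' the maximal Euclidean distance over all pairs of boundary vertices
#' (exhaustive pair search; the diameter of a polygon is attained at
#' vertices). Ties are broken deterministically by the lowest vertex index
#' pair.
#'
#' On raster-derived contours the chord length is nearly flat in the
#' endpoint position wherever the boundary curvature is low, so the argmax
#' endpoints wander laterally by a noise-dependent amount that tilts the
#' whole LD/PD construction. With `refine_band > 0` each endpoint is
#' replaced by the centroid of the contiguous boundary arc whose distance
#' to the opposite endpoint is within `refine_band` (relative) of the
#' maximum — symmetric about the true extreme point for a locally
#' quadratic tip — and the two endpoints are refined alternately. Leave
#' `refine_band = 0` (the default) for analytic polygons.
#'
#' @param contour A [planar_contour()] (or 2-column vertex matrix). For
#'   rasterized masks the contour should first pass through
#'   [resample_contour()] so the search is arc-length uniform.
#' @param refine_band Relative chord-length band used to stabilize the
#'   endpoints of raster-derived contours; 0 = raw vertex argmax.
#' @return A `ggn_chord`: list with endpoints `p1` (A), `p2` (B), `length`
#'   in mm and the vertex indices used.
#' @examples
#' sq <- planar_contour(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
#' longest_diameter(sq)$length  # 2 * sqrt(2)
#' @export
longest_diameter <- function(contour, refine_band = 0) {
  v <- as.matrix(contour)
  n <- nrow(v)
  if (n < 3) stop("degenerate polygon: fewer than 3 vertices", call. = FALSE)
  d <- as.matrix(stats::dist(v))
  dmax <- max(d)
  if (dmax <= 0) stop("degenerate polygon: all vertices coincide", call. = FALSE)
  hits <- which(d == dmax, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i <- hits[1, 1]; j <- hits[1, 2]
  if (refine_band <= 0) return(new_chord(v[i, ], v[j, ], i = i, j = j))
  p_a <- v[i, ]; p_b <- v[j, ]
  for (it in 1:2) {
    p_a <- tip_centroid(v, p_b, refine_band)
    p_b <- tip_centroid(v, p_a, refine_band)
  }
  new_chord(p_a, p_b, i = i, j = j)
}

# centroid of the contiguous boundary arc whose distance to `ref` is
# within `band` (relative) of the maximum
tip_centroid <- function(v, ref, band) {
  n <- nrow(v)
  d <- sqrt(rowSums(sweep(v, 2, ref)^2))
  i0 <- which.max(d)
  th <- d[i0] * (1 - band)
  lo <- i0
  for (step in seq_len(n - 1L)) {
    j <- ((lo - 2L) %% n) + 1L
    if (d[j] < th || j == i0) break
    lo <- j
  }
  hi <- i0
  for (step in seq_len(n - 1L)) {
    j <- (hi %% n) + 1L
    if (d[j] < th || j == lo) break
    hi <- j
  }
  ids <- if (lo <= hi) lo:hi else c(lo:n, 1:hi)
  colMeans(v[ids, , drop = FALSE])
}

new_chord <- function(p1, p2, ...) {
  structure(list(p1 = as.numeric(p1), p2 = as.numeric(p2),
                 length = sqrt(sum((p1 - p2)^2)), ...),
            class = "ggn_chord")
}

#' @export
print.ggn_chord <- function(x, ...) {
  cat(sprintf("<chord> (%.3f, %.3f) -- (%.3f, %.3f), length %.4f mm\n",
              x$p1[1], x$p1[2], x$p2[1], x$p2[2], x$length))
  invisible(x)
}

#' Greatest perpendicular diameter (PD)
#'
#' The perpendicular diameter is the longest chord of the contour that is
#' exactly perpendicular to the longest diameter AB and crosses it, so that
#' the two chords intersect at an interior point O. Candidate perpendicular
#' lines are swept along AB at `n_steps` equally spaced interior foot points
#' (step = LD / `n_steps`); at each foot the chord is the even-odd
#' intersection of the perpendicular line with the polygon. For non-convex
#' sections giving several intersection segments, the segment that straddles
#' line AB is taken (so O exists); if none straddles, the longest.
#'
#' The maximal width of a rounded cross-section varies only quadratically
#' around its peak, so at finite raster resolution the raw argmax of the
#' sweep wanders over a plateau of near-identical chord lengths. The foot
#' is therefore stabilized by a piecewise-quadratic apex fit to the
#' squared width profile over the near-maximal region (relative width drop
#' `peak_band`); for elliptic flanks the squared width is exactly
#' quadratic in the foot coordinate, so the fitted apex recovers the true
#' peak even when the two flanks are unequally curved, and pooling the
#' whole region suppresses raster aliasing. The reported chord is measured
#' at the fitted foot, so its length is within `peak_band` of the raw
#' sweep maximum.
#'
#' @param contour A [planar_contour()].
#' @param ld The chord returned by [longest_diameter()] on the same contour.
#' @param n_steps Sweep resolution along AB (default 500, i.e. steps of
#'   LD/500; see the methods vignette for the choice).
#' @param peak_band Relative width drop bounding the apex-fit region.
#' @return A `ggn_chord` with endpoints `p1` (C) and `p2` (D) on opposite
#'   sides of AB where possible, plus `foot` (distance of O from A along AB)
#'   and `straddles_ld` (logical).
#' @export
perpendicular_diameter <- function(contour, ld, n_steps = 500L,
                                   peak_band = 0.12) {
  v <- as.matrix(contour)
  n <- nrow(v)
  if (n < 3) stop("degenerate polygon", call. = FALSE)
  a <- ld$p1
  u <- (ld$p2 - ld$p1) / ld$length          # unit vector A -> B
  w <- c(-u[2], u[1])                        # unit normal
  rel <- sweep(v, 2, a)
  pu <- rel %*% u                            # coordinates along AB
  pw <- rel %*% w                            # signed offset from line AB
  # half-offset interior grid so feet are strictly inside segment AB
  feet <- (seq_len(n_steps) - 0.5) / n_steps * ld$length

  pu_next <- c(pu[-1], pu[1])
  pw_next <- c(pw[-1], pw[1])

  # even-odd chord of the perpendicular line whose foot sits at arc
  # coordinate s along AB; NULL at tangencies
  chord_at <- function(s) {
    crossing <- (pu <= s) != (pu_next <= s)   # half-open crossing rule
    if (!any(crossing)) return(NULL)
    t <- (s - pu[crossing]) / (pu_next[crossing] - pu[crossing])
    wc <- sort(pw[crossing] + t * (pw_next[crossing] - pw[crossing]))
    m <- length(wc)
    if (m < 2 || m %% 2 != 0) return(NULL)
    lo_w <- wc[seq(1, m, by = 2)]
    hi_w <- wc[seq(2, m, by = 2)]
    straddle <- lo_w <= 0 & hi_w >= 0
    k <- if (any(straddle)) which(straddle)[1] else which.max(hi_w - lo_w)
    list(lo = lo_w[k], hi = hi_w[k], len = hi_w[k] - lo_w[k],
         straddle = straddle[k])
  }

  prof <- lapply(feet, chord_at)
  res_len <- vapply(prof, function(p) if (is.null(p)) NA_real_ else p$len, 0)
  if (all(is.na(res_len)) || max(res_len, na.rm = TRUE) <= 0) {
    stop("no perpendicular chord intersects the interior (degenerate sliver)",
         call. = FALSE)
  }
  imax <- which.max(res_len)
  lmax <- res_len[imax]

  # Peak localization. Around its maximum the squared width of an
  # elliptic flank is exactly quadratic in the foot coordinate, so a
  # piecewise-quadratic apex model y = y0 - beta_left (s - b)^2 (s < b),
  # y0 - beta_right (s - b)^2 (s >= b) is fitted by least squares to w^2
  # over the contiguous near-maximal region (width within `peak_band` of
  # the maximum), scanning the apex b over the sweep grid; this pools the
  # whole peak region and is insensitive to raster aliasing that defeats a
  # raw argmax. Degenerate fits (true plateaus, narrow regions) fall back
  # to the argmax foot.
  th <- lmax * (1 - peak_band)
  lo_r <- imax
  while (lo_r > 1L && !is.na(res_len[lo_r - 1L]) && res_len[lo_r - 1L] >= th) {
    lo_r <- lo_r - 1L
  }
  hi_r <- imax
  while (hi_r < n_steps && !is.na(res_len[hi_r + 1L]) && res_len[hi_r + 1L] >= th) {
    hi_r <- hi_r + 1L
  }
  foot <- feet[imax]
  if (hi_r - lo_r + 1L >= 8L) {
    reg <- lo_r:hi_r
    s_reg <- feet[reg]
    y_reg <- res_len[reg]^2
    apex_sse <- function(b) {
      ds2 <- (s_reg - b)^2
      x1 <- -ds2 * (s_reg < b)
      x2 <- -ds2 * (s_reg >= b)
      sum(stats::lm.fit(cbind(1, x1, x2), y_reg)$residuals^2)
    }
    sse <- vapply(s_reg, apex_sse, 0)
    b_best <- s_reg[which.min(sse)]
    step <- ld$length / n_steps
    opt <- stats::optimize(apex_sse, c(b_best - step, b_best + step),
                           tol = step / 100)
    b_best <- if (opt$objective <= min(sse)) opt$minimum else b_best
    foot <- min(max(b_best, s_reg[1]), s_reg[length(s_reg)])
  }
  best <- chord_at(foot)
  if (is.null(best)) {                       # tangency at the refined foot
    foot <- feet[imax]
    best <- chord_at(foot)
  }
  c_pt <- a + foot * u + best$hi * w
  d_pt <- a + foot * u + best$lo * w
  new_chord(c_pt, d_pt, foot = foot, straddles_ld = best$straddle)
}

#' Vertex angles of the LD/PD quadrilateral
#'
#' The endpoints A, B of the longest diameter and C, D of the perpendicular
#' diameter span the quadrilateral ACBD; AB and CD intersect at an interior
#' point O. The angles at the LD endpoints are measured: `angle_A` between
#' rays A->C and A->D, `angle_B` between rays B->C and B->D. The larger is
#' the big angle (BiA), the smaller the small angle (SmA) — the vertex
#' nearer O carries the larger angle, and the BiA/SmA ratio grows with the
#' asymmetry of the mass about O.
#'
#' @param ld,pd Chords from [longest_diameter()] and
#'   [perpendicular_diameter()] on the same contour.
#' @return A `ggn_quad`: list with vertices `A`, `B`, `C`, `D`, intersection
#'   `O`, all four vertex angles in degrees, and `BiA`, `SmA`.
#' @export
quadrilateral_angles <- function(ld, pd) {
  a <- ld$p1; b <- ld$p2; cc <- pd$p1; d <- pd$p2
  o <- segment_intersection(a, b, cc, d)
  if (is.null(o)) {
    stop("LD and PD segments do not intersect: quadrilateral angles undefined",
         call. = FALSE)
  }
  ang <- function(p, q1, q2) {
    v1 <- q1 - p; v2 <- q2 - p
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    acos(min(1, max(-1, cosang))) * 180 / pi
  }
  angle_a <- ang(a, cc, d)
  angle_b <- ang(b, cc, d)
  structure(list(A = a, B = b, C = cc, D = d, O = o,
                 angle_A = angle_a, angle_B = angle_b,
                 angle_C = ang(cc, a, b), angle_D = ang(d, a, b),
                 BiA = max(angle_a, angle_b), SmA = min(angle_a, angle_b)),
            class = "ggn_quad")
}

# intersection of segments p1-p2 and p3-p4, NULL if they do not cross
segment_intersection <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1; d2 <- p4 - p3
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-14) return(NULL)
  dp <- p3 - p1
  t <- (dp[1] * d2[2] - dp[2] * d2[1]) / den
  s <- (dp[1] * d1[2] - dp[2] * d1[1]) / den
  eps <- 1e-10
  if (t < -eps || t > 1 + eps || s < -eps || s > 1 + eps) return(NULL)
  p1 + t * d1
}

#' @export
print.ggn_quad <- function(x, ...) {
  cat(sprintf("<quadrilateral> angle_A %.4f, angle_B %.4f, BiA/SmA %.4f\n",
              x$angle_A, x$angle_B, bia_sma_ratio(x$BiA, x$SmA)))
  invisible(x)
}

#' Big-angle / small-angle ratio (BiA/SmA)
#'
#' Ratio of the larger to the smaller LD-endpoint angle of the LD/PD
#' quadrilateral; >= 1, with 1 meaning the mass is symmetric about the chord
#' intersection. For instance a big angle of 77.03 degrees over a small
#' angle of 60.55 degrees gives a ratio of about 1.2722.
#'
#' @param biA,smA Angles in degrees with `biA >= smA > 0`.
#' @return The dimensionless ratio `biA / smA`.
#' @examples
#' bia_sma_ratio(77.03, 60.55)
#' @export
bia_sma_ratio <- function(biA, smA) {
  if (any(smA <= 0)) stop("SmA must be positive", call. = FALSE)
  if (any(biA < smA)) stop("BiA must be >= SmA", call. = FALSE)
  biA / smA
}
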