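#' Shape descriptors of one lesion
#'
#' Runs the full measurement chain on a segmented lesion: maximal
#' cross-section selection (for volumes), area (MA), longest diameter (LD),
#' greatest perpendicular diameter (PD), the LD/PD-quadrilateral vertex
#' angles, and the two ratios LD/PD and BiA/SmA. Deterministic for a fixed
#' input and configuration.
#'
#' MA is measured on the raw boundary; the chord searches run on an
#' arc-length-uniform resampling of it (see [resample_contour()]).
#'
#' @param x A [volume_mask()] or [planar_contour()].
#' @param lesion_id Identifier attached to the output row (and to error
#'   messages).
#' @param sweep_steps Perpendicular-diameter sweep resolution, passed to
#'   [perpendicular_diameter()].
#' @param resample_bounds (min, max) vertex counts for the chord search,
#'   passed to [resample_contour()].
#' @param ... Passed between methods.
#' @return A one-row tibble with columns `lesion_id`, `plane`, `MA_mm2`,
#'   `LD_mm`, `PD_mm`, `BiA_deg`, `SmA_deg`, `LD_PD`, `BiA_SmA`, `flags`.
#' @examples
#' shp <- make_biellipse_polygon(biellipse_params(6, 4, 3), n_vertices = 720)
#' shape_features(shp$contour)
#' @export
shape_features <- function(x, ...) UseMethod("shape_features")

#' @param sigma Slice pre-smoothing bandwidth in voxels, see
#'   [extract_max_cross_section()].
#' @param boundary_smooth_mm Boundary moving-average window applied to the
#'   raster-derived contour before chord measurement, see
#'   [smooth_contour()].
#' @rdname shape_features
#' @export
shape_features.volume_mask <- function(x, lesion_id = "lesion", sigma = 0.7,
                                       boundary_smooth_mm = 0.5, ...) {
  contour <- with_lesion_id(lesion_id, extract_max_cross_section(x, sigma = sigma))
  shape_features(contour, lesion_id = lesion_id,
                 boundary_smooth_mm = boundary_smooth_mm, ...)
}

#' @rdname shape_features
#' @export
shape_features.planar_contour <- function(x, lesion_id = "lesion",
                                          sweep_steps = 500L,
                                          resample_bounds = c(360L, 2000L),
                                          boundary_smooth_mm = 0,
                                          ld_refine_band = NULL,
                                          ...) {
  with_lesion_id(lesion_id, {
    ma <- polygon_area(x)
    rc <- resample_contour(x, bounds = resample_bounds)
    rc <- smooth_contour(rc, boundary_smooth_mm)
    # endpoint stabilization only matters (and is only safe) when the
    # boundary carries raster noise, which boundary_smooth_mm signals
    if (is.null(ld_refine_band)) {
      ld_refine_band <- if (boundary_smooth_mm > 0) 2e-3 else 0
    }
    ld <- longest_diameter(rc, refine_band = ld_refine_band)
    pd <- perpendicular_diameter(rc, ld, n_steps = sweep_steps)
    quad <- quadrilateral_angles(ld, pd)
    tibble::tibble(
      lesion_id = as.character(lesion_id),
      plane = attr(x, "plane") %||% "axial",
      MA_mm2 = ma,
      LD_mm = ld$length,
      PD_mm = pd$length,
      BiA_deg = quad$BiA,
      SmA_deg = quad$SmA,
      LD_PD = ld$length / pd$length,
      BiA_SmA = bia_sma_ratio(quad$BiA, quad$SmA),
      flags = ""
    )
  })
}

with_lesion_id <- function(lesion_id, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", lesion_id, conditionMessage(e)), call. = FALSE)
  })
}

#' Measure a batch of lesions
#'
#' Applies [shape_features()] to each element; a lesion whose geometry is
#' degenerate (no boundary, PD search failure, non-crossing chords) yields a
#' flagged row with `NA` features and the failure reason in `flags` instead
#' of aborting the batch. Flagged rows are excluded from cohort statistics
#' downstream.
#'
#' @param lesions A list of [volume_mask()] / [planar_contour()] objects
#'   (optionally named; names become lesion ids).
#' @param lesion_ids Character vector of ids; defaults to list names or
#'   `lesion_001`-style ids.
#' @inheritParams shape_features
#' @return A tibble with one row per lesion.
#' @export
shape_features_table <- function(lesions, lesion_ids = NULL, ...) {
  if (is.null(lesion_ids)) {
    lesion_ids <- names(lesions) %||%
      sprintf("lesion_%03d", seq_along(lesions))
  }
  purrr::map2_dfr(lesions, lesion_ids, function(obj, id) {
    tryCatch(shape_features(obj, lesion_id = id, ...),
             error = function(e) flagged_row(id, conditionMessage(e)))
  })
}

flagged_row <- function(id, reason) {
  tibble::tibble(lesion_id = as.character(id), plane = NA_character_,
                 MA_mm2 = NA_real_, LD_mm = NA_real_, PD_mm = NA_real_,
                 BiA_deg = NA_real_, SmA_deg = NA_real_, LD_PD = NA_real_,
                 BiA_SmA = NA_real_, flags = reason)
}
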