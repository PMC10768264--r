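#' Plot an ROC curve
#'
#' The empirical staircase with the chance diagonal and the Youden
#' operating point.
#'
#' @param object A `ggn_roc` from [empirical_roc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ggn_roc <- function(object, ...) {
  pts <- tidy(object)
  op <- tibble::tibble(fpr = 1 - object$spec_at_cutoff,
                       tpr = object$sens_at_cutoff)
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = op, ggplot2::aes(x = .data$fpr, y = .data$tpr),
                        colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC %.4f (95%% CI %.4f-%.4f)",
                      object$auc, object$auc_ci_95[1], object$auc_ci_95[2]),
      subtitle = sprintf("Youden cut-off >= %.4g (sens %.3f, spec %.3f)",
                         object$youden_cutoff, object$sens_at_cutoff,
                         object$spec_at_cutoff)) +
    ggplot2::theme_minimal()
}

#' Plot a nodule contour with its measurement chords
#'
#' Draws the cross-section boundary and, optionally, the longest diameter
#' AB, the perpendicular diameter CD and their intersection O — the
#' construction whose endpoint angles yield the BiA/SmA ratio.
#'
#' @param object A [planar_contour()].
#' @param measure If `TRUE` (default) overlay LD, PD and O.
#' @param ... Passed to [shape_features()]'s chord search
#'   (`sweep_steps`, `resample_bounds`).
#' @return A ggplot object.
#' @export
autoplot.planar_contour <- function(object, measure = TRUE, ...) {
  v <- as.matrix(object)
  df <- tibble::tibble(x = c(v[, 1], v[1, 1]), y = c(v[, 2], v[1, 2]))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
  if (measure) {
    rc <- resample_contour(object)
    ld <- longest_diameter(rc)
    pd <- perpendicular_diameter(rc, ld)
    quad <- quadrilateral_angles(ld, pd)
    chords <- tibble::tibble(
      x = c(ld$p1[1], pd$p1[1]), y = c(ld$p1[2], pd$p1[2]),
      xend = c(ld$p2[1], pd$p2[1]), yend = c(ld$p2[2], pd$p2[2]),
      chord = c("LD (A-B)", "PD (C-D)"))
    p <- p +
      ggplot2::geom_segment(
        data = chords,
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, colour = .data$chord)) +
      ggplot2::annotate("point", x = quad$O[1], y = quad$O[2], shape = 3) +
      ggplot2::labs(
        colour = NULL,
        subtitle = sprintf("LD %.2f mm, PD %.2f mm, BiA/SmA %.4f",
                           ld$length, pd$length,
                           bia_sma_ratio(quad$BiA, quad$SmA)))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-feature group distributions of a cohort
#'
#' Boxplots (with jittered points) of the shape descriptors by pathology
#' group.
#'
#' @param cohort Data frame with a `group` column and feature columns.
#' @param features Feature column names; defaults as in
#'   [compare_groups()].
#' @return A ggplot object.
#' @export
plot_cohort_features <- function(cohort, features = NULL) {
  if (is.null(features)) {
    features <- intersect(c("MA_mm2", "BiA_deg", "BiA_SmA", "LD_mm", "LD_PD"),
                          names(cohort))
  }
  long <- tidyr::pivot_longer(
    dplyr::select(cohort, "group", dplyr::all_of(features)),
    -"group", names_to = "feature", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
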