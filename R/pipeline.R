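#' Simulate a cohort and write it to disk
#'
#' Front end to [sample_cohort()]: writes the ground-truth cohort table as
#' CSV, one boundary-contour CSV per lesion (columns x, y in mm) or NIfTI
#' masks, and a JSON sidecar recording the seed and a hash of the
#' configuration, so a re-run with the same spec is byte-identical.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if missing).
#' @param shapes `"contour"` (CSV polygons), `"volume"` (NIfTI masks) or
#'   `"none"`.
#' @param ... Passed to [sample_cohort()].
#' @return The cohort tibble, invisibly.
#' @export
run_simulate <- function(spec = cohort_spec(), out_dir,
                         shapes = c("contour", "volume", "none"), ...) {
  shapes <- match.arg(shapes)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- sample_cohort(spec, shapes = shapes, ...)
  tab <- dplyr::select(cohort, -dplyr::any_of("shape"))
  readr::write_csv(tab, file.path(out_dir, "cohort.csv"))
  if (shapes == "contour") {
    dir.create(file.path(out_dir, "contours"), showWarnings = FALSE)
    purrr::walk2(cohort$shape, cohort$lesion_id, function(ct, id) {
      readr::write_csv(
        tibble::tibble(x = as.matrix(ct)[, 1], y = as.matrix(ct)[, 2]),
        file.path(out_dir, "contours", paste0(id, ".csv")))
    })
  } else if (shapes == "volume") {
    dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
    purrr::walk2(cohort$shape, cohort$lesion_id, function(mk, id) {
      write_mask_nifti(mk, file.path(out_dir, "masks", paste0(id, ".nii.gz")))
    })
  }
  write_run_config(file.path(out_dir, "run_config.json"),
                   list(command = "simulate", seed = spec$seed,
                        n = as.list(spec$n), shapes = shapes),
                   spec)
  invisible(cohort)
}

#' Measure shape features for a batch of mask or contour files
#'
#' Applies the full measurement chain to each input. Inputs may be a
#' directory (every `.nii`/`.nii.gz` mask or `.csv` contour inside), a
#' character vector of such paths, or a list of [volume_mask()] /
#' [planar_contour()] objects. Unreadable files and degenerate lesions
#' yield flagged rows; the run continues and reports the failure count.
#'
#' @param input Directory, file paths, or list of objects.
#' @param out_csv Optional path for the feature CSV.
#' @param sweep_steps,resample_bounds Measurement configuration, see
#'   [shape_features()].
#' @param quiet Suppress per-run messages.
#' @return The feature tibble (one row per lesion, flagged rows included).
#' @export
run_features <- function(input, out_csv = NULL, sweep_steps = 500L,
                         resample_bounds = c(360L, 2000L), quiet = FALSE) {
  if (is.character(input) && length(input) == 1 && dir.exists(input)) {
    input <- sort(list.files(input, pattern = "\\.(nii|nii\\.gz|csv)$",
                             full.names = TRUE))
  }
  if (is.character(input)) {
    ids <- sub("\\.(nii\\.gz|nii|csv)$", "", basename(input))
    objects <- purrr::map(input, function(path) {
      tryCatch({
        if (grepl("\\.csv$", path)) {
          xy <- suppressWarnings(readr::read_csv(path, show_col_types = FALSE,
                                                 progress = FALSE))
          if (!all(c("x", "y") %in% names(xy))) {
            stop("contour CSV needs x and y columns")
          }
          planar_contour(cbind(xy$x, xy$y))
        } else {
          read_mask_nifti(path)
        }
      }, error = function(e) e)
    })
  } else {
    objects <- input
    ids <- names(input) %||% sprintf("lesion_%03d", seq_along(input))
  }
  feats <- purrr::map2_dfr(objects, ids, function(obj, id) {
    if (inherits(obj, "condition")) {
      flagged_row(id, paste("unreadable input:", conditionMessage(obj)))
    } else {
      tryCatch(shape_features(obj, lesion_id = id, sweep_steps = sweep_steps,
                              resample_bounds = resample_bounds),
               error = function(e) flagged_row(id, conditionMessage(e)))
    }
  })
  n_flag <- sum(feats$flags != "")
  if (!quiet) {
    message(sprintf("measured %d lesions (%d flagged)", nrow(feats), n_flag))
  }
  if (!is.null(out_csv)) readr::write_csv(feats, out_csv)
  feats
}

#' Run the full cohort analysis and write a report
#'
#' Reproduces the statistical pipeline on a labelled feature table:
#' categorical baseline tests (sex, lobe by Pearson chi-square; age by
#' Welch t), per-feature group comparisons, the two-predictor logistic
#' model with odds ratios, per-feature ROC curves with Youden cut-offs,
#' the fitted combined-model ROC, and the published-equation probability
#' for every lesion (with its ROC). Flagged lesions are excluded from all
#' statistics.
#'
#' @param features A feature data frame with a `group` column, or a CSV
#'   path.
#' @param out_json Optional path for the JSON report.
#' @param test Headline test for group comparisons (`"welch"` or
#'   `"wilcoxon"`).
#' @param positive Positive (invasive) class label.
#' @param seed Recorded in the report for provenance.
#' @return The report as a named list, invisibly if `out_json` is given.
#' @export
run_analyze <- function(features, out_json = NULL, test = "welch",
                        positive = "IAC", seed = NA_integer_) {
  if (is.character(features)) {
    features <- readr::read_csv(features, show_col_types = FALSE)
  }
  if (is.null(features$group)) stop("features need a `group` column", call. = FALSE)
  if ("flags" %in% names(features)) {
    features <- dplyr::filter(features, is.na(.data$flags) | .data$flags == "")
  }
  if (min(table(features$group)) < 2) {
    stop("need at least 2 lesions per group", call. = FALSE)
  }
  feature_cols <- intersect(c("MA_mm2", "BiA_deg", "BiA_SmA", "LD_mm", "LD_PD"),
                            names(features))

  table1 <- list()
  for (v in intersect(c("sex", "lobe"), names(features))) {
    tab <- table(features$group, features[[v]])
    if (all(dim(tab) >= 2) && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      table1[[v]] <- pearson_chi_square(tab)
    }
  }
  if ("age" %in% names(features)) {
    table1$age <- compare_groups(features, "age", test = test)
  }

  table2 <- compare_groups(features, feature_cols, test = test)

  model <- fit_logistic(features, positive = positive)
  roc_single <- purrr::map(
    rlang::set_names(intersect(c("BiA_SmA", "LD_mm"), feature_cols)),
    function(f) empirical_roc(features[[f]], features$group, positive))
  roc_fitted <- combined_score_roc(features, model, positive = positive)
  roc_published <- combined_score_roc(features, published_model(),
                                      positive = positive)
  predictions <- tibble::tibble(
    lesion_id = features$lesion_id %||% as.character(seq_len(nrow(features))),
    group = as.character(features$group),
    p_fitted = predict(model, newdata = features),
    p_published = published_probability(features$BiA_SmA, features$LD_mm)
  )

  report <- list(
    config = list(seed = seed, test = test, positive = positive,
                  n = as.list(table(features$group))),
    table1 = table1,
    table2 = table2,
    logistic = list(coefficients = tidy(model), model = glance(model)),
    roc = c(purrr::map(roc_single, glance),
            list(combined_fitted = glance(roc_fitted),
                 combined_published = glance(roc_published))),
    cutoffs = purrr::map(roc_single, youden_cutoff),
    predictions = predictions
  )
  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' Score lesions with the published predictive equation
#'
#' @param data Data frame (or CSV path) with `BiA_SmA` and `LD_mm`
#'   columns.
#' @param out_csv Optional output CSV path.
#' @param threshold Probability threshold for the predicted class.
#' @return The input with `p_published` and `predicted_class` columns
#'   appended.
#' @export
run_predict <- function(data, out_csv = NULL, threshold = 0.5) {
  if (is.character(data)) data <- readr::read_csv(data, show_col_types = FALSE)
  if (!all(c("BiA_SmA", "LD_mm") %in% names(data))) {
    stop("data needs `BiA_SmA` and `LD_mm` columns", call. = FALSE)
  }
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    p_published = published_probability(.data$BiA_SmA, .data$LD_mm),
    predicted_class = ifelse(.data$p_published >= threshold, "IAC", "PGL_MIA"))
  if (!is.null(out_csv)) readr::write_csv(out, out_csv)
  out
}

write_run_config <- function(path, config, spec_obj = NULL) {
  config$config_hash <- rlang::hash(list(config, spec_obj))
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
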