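#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson X^2 without continuity correction (the variant that
#' reproduces the published lobe-location comparison), with
#' `df = (r - 1)(c - 1)` and an upper-tail p-value.
#'
#' @param table An r x c matrix (or table) of non-negative integer counts
#'   with positive row and column margins.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' lobes <- rbind(PGL_MIA = c(17, 4, 4, 8, 6), IAC = c(25, 4, 8, 17, 5))
#' pearson_chi_square(lobes)
#' @export
pearson_chi_square <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || anyNA(tab)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has a zero row or column margin", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = res$p.value)
}

#' Compare continuous features between the two pathology groups
#'
#' For each feature, reports the per-group mean and SD and p-values from
#' both Welch's t-test and the Mann-Whitney (Wilcoxon rank-sum) test; the
#' `p_value` column carries the one selected by `test`. Rows with missing
#' feature values (flagged lesions) are dropped per feature. A feature that
#' is constant within both groups has no defined test and is flagged with
#' `NA` p-values.
#'
#' @param cohort Data frame with a `group` column (two levels) and the
#'   feature columns.
#' @param features Character vector of feature column names; default: the
#'   standard descriptor columns present in `cohort`.
#' @param group Name of the grouping column.
#' @param test `"welch"` (default) or `"wilcoxon"` for the headline
#'   `p_value`.
#' @return A tibble with one row per feature: group means/SDs, `p_welch`,
#'   `p_wilcoxon`, `p_value`, `flag`.
#' @export
compare_groups <- function(cohort, features = NULL, group = "group",
                           test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  g <- factor(cohort[[group]])
  if (nlevels(g) != 2) stop("`group` must have exactly two levels", call. = FALSE)
  if (is.null(features)) {
    features <- intersect(c("MA_mm2", "BiA_deg", "BiA_SmA", "LD_mm", "LD_PD"),
                          names(cohort))
  }
  lv <- levels(g)
  purrr::map_dfr(features, function(f) {
    x <- cohort[[f]]
    keep <- !is.na(x)
    x1 <- x[keep & g == lv[1]]; x2 <- x[keep & g == lv[2]]
    if (length(x1) == 0 || length(x2) == 0) {
      stop("both groups must be non-empty for feature ", f, call. = FALSE)
    }
    constant <- length(unique(x1)) == 1 && length(unique(x2)) == 1
    pw <- pm <- NA_real_
    flag <- ""
    if (constant) {
      flag <- "constant feature: test undefined"
    } else {
      pw <- tryCatch(stats::t.test(x1, x2)$p.value, error = function(e) NA_real_)
      pm <- suppressWarnings(
        stats::wilcox.test(x1, x2, exact = FALSE, correct = FALSE)$p.value)
    }
    tibble::tibble(
      feature = f,
      group1 = lv[1], mean1 = mean(x1), sd1 = stats::sd(x1), n1 = length(x1),
      group2 = lv[2], mean2 = mean(x2), sd2 = stats::sd(x2), n2 = length(x2),
      p_welch = pw, p_wilcoxon = pm,
      p_value = if (test == "welch") pw else pm,
      flag = flag
    )
  })
}

#' Fit the binary logistic diagnostic model
#'
#' Maximum-likelihood binary logistic regression (IRLS via [stats::glm()],
#' no regularization) of the pathology group on the chosen descriptors,
#' with odds ratios and Wald 95% confidence intervals. The default
#' predictors are the two independent factors of the published model,
#' BiA/SmA and LD. Perfect or quasi-perfect separation is detected (fitted
#' probabilities numerically 0/1 or exploding standard errors) and flagged
#' with a warning rather than silently reported.
#'
#' @param cohort Data frame with the outcome and feature columns.
#' @param features Character vector of predictor column names.
#' @param outcome Name of the outcome column (two levels).
#' @param positive Level treated as the event (default `"IAC"`, i.e. the
#'   invasive class).
#' @return A `ggn_logit` object; see [tidy.ggn_logit()] and
#'   [glance.ggn_logit()].
#' @export
fit_logistic <- function(cohort, features = c("BiA_SmA", "LD_mm"),
                         outcome = "group", positive = "IAC") {
  y_raw <- cohort[[outcome]]
  if (is.null(y_raw)) stop("outcome column not found: ", outcome, call. = FALSE)
  keep <- stats::complete.cases(cohort[, c(outcome, features)])
  dat <- cohort[keep, , drop = FALSE]
  y <- as.integer(dat[[outcome]] == positive)
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    stop("need at least two rows in each outcome class", call. = FALSE)
  }
  df <- data.frame(.y = y, dat[, features, drop = FALSE], check.names = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(stats::reformulate(sprintf("`%s`", features), ".y"),
               family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(se)) || any(se > 1e3) || !fit$converged) separation <- TRUE
  if (separation) {
    warning("possible (quasi-)separation: coefficient estimates may diverge",
            call. = FALSE)
  }
  structure(list(fit = fit, features = features, outcome = outcome,
                 positive = positive, separation = separation,
                 n = nrow(df), n_event = sum(y)),
            class = "ggn_logit")
}

#' @export
print.ggn_logit <- function(x, ...) {
  cat(sprintf("<ggn_logit> %s ~ %s (%d obs, %d events%s)\n",
              x$outcome, paste(x$features, collapse = " + "),
              x$n, x$n_event,
              if (x$separation) ", SEPARATION FLAGGED" else ""))
  print(tidy(x))
  invisible(x)
}

#' Predicted probabilities from a fitted diagnostic model
#'
#' @param object A `ggn_logit`.
#' @param newdata Data frame with the predictor columns; default the
#'   training data.
#' @param ... Unused.
#' @return Numeric vector of probabilities of the positive (invasive)
#'   class.
#' @export
predict.ggn_logit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    unname(stats::predict(object$fit, type = "response"))
  } else {
    unname(stats::predict(object$fit, newdata = newdata, type = "response"))
  }
}

#' The published predictive-probability model
#'
#' The reported logistic diagnostic model for separating PGL+MIA from IAC:
#' `logit(P) = -34.571 + 28.443 * x1 + 0.27 * x2`, with `x1` the BiA/SmA
#' ratio and `x2` the longest diameter in mm. Its per-mm LD odds ratio is
#' `exp(0.27) = 1.310`, and the 0.5-probability decision boundary is the
#' line `28.443 * x1 + 0.27 * x2 = 34.571`.
#'
#' @return A `ggn_published_model` list with `intercept`, `beta_ratio`,
#'   `beta_ld`.
#' @examples
#' m <- published_model()
#' exp(m$beta_ld)
#' @export
published_model <- function() {
  structure(list(intercept = -34.571, beta_ratio = 28.443, beta_ld = 0.27),
            class = "ggn_published_model")
}

#' @export
print.ggn_published_model <- function(x, ...) {
  cat(sprintf("<published model> logit(P) = %g + %g * BiA/SmA + %g * LD_mm\n",
              x$intercept, x$beta_ratio, x$beta_ld))
  invisible(x)
}

#' Evaluate the published predictive probability
#'
#' @param x1 BiA/SmA ratio(s), >= 1.
#' @param x2 Longest diameter(s) in mm, > 0.
#' @param model A `ggn_published_model` (default: the published
#'   coefficients).
#' @return Probability of the invasive (IAC) class, strictly increasing in
#'   both arguments.
#' @examples
#' published_probability(1.136, 19.488)
#' @export
published_probability <- function(x1, x2, model = published_model()) {
  if (any(x1 < 1, na.rm = TRUE)) stop("x1 (BiA/SmA) must be >= 1", call. = FALSE)
  if (any(x2 <= 0, na.rm = TRUE)) stop("x2 (LD, mm) must be > 0", call. = FALSE)
  stats::plogis(model$intercept + model$beta_ratio * x1 + model$beta_ld * x2)
}
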