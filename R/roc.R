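#' Empirical ROC curve with AUC, DeLong CI and Youden cut-off
#'
#' Builds the empirical ROC of a continuous score against a binary label
#' with the classification rule `score >= threshold` is positive. The AUC
#' is computed through the Mann-Whitney U identity (ties count one half),
#' which equals the trapezoidal integral of the empirical staircase; its
#' 95% confidence interval uses DeLong's structural-components variance.
#' The optimal cut-off maximizes the Youden index J = sensitivity +
#' specificity - 1 over the observed scores (ties broken toward the
#' smallest score).
#'
#' @param scores Numeric vector.
#' @param labels Vector with exactly two classes present.
#' @param positive Label value counted as positive; default the larger
#'   level (factor) or of the sorted unique values.
#' @return A `ggn_roc` object: list with `points` (tibble of threshold,
#'   sensitivity, specificity), `auc`, `auc_ci_95`, `auc_se`,
#'   `youden_cutoff`, `youden_j`, `sens_at_cutoff`, `spec_at_cutoff`,
#'   `n_pos`, `n_neg`.
#' @examples
#' r <- empirical_roc(c(1, 2, 3, 4), c(0, 0, 1, 1), positive = 1)
#' r$auc
#' @export
empirical_roc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  lv <- if (is.factor(labels)) levels(droplevels(labels)) else sort(unique(labels))
  if (length(lv) != 2) stop("labels must contain exactly two classes", call. = FALSE)
  if (is.null(positive)) positive <- lv[2]
  y <- labels == positive
  if (!any(y) || all(y)) stop("both classes must be present", call. = FALSE)
  pos <- scores[y]; neg <- scores[!y]
  m <- length(pos); n <- length(neg)

  # Mann-Whitney U via midranks
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)

  # DeLong structural components
  v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)), 0)
  v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)), 0)
  var_auc <- stats::var(v10) / m + stats::var(v01) / n
  se <- sqrt(max(var_auc, 0))
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * stats::qnorm(0.975) * se))

  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(pos >= t), 0)
  spec <- vapply(thr, function(t) mean(neg < t), 0)
  points <- tibble::tibble(
    threshold = c(thr, Inf),
    sensitivity = c(sens, 0),
    specificity = c(spec, 1)
  )
  j <- sens + spec - 1
  best <- which(j == max(j))[1]        # smallest score among ties
  structure(list(points = points, auc = auc, auc_se = se,
                 auc_ci_95 = ci, youden_cutoff = thr[best],
                 youden_j = j[best], sens_at_cutoff = sens[best],
                 spec_at_cutoff = spec[best],
                 n_pos = m, n_neg = n, positive = positive),
            class = "ggn_roc")
}

#' @export
print.ggn_roc <- function(x, ...) {
  cat(sprintf(
    "<ggn_roc> %d pos / %d neg; AUC %.4f (95%% CI %.4f-%.4f)\n  Youden cut-off >= %.4g: sens %.4f, spec %.4f (J = %.4f)\n",
    x$n_pos, x$n_neg, x$auc, x$auc_ci_95[1], x$auc_ci_95[2],
    x$youden_cutoff, x$sens_at_cutoff, x$spec_at_cutoff, x$youden_j))
  invisible(x)
}

#' Youden-optimal cut-off of an ROC curve
#'
#' The observed score value maximizing sensitivity + specificity - 1 under
#' the `score >= cutoff` positivity rule; among ties, the smallest score.
#'
#' @param roc A `ggn_roc` from [empirical_roc()].
#' @return One-row tibble: `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "ggn_roc"))
  tibble::tibble(cutoff = roc$youden_cutoff,
                 sensitivity = roc$sens_at_cutoff,
                 specificity = roc$spec_at_cutoff,
                 youden_j = roc$youden_j)
}

#' Trapezoidal area under the empirical ROC staircase
#'
#' Provided as the geometric counterpart of the U-statistic AUC; the two
#' agree to machine precision on every data set.
#'
#' @param roc A `ggn_roc`.
#' @return The trapezoidal AUC.
#' @export
trapezoid_auc <- function(roc) {
  stopifnot(inherits(roc, "ggn_roc"))
  fpr <- 1 - roc$points$specificity
  tpr <- roc$points$sensitivity
  ord <- order(fpr, tpr)
  fpr <- c(fpr[ord], 1); tpr <- c(tpr[ord], 1)
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' ROC of a combined diagnostic model
#'
#' Scores every lesion with a model's predicted probability of invasion and
#' returns the ROC of that combined score: either a fitted `ggn_logit` or
#' the published coefficient model (applied to the `BiA_SmA` and `LD_mm`
#' columns).
#'
#' @param cohort Data frame with the feature columns and the outcome.
#' @param model A `ggn_logit` or `ggn_published_model`.
#' @param outcome,positive Outcome column and positive class.
#' @return A `ggn_roc`.
#' @export
combined_score_roc <- function(cohort, model, outcome = "group",
                               positive = "IAC") {
  scores <- if (inherits(model, "ggn_logit")) {
    predict(model, newdata = cohort)
  } else if (inherits(model, "ggn_published_model")) {
    published_probability(cohort$BiA_SmA, cohort$LD_mm, model)
  } else {
    stop("`model` must be a ggn_logit or ggn_published_model", call. = FALSE)
  }
  empirical_roc(scores, cohort[[outcome]], positive = positive)
}
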