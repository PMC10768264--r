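#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted diagnostic logistic model
#'
#' One row per model term with the coefficient, Wald statistics, and the
#' odds ratio with its Wald 95% confidence interval.
#'
#' @param x A `ggn_logit` from [fit_logistic()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `odds_ratio`, `or_ci_lo`, `or_ci_hi`.
#' @export
tidy.ggn_logit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  z <- stats::qnorm(0.975)
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, 1],
    std_error = cf[, 2],
    statistic = cf[, 3],
    p_value = cf[, 4],
    odds_ratio = exp(cf[, 1]),
    or_ci_lo = exp(cf[, 1] - z * cf[, 2]),
    or_ci_hi = exp(cf[, 1] + z * cf[, 2])
  )
}

#' Model-level summary of a fitted diagnostic logistic model
#'
#' @param x A `ggn_logit`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_event`, `null_deviance`, `deviance`,
#'   `aic`, `converged`, `separation`.
#' @export
glance.ggn_logit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_event = x$n_event,
    null_deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    aic = x$fit$aic,
    converged = x$fit$converged,
    separation = x$separation
  )
}

#' Tidy an ROC curve
#'
#' @param x A `ggn_roc` from [empirical_roc()].
#' @param ... Unused.
#' @return The ROC points tibble (`threshold`, `sensitivity`,
#'   `specificity`).
#' @export
tidy.ggn_roc <- function(x, ...) x$points

#' Curve-level summary of an ROC
#'
#' @param x A `ggn_roc`.
#' @param ... Unused.
#' @return One-row tibble with the AUC, its DeLong 95% CI, the Youden
#'   cut-off and its operating point.
#' @export
glance.ggn_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, auc_se = x$auc_se,
    auc_ci_lo = x$auc_ci_95[1], auc_ci_hi = x$auc_ci_95[2],
    youden_cutoff = x$youden_cutoff, youden_j = x$youden_j,
    sens_at_cutoff = x$sens_at_cutoff, spec_at_cutoff = x$spec_at_cutoff,
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}
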