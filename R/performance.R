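#' Mann-Whitney AUC with confidence interval
#'
#' The area under the ROC curve computed as the Mann-Whitney probability
#' that a randomly chosen case scores above a randomly chosen control, with
#' half credit for ties (midranks). The 95% confidence interval uses the
#' DeLong paired-placement variance estimator by default (Hanley-McNeil
#' available), truncated to (0, 1). AUC is invariant under any strictly
#' increasing transform of the scores, so scoring on the linear predictor
#' `x` or on the probability `p` gives the same value.
#'
#' @param case_scores,control_scores Numeric score vectors (`NA` dropped).
#' @param conf_level Confidence level (default 0.95).
#' @param ci_method `"delong"` (default) or `"hanley"`.
#' @return One-row tibble: `auc`, `ci_lo`, `ci_hi`, `n_cases`, `n_controls`.
#' @export
#' @examples
#' auc_mann_whitney(c(3, 4, 5), c(1, 2, 3.5))
auc_mann_whitney <- function(case_scores, control_scores, conf_level = 0.95,
                             ci_method = c("delong", "hanley")) {
  ci_method <- match.arg(ci_method)
  case_scores <- case_scores[!is.na(case_scores)]
  control_scores <- control_scores[!is.na(control_scores)]
  m <- length(case_scores)
  n <- length(control_scores)
  if (m == 0 || n == 0) abort("Both score groups must be non-empty.")

  # placements: for each case, fraction of controls it beats (ties half)
  v10 <- vapply(case_scores, function(s) {
    (sum(s > control_scores) + 0.5 * sum(s == control_scores)) / n
  }, numeric(1))
  v01 <- vapply(control_scores, function(s) {
    (sum(case_scores > s) + 0.5 * sum(case_scores == s)) / m
  }, numeric(1))
  auc <- mean(v10)

  if (ci_method == "delong") {
    var_auc <- stats::var(v10) / m + stats::var(v01) / n
    if (m == 1) var_auc <- stats::var(v01) / n
    if (n == 1) var_auc <- stats::var(v10) / m
    if (m == 1 && n == 1) var_auc <- 0
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    var_auc <- (auc * (1 - auc) + (m - 1) * (q1 - auc^2) +
                  (n - 1) * (q2 - auc^2)) / (m * n)
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(max(var_auc, 0))
  tibble::tibble(
    auc = auc,
    ci_lo = max(0, auc - half),
    ci_hi = min(1, auc + half),
    n_cases = m,
    n_controls = n
  )
}

#' Detection rates at fixed false-positive rates
#'
#' For each nominal false-positive rate `f`, the risk-score threshold is the
#' `(1 - f)` empirical percentile of the control scores (linear
#' interpolation between order statistics) and the detection rate is the
#' fraction of cases scoring strictly above it. By construction the
#' observed control exceedance never overshoots `f` by more than the
#' percentile granularity `1 / n_controls`.
#'
#' @param case_scores,control_scores Numeric score vectors (`NA` dropped).
#' @param fprs Nominal false-positive rates (default 10%, 20%, 30%).
#' @return Tibble with one row per FPR: `fpr`, `threshold`,
#'   `detection_rate`, `control_exceedance`.
#' @export
#' @examples
#' dr_at_fixed_fpr(rnorm(30, 1), rnorm(100))
dr_at_fixed_fpr <- function(case_scores, control_scores,
                            fprs = c(0.10, 0.20, 0.30)) {
  case_scores <- case_scores[!is.na(case_scores)]
  control_scores <- control_scores[!is.na(control_scores)]
  if (length(control_scores) < 10) {
    abort("Need at least 10 control scores to place percentile thresholds.")
  }
  if (any(fprs <= 0) || any(fprs >= 1)) abort("FPRs must lie in (0, 1).")
  if (length(unique(control_scores)) == 1) {
    warn("Control scores are constant; detection rate is the case fraction above that constant.")
  }
  purrr::map_dfr(fprs, function(f) {
    thr <- unname(quantile(control_scores, 1 - f, type = 7))
    tibble::tibble(
      fpr = f,
      threshold = thr,
      detection_rate = mean(case_scores > thr),
      control_exceedance = mean(control_scores > thr)
    )
  })
}

#' Evaluate a risk model's screening performance
#'
#' Scores the cohort with [score_risk()] (missingness-aware; subjects with
#' no matching variant are dropped with a message), splits scores into the
#' case stratum and the non-case comparator group (subjects with neither
#' preterm birth nor preeclampsia), and summarizes performance as
#' Mann-Whitney AUC with confidence interval plus detection rates at the
#' fixed false-positive rates.
#'
#' @param data MoM-normalized cohort tibble with an `outcome` column.
#' @param model A `risk_model`.
#' @param case_group Case stratum label (defaults to the model's outcome).
#' @param fprs Nominal false-positive rates (default 10%, 20%, 30%).
#' @param incomplete Passed to [score_risk()] (default `"drop"`).
#' @inheritParams auc_mann_whitney
#' @return A `screening_result`: list with `outcome`, `model_label`, `auc`
#'   (one-row tibble), `rates` (DR table), `scores` (per-subject tibble).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 400), seed = 1)
#' cohort |>
#'   mom_normalize() |>
#'   evaluate_model(published_equation("SPTB_LE32"))
evaluate_model <- function(data, model, case_group = model$outcome,
                           fprs = c(0.10, 0.20, 0.30),
                           incomplete = "drop",
                           ci_method = c("delong", "hanley")) {
  scored <- score_risk(data, model, incomplete = incomplete)
  is_case <- outcome_in_group(scored$outcome, case_group)
  is_control <- scored$outcome == "NONCASE"
  if (!any(is_case)) abort("No scored cases for this outcome stratum.")
  case_p <- scored$p[is_case]
  control_p <- scored$p[is_control]
  res <- structure(
    list(
      outcome = case_group,
      model_label = model$label,
      auc = auc_mann_whitney(case_p, control_p,
                             ci_method = match.arg(ci_method)),
      rates = dr_at_fixed_fpr(case_p, control_p, fprs),
      scores = scored[is_case | is_control, , drop = FALSE]
    ),
    class = "screening_result"
  )
  res
}

#' @export
print.screening_result <- function(x, ...) {
  a <- x$auc
  cat("<screening_result>", x$outcome, "~", x$model_label, "\n")
  cat(sprintf("  AUC %.2f [95%% CI %.2f-%.2f]  (%d cases / %d controls)\n",
              a$auc, a$ci_lo, a$ci_hi, a$n_cases, a$n_controls))
  for (i in seq_len(nrow(x$rates))) {
    cat(sprintf("  DR %.0f%% at FPR %.0f%%\n",
                100 * x$rates$detection_rate[i], 100 * x$rates$fpr[i]))
  }
  invisible(x)
}

#' @method tidy screening_result
#' @export
tidy.screening_result <- function(x, ...) {
  dplyr::mutate(x$rates, outcome = x$outcome, model = x$model_label,
                .before = 1)
}

#' @method glance screening_result
#' @export
glance.screening_result <- function(x, ...) {
  dplyr::mutate(x$auc, outcome = x$outcome, model = x$model_label,
                .before = 1)
}

#' ROC points of a screening result
#'
#' Sensitivity and 1 - specificity at every distinct score threshold, for
#' ROC export or plotting.
#'
#' @param x A `screening_result`.
#' @return Tibble with `score`, `sensitivity`, `one_minus_specificity`.
#' @export
roc_points <- function(x) {
  stopifnot(inherits(x, "screening_result"))
  is_case <- outcome_in_group(x$scores$outcome, x$outcome)
  case <- x$scores$p[is_case]
  control <- x$scores$p[!is_case]
  thr <- sort(unique(c(Inf, x$scores$p, -Inf)), decreasing = TRUE)
  purrr::map_dfr(thr, function(t) {
    tibble::tibble(
      score = t,
      sensitivity = mean(case >= t),
      one_minus_specificity = mean(control >= t)
    )
  })
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the ROC curve of a screening result
#'
#' @param object A `screening_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screening_result
#' @export
autoplot.screening_result <- function(object, ...) {
  pts <- roc_points(object)
  lab <- sprintf("%s ~ %s\nAUC %.2f [%.2f-%.2f]", object$outcome,
                 object$model_label, object$auc$auc, object$auc$ci_lo,
                 object$auc$ci_hi)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$one_minus_specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate (1 - specificity)",
                  y = "Detection rate (sensitivity)", title = lab) +
    ggplot2::theme_minimal()
}
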