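#' Wilcoxon rank-sum comparison of case and non-case log MoMs
#'
#' Compares the distribution of log MoMs between cases and non-cases with
#' the Wilcoxon (Mann-Whitney) rank-sum test: midranks for ties, exact
#' enumeration for small tie-free samples (`min(n) <= 8`), otherwise the
#' normal approximation with continuity and tie correction. One-tailed
#' testing is reserved for markers with a known direction (cervical length
#' shorter in cases, MAP higher).
#'
#' @param case,noncase Numeric vectors of log10 MoMs (or any values; the
#'   test is rank-based).
#' @param tails 1 or 2 (default 2).
#' @param alternative For one-tailed tests, the direction of the case group
#'   relative to non-cases (`"greater"` or `"less"`); ignored when
#'   `tails = 2`.
#' @param comparison Label carried into the result row.
#' @return One-row tibble: `comparison`, `statistic` (Mann-Whitney U of the
#'   case group), `p_value`, `tails`, `median_case`, `median_noncase`,
#'   `n_case`, `n_noncase`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
wilcoxon_rank_sum <- function(case, noncase, tails = 2,
                              alternative = c("greater", "less"),
                              comparison = "case vs non-case") {
  case <- case[!is.na(case)]
  noncase <- noncase[!is.na(noncase)]
  if (length(case) == 0 || length(noncase) == 0) {
    abort("Both groups must be non-empty.")
  }
  stopifnot(tails %in% c(1, 2))
  alternative <- if (tails == 2) "two.sided" else match.arg(alternative)

  pooled <- c(case, noncase)
  ties <- anyDuplicated(pooled) > 0
  if (length(unique(pooled)) == 1) {
    warn("All values identical; rank test is uninformative (p = 1).")
    p <- 1
    stat <- length(case) * length(noncase) / 2
  } else {
    use_exact <- !ties && min(length(case), length(noncase)) <= 8
    ht <- suppressWarnings(
      wilcox.test(case, noncase, alternative = alternative,
                  exact = use_exact, correct = TRUE)
    )
    p <- ht$p.value
    stat <- unname(ht$statistic)
  }
  tibble::tibble(
    comparison = comparison,
    statistic = stat,
    p_value = p,
    tails = as.integer(tails),
    median_case = median(case),
    median_noncase = median(noncase),
    n_case = length(case),
    n_noncase = length(noncase)
  )
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson chi-square (no continuity correction) on an `r x k` table
#' of counts, `df = (r - 1)(k - 1)`, two-sided p-value — the test used for
#' comparing maternal characteristics between outcome groups.
#'
#' @param counts Matrix (or object coercible to one) of non-negative integer
#'   counts with positive margins.
#' @param comparison Label carried into the result row.
#' @return One-row tibble: `comparison`, `statistic`, `df`, `p_value`,
#'   `tails` (always 2), `n`.
#' @export
#' @examples
#' # prior preterm birth: 25/5 in cases vs 83/109 in non-cases
#' chi_square_test(matrix(c(25, 5, 83, 109), nrow = 2))
chi_square_test <- function(counts, comparison = "contingency") {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("Counts must be non-negative.")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("Contingency table has a zero margin.")
  }
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble::tibble(
    comparison = comparison,
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    tails = 2L,
    n = sum(counts)
  )
}

#' Correlation between a marker and a clinical measurement
#'
#' Pearson product-moment correlation with a two-sided t-test on `n - 2`
#' degrees of freedom (the study reports `r` without naming a method;
#' Spearman rank correlation is available via `method`).
#'
#' @param x,y Paired numeric vectors; pairs with missing values are dropped.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param comparison Label carried into the result row.
#' @return One-row tibble: `comparison`, `statistic` (the correlation `r`),
#'   `p_value`, `tails`, `n`.
#' @export
#' @examples
#' pearson_correlation(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
pearson_correlation <- function(x, y, method = c("pearson", "spearman"),
                                comparison = "correlation") {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in one of the inputs.")
  ht <- suppressWarnings(cor.test(x, y, method = method))
  tibble::tibble(
    comparison = comparison,
    statistic = unname(ht$estimate),
    p_value = ht$p.value,
    tails = 2L,
    n = length(x)
  )
}

#' Select markers significant in the univariate screen
#'
#' Markers and factors whose univariate screen reaches `p < alpha` proceed
#' to the logistic risk modelling stage. No multiple-testing correction is
#' applied across the panel, following the source analysis; this is recorded
#' in the report output.
#'
#' @param results Tibble of association rows with `comparison` and `p_value`
#'   columns (e.g. from [associate_markers()]).
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector of significant comparison labels.
#' @export
select_significant_markers <- function(results, alpha = 0.05) {
  results$comparison[results$p_value < alpha]
}

#' Univariate marker association screen for one case definition
#'
#' Runs the Wilcoxon rank-sum comparison of log10 MoMs between a case
#' stratum and the non-case group for every marker, yielding a marker-table
#' shaped summary: case and non-case median MoMs with group sizes and the
#' rank-test p-value. Cervical length and MAP are tested one-tailed in their
#' known directions; RNAs two-tailed.
#'
#' @param data MoM-normalized cohort tibble with an `outcome` column.
#' @param case_group Case stratum label (nesting; see [outcome_in_group()]).
#' @param markers Markers to screen (default all present).
#' @param one_tailed Named character vector mapping markers to a one-tailed
#'   direction for the case group (`"less"` or `"greater"`).
#' @return Tibble with one row per marker: `marker`, `median_case`,
#'   `median_noncase`, `n_case`, `n_noncase`, `p_value`, `tails`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 400), seed = 1)
#' cohort |>
#'   mom_normalize() |>
#'   associate_markers("SPTB_LE32")
associate_markers <- function(data, case_group,
                              markers = intersect(all_markers(), names(data)),
                              one_tailed = c(CL_CM = "less",
                                             MAP_MMHG = "greater")) {
  is_case <- outcome_in_group(data$outcome, case_group)
  is_control <- data$outcome == "NONCASE"
  purrr::map_dfr(markers, function(m) {
    case <- data[[m]][is_case]
    noncase <- data[[m]][is_control]
    tails <- if (m %in% names(one_tailed)) 1 else 2
    res <- wilcoxon_rank_sum(
      case, noncase, tails = tails,
      alternative = if (tails == 1) one_tailed[[m]] else "greater",
      comparison = m
    )
    dplyr::transmute(res,
      marker = .data$comparison,
      median_case = .data$median_case,
      median_noncase = .data$median_noncase,
      n_case = .data$n_case,
      n_noncase = .data$n_noncase,
      p_value = .data$p_value,
      tails = .data$tails
    )
  })
}

#' MoM distributions by outcome group
#'
#' Boxplots of log10 MoM per marker and outcome group — the visual
#' counterpart of the marker association tables.
#'
#' @param data MoM-normalized cohort tibble with an `outcome` column.
#' @param markers Markers to plot (default all present).
#' @return A ggplot object.
#' @export
plot_mom_distributions <- function(data,
                                   markers = intersect(all_markers(),
                                                       names(data))) {
  long <- mom_profiles(data, markers)
  long <- dplyr::filter(long, !is.na(.data$mom))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$outcome, y = .data$log10_mom)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~marker, scales = "free_y") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = NULL, y = "log10 MoM") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
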