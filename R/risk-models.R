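#' Predictor transforms for risk models
#'
#' Risk models are linear in a small vocabulary of derived predictors:
#'
#' * markers (`PSME2`, ..., `LET7G`, `CL_CM`, `MAP_MMHG`) enter as
#'   `log10(MoM)`;
#' * `race_other` — indicator of self-identified race other than
#'   non-Hispanic Black;
#' * `smoker` — tobacco-use indicator;
#' * `nulliparous` — indicator of parity 0;
#' * `parity_1_2` — indicator of parity 1 or 2 (parity 3+ is the reference
#'   level with coefficient 0);
#' * `prior_ptb` — prior preterm birth indicator;
#' * `earliest_prior_ptb_weeks` — earliest gestation of a prior preterm
#'   birth in weeks, 40 when there was none (a continuous history summary).
#'
#' `risk_term_values()` evaluates any of these on a MoM-normalized cohort
#' tibble.
#'
#' @param data MoM-normalized cohort tibble.
#' @param predictors Character vector of predictor names.
#' @return Tibble of numeric predictor columns (`NA` where unavailable).
#' @export
risk_term_values <- function(data, predictors) {
  vals <- purrr::map(predictors, function(p) {
    if (p %in% all_markers()) return(log10(data[[p]]))
    switch(p,
      race_other = as.numeric(!data$race_nhb),
      smoker = as.numeric(data$smoker),
      nulliparous = as.numeric(data$parity == 0),
      parity_1_2 = as.numeric(data$parity %in% 1:2),
      prior_ptb = as.numeric(data$prior_ptb),
      earliest_prior_ptb_weeks = as.numeric(data$earliest_prior_ptb_weeks),
      abort(paste0("Unknown predictor: ", p))
    )
  })
  tibble::as_tibble(setNames(vals, predictors),
                    .name_repair = "minimal")
}

risk_term_transform <- function(predictor) {
  dplyr::case_when(
    predictor %in% all_markers() ~ "log10_mom",
    predictor == "earliest_prior_ptb_weeks" ~ "linear",
    TRUE ~ "indicator"
  )
}

new_risk_model <- function(outcome, intercept, terms, variants = list(),
                           converged = NA, separation = FALSE,
                           n = NA_integer_, n_cases = NA_integer_,
                           label = NULL) {
  structure(
    list(outcome = outcome, intercept = intercept, terms = terms,
         variants = variants, converged = converged, separation = separation,
         n = n, n_cases = n_cases,
         label = label %||% paste(terms$predictor, collapse = " + ")),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model>", x$outcome, "\n")
  cat("  x =", signif(x$intercept, 6))
  for (i in seq_len(nrow(x$terms))) {
    co <- x$terms$coefficient[i]
    cat(if (co >= 0) " + " else " - ", abs(signif(co, 6)), "*",
        x$terms$predictor[i], sep = "")
  }
  cat("\n  p = e^x / (1 + e^x)\n")
  if (length(x$variants)) {
    cat("  missingness variants:", length(x$variants), "\n")
  }
  if (isTRUE(x$separation)) cat("  warning: quasi-separation detected\n")
  invisible(x)
}

#' @method tidy risk_model
#' @export
tidy.risk_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$terms$predictor),
    transform = c(NA_character_, x$terms$transform),
    estimate = c(x$intercept, x$terms$coefficient)
  )
}

#' @method glance risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    n_terms = nrow(x$terms),
    n_variants = length(x$variants),
    converged = x$converged,
    separation = x$separation,
    n = x$n,
    n_cases = x$n_cases
  )
}

ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1)), ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, X * w) + pen, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      return(list(coefficients = drop(beta_new), converged = TRUE))
    }
    beta <- drop(beta_new)
  }
  list(coefficients = beta, converged = FALSE)
}

#' Fit a logistic risk model
#'
#' Maximum-likelihood logistic regression of case status (a nesting case
#' stratum versus the non-case group) on the requested predictors,
#' transformed per [risk_term_values()]. Rows outside the case and non-case
#' strata and rows with any missing predictor are dropped. Quasi-complete
#' separation (e.g. a parity level containing no events) is reported when
#' any standardized coefficient exceeds 15 in magnitude; a lightly
#' ridge-penalized fit (`lambda = 1e-4`) is available as a fallback for such
#' data — it is never applied to the published fixed equations.
#'
#' @param data MoM-normalized cohort tibble with an `outcome` column.
#' @param case_group Case stratum label.
#' @param predictors Predictor names (see [risk_term_values()]), typically
#'   pre-screened with [select_significant_markers()].
#' @param ridge Use the ridge-penalized fit (default `FALSE`).
#' @param min_cases Minimum number of cases required (default 10).
#' @return A `risk_model`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 600), seed = 1)
#' moms <- mom_normalize(cohort)
#' fit_risk_model(moms, "SPTB_LE32", c("PSME2", "LET7G"))
fit_risk_model <- function(data, case_group, predictors, ridge = FALSE,
                           min_cases = 10) {
  keep <- outcome_in_group(data$outcome, case_group) |
    data$outcome == "NONCASE"
  data <- data[keep, , drop = FALSE]
  y <- as.numeric(outcome_in_group(data$outcome, case_group))

  tv <- if (length(predictors)) risk_term_values(data, predictors) else
    tibble::tibble(.rows = nrow(data))
  complete <- if (length(predictors)) complete.cases(tv) else
    rep(TRUE, nrow(data))
  tv <- tv[complete, , drop = FALSE]
  y <- y[complete]
  if (sum(y) < min_cases) {
    abort(paste0("Need at least ", min_cases, " complete cases for ",
                 case_group, "; got ", sum(y), "."))
  }

  X <- cbind(`(Intercept)` = 1, as.matrix(tv))
  if (ridge) {
    fit <- ridge_logistic(X, y)
    co <- fit$coefficients
    converged <- fit$converged
  } else {
    df <- dplyr::bind_cols(tibble::tibble(.y = y), tv)
    names(df) <- make.names(names(df))
    form <- as.formula(paste(".y ~",
                             if (length(predictors))
                               paste(make.names(predictors), collapse = " + ")
                             else "1"))
    fit <- suppressWarnings(
      glm(form, family = binomial(),
          data = df, control = stats::glm.control(epsilon = 1e-12,
                                                  maxit = 100))
    )
    co <- coef(fit)
    converged <- fit$converged
  }

  slopes <- co[-1]
  separation <- FALSE
  if (length(slopes)) {
    # indicators are already unit-scale; continuous predictors scaled by sd
    is_indicator <- risk_term_transform(predictors) == "indicator"
    sds <- vapply(tv, sd, numeric(1))
    scale_by <- ifelse(is_indicator | sds == 0, 1, sds)
    std <- abs(slopes) * scale_by
    if (any(std > 15)) {
      separation <- TRUE
      warn(paste0("Possible quasi-complete separation in predictors: ",
                  paste(names(std)[std > 15], collapse = ", "),
                  ". Consider `ridge = TRUE`."))
    }
  }

  terms <- tibble::tibble(
    predictor = predictors,
    transform = risk_term_transform(predictors),
    coefficient = unname(slopes)[seq_along(predictors)]
  )
  new_risk_model(case_group, unname(co[1]), terms,
                 converged = converged, separation = separation,
                 n = length(y), n_cases = as.integer(sum(y)))
}

#' Published risk equations
#'
#' The four best-fit logistic prediction equations of the source study,
#' shipped as fixed fixtures (no refitting, no randomness):
#'
#' * `SPTB_LE32` — spontaneous preterm birth at or before 32 weeks:
#'   `x = 1.4677 + 0.5732 log10(PSME2 MoM) + 0.8268 log10(Let-7g MoM)
#'   - 1.8931 [race other than non-Hispanic Black]
#'   - 0.1119 [earliest gestation of prior PTB, 40 if none]`;
#' * `PTB_LT37` — all spontaneous preterm birth before 37 weeks;
#' * `EOP_LT34` — early-onset preeclampsia delivered before 34 weeks
#'   (NAMPT, APOA1 and parity offsets: +3.6091 nulliparous, -7.9772 parity
#'   1-2, 0 for parity 3+);
#' * `PE_ALL` — all preeclampsia (NAMPT, MAP MoM and parity offsets).
#'
#' The risk probability is `p = e^x / (1 + e^x)`.
#'
#' @param name One of `"SPTB_LE32"`, `"PTB_LT37"`, `"EOP_LT34"`, `"PE_ALL"`.
#' @param path Optional path to a YAML equation file; defaults to the
#'   packaged fixture.
#' @return A `risk_model`.
#' @export
#' @examples
#' published_equation("SPTB_LE32")
published_equation <- function(name, path = NULL) {
  path <- path %||% system.file("extdata", "published_equations.yaml",
                                package = "momscreen", mustWork = TRUE)
  defs <- yaml::read_yaml(path)
  if (!name %in% names(defs)) {
    abort(paste0("Unknown equation `", name, "`. Available: ",
                 paste(names(defs), collapse = ", "), "."))
  }
  d <- defs[[name]]
  terms <- purrr::map_dfr(d$terms, tibble::as_tibble)
  new_risk_model(d$outcome %||% name, d$intercept, terms,
                 converged = TRUE, label = paste0("published:", name))
}

variant_key <- function(predictors) {
  if (length(predictors) == 0) "(covariates only)" else
    paste(sort(predictors), collapse = "+")
}

#' Score subjects with a risk model
#'
#' Computes each subject's linear predictor `x` (intercept plus coefficient
#' times transformed predictor), odds `y = e^x` and risk probability
#' `p = e^x / (1 + e^x)`. Subjects with a missing predictor (unmeasured or
#' below detection) are dispatched to the model's missingness variant fit on
#' the remaining predictors; without a matching variant the behaviour is
#' governed by `incomplete`.
#'
#' @param data MoM-normalized cohort tibble.
#' @param model A `risk_model` (fitted or published).
#' @param incomplete What to do with subjects whose missingness pattern has
#'   no variant: `"error"` (default), `"drop"` (omit the rows, with a
#'   message), or `"na"` (keep rows, scores `NA`).
#' @return Tibble with `subject_id` (if present), `x`, `odds`, `p`,
#'   `variant` (the predictor set used).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 50), seed = 1)
#' cohort |>
#'   mom_normalize() |>
#'   score_risk(published_equation("SPTB_LE32"), incomplete = "drop")
score_risk <- function(data, model, incomplete = c("error", "drop", "na")) {
  incomplete <- match.arg(incomplete)
  stopifnot(inherits(model, "risk_model"))
  predictors <- model$terms$predictor
  tv <- if (length(predictors)) risk_term_values(data, predictors) else
    tibble::tibble(.rows = nrow(data))

  avail <- !is.na(as.matrix(tv))
  pattern <- apply(avail, 1, function(a) variant_key(predictors[a]))
  if (nrow(tv) > 0 && length(predictors) == 0) {
    pattern <- rep(variant_key(character(0)), nrow(data))
  }
  full_key <- variant_key(predictors)

  linear_predictor <- function(mod, rows) {
    x <- rep(mod$intercept, length(rows))
    if (nrow(mod$terms) > 0) {
      sub_tv <- risk_term_values(data[rows, , drop = FALSE],
                                 mod$terms$predictor)
      x <- x + drop(as.matrix(sub_tv) %*% mod$terms$coefficient)
    }
    x
  }

  x <- rep(NA_real_, nrow(data))
  used <- rep(NA_character_, nrow(data))
  unmatched <- integer(0)
  for (key in unique(pattern)) {
    rows <- which(pattern == key)
    if (key == full_key) {
      x[rows] <- linear_predictor(model, rows)
      used[rows] <- key
    } else if (key %in% names(model$variants)) {
      x[rows] <- linear_predictor(model$variants[[key]], rows)
      used[rows] <- key
    } else {
      unmatched <- c(unmatched, rows)
    }
  }
  if (length(unmatched)) {
    msg <- paste0(length(unmatched),
                  " subject(s) have no model variant for their missing-",
                  "predictor pattern.")
    if (incomplete == "error") abort(msg)
    inform(paste0(msg, if (incomplete == "drop") " Dropped." else
                  " Scored as NA."))
  }

  out <- tibble::tibble(x = x, odds = exp(x), p = plogis(x), variant = used)
  if ("subject_id" %in% names(data)) {
    out <- dplyr::bind_cols(data["subject_id"], out)
  }
  if ("outcome" %in% names(data)) {
    out <- dplyr::bind_cols(out, data["outcome"])
  }
  if (incomplete == "drop") out <- out[!is.na(out$x), , drop = FALSE]
  out
}

#' Fit a risk model with missingness-pattern sub-models
#'
#' Fits the main logistic model on complete data, then one sub-model per
#' missing-predictor pattern observed in the cohort (e.g. NAMPT below
#' detection), each fit on the subjects for whom that pattern's predictors
#' are all available. Scoring then dispatches each subject to the variant
#' matching their available predictors. Patterns with fewer than `min_cases`
#' cases fall back to the clinical-covariate-only predictor set (with a
#' message). Variants correspond exactly to the missingness patterns
#' observed in training; a cohort with no missingness yields a single model
#' with no variants.
#'
#' @inheritParams fit_risk_model
#' @param min_cases Minimum cases for the main fit and each variant
#'   (default 5).
#' @return A `risk_model` whose `variants` field maps predictor subsets to
#'   sub-models.
#' @export
fit_missingness_variants <- function(data, case_group, predictors,
                                     ridge = FALSE, min_cases = 5) {
  model <- fit_risk_model(data, case_group, predictors, ridge = ridge,
                          min_cases = min_cases)
  markers <- intersect(predictors, all_markers())
  clinical <- setdiff(predictors, markers)

  tv <- risk_term_values(data, predictors)
  avail <- !is.na(as.matrix(tv))
  patterns <- unique(apply(avail, 1, function(a) list(predictors[a])))
  variants <- list()
  for (p in patterns) {
    subset <- p[[1]]
    key <- variant_key(subset)
    if (key == variant_key(predictors)) next
    sub <- tryCatch(
      fit_risk_model(data, case_group, subset, ridge = ridge,
                     min_cases = min_cases),
      error = function(e) NULL
    )
    if (is.null(sub)) {
      inform(paste0("Too few cases for variant `", key,
                    "`; falling back to clinical covariates only."))
      sub <- fit_risk_model(data, case_group, clinical, ridge = ridge,
                            min_cases = 1)
      variants[[key]] <- sub
      next
    }
    variants[[key]] <- sub
  }
  model$variants <- variants
  model
}
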