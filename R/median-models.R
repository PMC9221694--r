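#' Construct an expected-median model for a marker
#'
#' A median model gives the expected median level of a marker in unaffected
#' pregnancies as a function of the subject's covariates (gestational age at
#' sampling in days, maternal weight in kg). Three forms are supported:
#'
#' * `constant` — the overall reference median, no covariate terms;
#' * `linear` — `intercept + ga_days * days + weight * w` on the raw scale
#'   (used for cervical length and mean arterial pressure);
#' * `log_linear` — `10^(intercept + ga_days * days + weight * w)` (used for
#'   RNA expression, whose medians are modelled on the log10 scale).
#'
#' The weight covariate `w` enters either as kilograms (`identity`) or as
#' `log10(kg)`, per `weight_transform`.
#'
#' @param marker Marker name.
#' @param form One of `"constant"`, `"linear"`, `"log_linear"`.
#' @param coefficients Named numeric vector: `intercept`, optional `ga_days`
#'   and `weight`.
#' @param weight_transform `"log10"` or `"identity"`.
#' @param n Number of reference subjects the model was fit on (or `NA` for
#'   fixtures).
#' @return An object of class `median_model`.
#' @export
#' @examples
#' m <- median_model("PSME2", "constant", c(intercept = 0.85))
#' predict(m, tibble::tibble(ga_sampling_days = 130, weight_kg = 70))
median_model <- function(marker, form = c("constant", "linear", "log_linear"),
                         coefficients, weight_transform = c("log10", "identity"),
                         n = NA_integer_) {
  form <- match.arg(form)
  weight_transform <- match.arg(weight_transform)
  if (!"intercept" %in% names(coefficients)) {
    abort("`coefficients` must include an `intercept`.")
  }
  if (form == "constant") {
    if (length(coefficients) > 1) {
      abort("A constant median model has no covariate terms.")
    }
    if (coefficients[["intercept"]] <= 0) {
      abort("A constant median must be positive.")
    }
  }
  structure(
    list(marker = marker, form = form,
         coefficients = coefficients,
         weight_transform = weight_transform,
         n = n),
    class = "median_model"
  )
}

#' @export
print.median_model <- function(x, ...) {
  cat("<median_model>", x$marker, "-", x$form)
  if (x$form != "constant") cat(" (weight:", x$weight_transform, ")")
  cat("\n  ", paste(names(x$coefficients), signif(x$coefficients, 6),
                    sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

transform_weight <- function(weight_kg, transform) {
  if (transform == "log10") log10(weight_kg) else weight_kg
}

#' Predict expected medians at subject covariates
#'
#' @param object A [median_model()].
#' @param newdata Tibble with `ga_sampling_days` and `weight_kg` columns (not
#'   needed for constant models).
#' @param ... Unused.
#' @return Numeric vector of expected medians, one per row of `newdata`.
#' @export
predict.median_model <- function(object, newdata, ...) {
  co <- object$coefficients
  if (object$form == "constant") {
    return(rep(co[["intercept"]], nrow(newdata)))
  }
  eta <- rep(co[["intercept"]], nrow(newdata))
  if ("ga_days" %in% names(co)) {
    eta <- eta + co[["ga_days"]] * newdata$ga_sampling_days
  }
  if ("weight" %in% names(co)) {
    eta <- eta + co[["weight"]] *
      transform_weight(newdata$weight_kg, object$weight_transform)
  }
  out <- if (object$form == "log_linear") 10^eta else eta
  if (any(out <= 0, na.rm = TRUE)) {
    abort(paste0("Median model for ", object$marker,
                 " predicts non-positive medians over the given covariates."))
  }
  out
}

#' @method tidy median_model
#' @export
tidy.median_model <- function(x, ...) {
  tibble::tibble(
    marker = x$marker,
    term = names(x$coefficients),
    estimate = unname(x$coefficients)
  )
}

#' @method glance median_model
#' @export
glance.median_model <- function(x, ...) {
  tibble::tibble(marker = x$marker, form = x$form,
                 weight_transform = x$weight_transform, n = x$n)
}

#' Fit a median model on reference subjects
#'
#' Fits the expected-median model of a marker on the reference (unaffected)
#' group: log10 levels are regressed on gestational age at sampling and
#' maternal weight by least squares; if neither slope is significant at
#' `alpha` (two-tailed t test), the model collapses to the constant overall
#' median (midpoint-interpolated sample median), otherwise a `log_linear`
#' model retaining only the significant terms is refit. Least squares on
#' log10 values estimates the median of a log-normal level, reproducing the
#' `10^(linear)` form of the published regressed medians.
#'
#' @param data Reference-group cohort tibble (e.g. the non-case rows); rows
#'   with missing or below-detection values of `marker` are dropped.
#' @param marker Marker column to model.
#' @param alpha Two-tailed significance level gating each covariate term
#'   (default 0.05).
#' @param covariates Candidate covariates, a subset of
#'   `c("ga_days", "weight_kg")`; `character(0)` forces the constant model.
#' @param weight_transform How maternal weight enters the regression
#'   (default `"log10"`, matching the published Hsa-Let-7g median model).
#' @param min_n Minimum number of detected reference values (default 20).
#' @return A [median_model()].
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 300), seed = 1)
#' noncases <- dplyr::filter(cohort, outcome == "NONCASE")
#' fit_median_model(noncases, "PSME2")
fit_median_model <- function(data, marker, alpha = 0.05,
                             covariates = c("ga_days", "weight_kg"),
                             weight_transform = c("log10", "identity"),
                             min_n = 20) {
  weight_transform <- match.arg(weight_transform)
  covariates <- intersect(covariates, c("ga_days", "weight_kg"))
  flag_col <- paste0(marker, "_below_detection")
  keep <- !is.na(data[[marker]])
  if (flag_col %in% names(data)) keep <- keep & !data[[flag_col]]
  values <- data[[marker]][keep]
  if (length(values) < min_n) {
    abort(paste0("Need at least ", min_n, " detected reference values for ",
                 marker, "; got ", length(values), "."))
  }
  if (any(values <= 0)) abort("Marker levels must be positive.")

  if (length(covariates) > 0) {
    df <- tibble::tibble(
      y = log10(values),
      ga = data$ga_sampling_days[keep],
      w = transform_weight(data$weight_kg[keep], weight_transform)
    )
    terms <- c(ga_days = "ga", weight_kg = "w")[covariates]
    fit <- lm(as.formula(paste("y ~", paste(terms, collapse = " + "))),
              data = df)
    pvals <- suppressWarnings(summary(fit))$coefficients[-1, 4]
    pvals[is.na(pvals)] <- 1  # degenerate fits (e.g. constant response)
    sig <- names(terms)[match(names(pvals)[pvals < alpha], terms)]
    if (length(sig) > 0) {
      keep_terms <- c(ga_days = "ga", weight_kg = "w")[sig]
      fit2 <- lm(as.formula(paste("y ~", paste(keep_terms, collapse = " + "))),
                 data = df)
      co <- coef(fit2)
      coefficients <- c(intercept = unname(co[["(Intercept)"]]))
      if ("ga" %in% names(co)) coefficients["ga_days"] <- co[["ga"]]
      if ("w" %in% names(co)) coefficients["weight"] <- co[["w"]]
      return(median_model(marker, "log_linear", coefficients,
                          weight_transform, n = length(values)))
    }
  }
  median_model(marker, "constant", c(intercept = median(values)),
               weight_transform, n = length(values))
}

#' Published expected-median models
#'
#' The fixed median models printed with the source study's marker tables,
#' shipped as a package fixture so MoMs can be computed without refitting:
#' constant medians for PSME2 (0.85), NAMPT (2.34), APOA1 (0.16) and APOA4
#' (2.44); a log-linear gestational-age and weight model for Hsa-Let-7g;
#' and linear maternal-weight models for cervical length
#' (3.14 + 0.00287 kg, cm) and mean arterial pressure (75.4 + 0.0409 kg,
#' mmHg).
#'
#' @param path Optional path to a YAML file of median-model definitions;
#'   defaults to the packaged fixture.
#' @return Named list of [median_model()] objects, one per marker.
#' @export
#' @examples
#' models <- published_median_models()
#' models$CL_CM
published_median_models <- function(path = NULL) {
  path <- path %||% system.file("extdata", "published_medians.yaml",
                                package = "momscreen", mustWork = TRUE)
  defs <- yaml::read_yaml(path)
  out <- purrr::imap(defs, function(d, marker) {
    co <- c(intercept = d$intercept)
    if (!is.null(d$ga_days)) co["ga_days"] <- d$ga_days
    if (!is.null(d$weight)) co["weight"] <- d$weight
    median_model(marker, d$form, co,
                 weight_transform = d$weight_transform %||% "identity")
  })
  out
}

#' Convert raw marker levels to multiples of the median (MoM)
#'
#' Divides each subject's raw marker value by the expected median at their
#' own covariates, giving a dimensionless MoM that is comparable across
#' gestational age and maternal weight. Below-detection and unmeasured
#' values stay `NA`. The marker columns of the returned tibble are on the
#' MoM scale.
#'
#' @param data Cohort tibble with raw marker columns.
#' @param models Named list of [median_model()]s (default the published
#'   fixtures); markers without a model are left on the raw scale.
#' @return The tibble with marker columns replaced by MoMs.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 50), seed = 1)
#' moms <- mom_normalize(cohort)
#' dplyr::select(moms, subject_id, PSME2, LET7G)
mom_normalize <- function(data, models = published_median_models()) {
  for (m in intersect(names(models), names(data))) {
    expected <- predict(models[[m]], data)
    if (any(expected <= 0, na.rm = TRUE)) {
      abort(paste0("Non-positive expected median for ", m, "."))
    }
    data[[m]] <- data[[m]] / expected
  }
  data
}

#' Long-format MoM profiles
#'
#' Pivots a MoM-normalized cohort into one row per subject and marker, with
#' `mom`, `log10_mom` and the below-detection flag — the shape used by the
#' association screens.
#'
#' @param data MoM-normalized cohort tibble (see [mom_normalize()]).
#' @param markers Markers to include (default all present).
#' @return Tibble with columns `subject_id`, `outcome` (if present),
#'   `marker`, `mom`, `log10_mom`, `below_detection`.
#' @export
mom_profiles <- function(data, markers = intersect(all_markers(), names(data))) {
  id_cols <- intersect(c("subject_id", "outcome"), names(data))
  out <- purrr::map_dfr(markers, function(m) {
    flag_col <- paste0(m, "_below_detection")
    below <- if (flag_col %in% names(data)) data[[flag_col]] else FALSE
    dplyr::bind_cols(
      data[id_cols],
      tibble::tibble(marker = m, mom = data[[m]],
                     log10_mom = log10(data[[m]]),
                     below_detection = below)
    )
  })
  out
}

#' Median MoM of the reference group
#'
#' The sample median (midpoint interpolation) of a marker's MoMs among
#' reference subjects. When the constant median model was fit on the same
#' group this equals 1.0 exactly; regressed models center it near 1.0.
#'
#' @param data MoM-normalized cohort tibble. If an `outcome` column is
#'   present, only `NONCASE` rows are used; otherwise all rows are taken as
#'   the reference group.
#' @param marker Marker column.
#' @return The median MoM, a single number.
#' @export
reference_median_mom <- function(data, marker) {
  if ("outcome" %in% names(data)) {
    data <- dplyr::filter(data, .data$outcome == "NONCASE")
  }
  moms <- data[[marker]][!is.na(data[[marker]])]
  if (length(moms) == 0) {
    abort(paste0("No detected reference MoMs for ", marker, "."))
  }
  median(moms)
}
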