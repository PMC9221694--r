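#' Default group-median MoM effects for the synthetic cohort
#'
#' One row per marker, one column per outcome group, giving the median MoM
#' around which that group's log10 MoM values are centred. RNA and clinical
#' marker values are drawn log10-normally around these medians. Defaults
#' reproduce the published group medians of the source cohort: non-case
#' medians are 1.00 by construction of the MoM scale (1.03 for Hsa-Let-7g,
#' 1.01 for MAP, as observed), case medians are the printed group medians.
#'
#' @return A tibble with columns `marker` and one column per outcome level.
#' @export
#' @examples
#' default_marker_effects()
default_marker_effects <- function() {
  tibble::tribble(
    ~marker,    ~NONCASE, ~PTB_LT37, ~SPTB_LE32, ~PREECLAMPSIA, ~EOP_LT34,
    "PSME2",        1.00,      1.86,       4.09,          2.31,      3.61,
    "NAMPT",        1.00,      1.47,       1.46,          1.69,      3.64,
    "APOA1",        1.00,      1.66,       1.91,          1.62,     15.84,
    "APOA4",        1.00,      0.88,       2.01,          1.26,      2.19,
    "LET7G",        1.03,      2.15,       8.84,          0.58,      5.36,
    "CL_CM",        1.00,      0.89,       0.74,          1.00,      1.00,
    "MAP_MMHG",     1.01,      1.01,       1.01,          1.06,      1.08
  )
}

#' Specify a synthetic screening cohort
#'
#' Builds the parameter set from which [simulate_cohort()] draws a cohort
#' with the statistical structure of the source second-trimester high-risk
#' obstetric cohort: outcome prevalences, covariate frequencies (including
#' prior-preterm-birth history conditional on outcome), group-median MoM
#' effects per marker, log10 MoM spreads, below-detection censoring of the
#' low-abundance RNAs, and availability of the optional clinical markers.
#'
#' Prevalences are given for the nesting strata as the cohort tables print
#' them: `ptb_lt37` includes the `sptb_le32` subset, `preeclampsia` includes
#' `eop_lt34`; the remainder of the cohort is non-case.
#'
#' @param n_subjects Number of subjects (default 289, the source cohort size).
#' @param prevalences Named numeric vector with entries `ptb_lt37`,
#'   `sptb_le32`, `preeclampsia`, `eop_lt34` (cohort proportions; nested).
#' @param covariate_freqs Named list: `race_nhb`, `smoker` (marginal
#'   probabilities); `prior_ptb` (probability of a prior preterm birth given
#'   outcome group: entries `SPTB_LE32`, `PTB_LT37`, `other`);
#'   `early_prior_le32` (probability that the earliest prior preterm birth was
#'   at or before 32 weeks, same keys); `parity` (list of length-3 probability
#'   vectors `c(nulliparous, parity 1-2, parity 3+)` with entries `default`,
#'   `PREECLAMPSIA`, `EOP_LT34`).
#' @param marker_effects Tibble of group median MoMs as returned by
#'   [default_marker_effects()].
#' @param log10_mom_sd Named numeric vector of log10 MoM standard deviations
#'   per marker. The source study reports no spreads; these are free
#'   parameters of the generator.
#' @param detection_censor_frac Named numeric vector in `[0, 1)`: the fraction
#'   of lowest raw values flagged below the qPCR detection limit, per marker.
#' @param measured_frac Named numeric vector: probability that each optional
#'   clinical marker (`CL_CM`, `MAP_MMHG`) was measured.
#' @param weight_mean,weight_sd Maternal weight distribution (kg), truncated
#'   to `[40, 180]`.
#' @param ga_range Integer range of gestational age at sampling, in days
#'   (default 112-146, i.e. 16.0-20.9 weeks).
#' @return An object of class `cohort_spec` (a validated list).
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 100)
#' spec$prevalences
cohort_spec <- function(n_subjects = 289,
                        prevalences = c(ptb_lt37 = 0.253, sptb_le32 = 0.104,
                                        preeclampsia = 0.076, eop_lt34 = 0.021),
                        covariate_freqs = list(
                          race_nhb = 0.85,
                          smoker = 0.273,
                          prior_ptb = c(SPTB_LE32 = 0.83, PTB_LT37 = 0.79,
                                        other = 0.43),
                          early_prior_le32 = c(SPTB_LE32 = 0.92,
                                               PTB_LT37 = 0.74, other = 0.65),
                          parity = list(
                            default = c(0.17, 0.57, 0.26),
                            PREECLAMPSIA = c(0.33, 0.29, 0.38),
                            EOP_LT34 = c(0.17, 0.00, 0.83)
                          )
                        ),
                        marker_effects = default_marker_effects(),
                        log10_mom_sd = c(PSME2 = 0.35, NAMPT = 0.35,
                                         APOA1 = 0.35, APOA4 = 0.35,
                                         LET7G = 0.35, CL_CM = 0.10,
                                         MAP_MMHG = 0.03),
                        detection_censor_frac = c(NAMPT = 0.05, APOA1 = 0.02),
                        measured_frac = c(CL_CM = 154 / 289, MAP_MMHG = 0.95),
                        weight_mean = 80, weight_sd = 18,
                        ga_range = c(112L, 146L)) {
  if (length(n_subjects) != 1 || is.na(n_subjects) || n_subjects < 1) {
    abort("`n_subjects` must be a single positive integer.")
  }
  req <- c("ptb_lt37", "sptb_le32", "preeclampsia", "eop_lt34")
  if (!all(req %in% names(prevalences))) {
    abort(paste0("`prevalences` must name ", paste(req, collapse = ", "), "."))
  }
  prevalences <- prevalences[req]
  if (any(prevalences < 0) || any(prevalences > 1)) {
    abort("Prevalences must lie in [0, 1].")
  }
  if (prevalences[["sptb_le32"]] > prevalences[["ptb_lt37"]]) {
    abort("`sptb_le32` prevalence cannot exceed `ptb_lt37` (nested strata).")
  }
  if (prevalences[["eop_lt34"]] > prevalences[["preeclampsia"]]) {
    abort("`eop_lt34` prevalence cannot exceed `preeclampsia` (nested strata).")
  }
  if (prevalences[["ptb_lt37"]] + prevalences[["preeclampsia"]] > 1) {
    abort("Case prevalences exceed 1; no room left for non-cases.")
  }
  if (any(log10_mom_sd <= 0)) abort("All `log10_mom_sd` must be positive.")
  if (any(detection_censor_frac < 0) || any(detection_censor_frac >= 1)) {
    abort("`detection_censor_frac` values must lie in [0, 1).")
  }
  missing_m <- setdiff(all_markers(), marker_effects$marker)
  if (length(missing_m)) {
    abort(paste0("`marker_effects` missing rows for: ",
                 paste(missing_m, collapse = ", ")))
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      prevalences = prevalences,
      covariate_freqs = covariate_freqs,
      marker_effects = marker_effects,
      log10_mom_sd = log10_mom_sd,
      detection_censor_frac = detection_censor_frac,
      measured_frac = measured_frac,
      weight_mean = weight_mean,
      weight_sd = weight_sd,
      ga_range = as.integer(ga_range)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_subjects, "subjects\n")
  cat("  prevalences:",
      paste(names(x$prevalences), signif(x$prevalences, 3),
            sep = "=", collapse = ", "), "\n")
  cat("  markers:", paste(x$marker_effects$marker, collapse = ", "), "\n")
  invisible(x)
}

# Finest-label outcome probabilities implied by the nested prevalences.
finest_outcome_probs <- function(prevalences) {
  c(
    NONCASE = 1 - prevalences[["ptb_lt37"]] - prevalences[["preeclampsia"]],
    PTB_LT37 = prevalences[["ptb_lt37"]] - prevalences[["sptb_le32"]],
    SPTB_LE32 = prevalences[["sptb_le32"]],
    PREECLAMPSIA = prevalences[["preeclampsia"]] - prevalences[["eop_lt34"]],
    EOP_LT34 = prevalences[["eop_lt34"]]
  )
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  u <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  qnorm(u, mean, sd)
}

#' Simulate a synthetic screening cohort
#'
#' Draws one subject record per row: outcome label (finest stratum),
#' clinical covariates, raw marker values and below-detection flags. For each
#' marker the subject's MoM is drawn log10-normally around the median MoM of
#' their outcome group, then converted to a raw value by multiplying by the
#' expected median at the subject's covariates (from the published median
#' models, see [published_median_models()]), so that re-normalizing the
#' cohort recovers the specified group medians. Prior preterm-birth history
#' is drawn conditionally on outcome; the lowest fraction of NAMPT and APOA1
#' raw values is flagged below the detection limit.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed; identical `spec` + `seed` give an
#'   identical cohort.
#' @return A tibble with one row per subject: `subject_id`,
#'   `ga_sampling_days`, `weight_kg`, `race_nhb`, `smoker`, `parity`,
#'   `prior_ptb`, `earliest_prior_ptb_weeks` (40 when no prior preterm
#'   birth), `outcome`, raw marker columns (`PSME2` ... `LET7G`, `CL_CM`,
#'   `MAP_MMHG`; `NA` when unmeasured or below detection) and
#'   `*_below_detection` flags for the five RNAs.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 50), seed = 1)
#' dplyr::count(cohort, outcome)
simulate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) withr::local_seed(seed)
  n <- spec$n_subjects
  cf <- spec$covariate_freqs

  probs <- finest_outcome_probs(spec$prevalences)
  outcome <- sample(names(probs), n, replace = TRUE, prob = probs)

  ga_sampling_days <- sample(seq(spec$ga_range[1], spec$ga_range[2]), n,
                             replace = TRUE)
  weight_kg <- rtrunc_norm(n, spec$weight_mean, spec$weight_sd, 40, 180)
  race_nhb <- runif(n) < cf$race_nhb
  smoker <- runif(n) < cf$smoker

  parity_key <- dplyr::case_when(
    outcome == "EOP_LT34" ~ "EOP_LT34",
    outcome == "PREECLAMPSIA" ~ "PREECLAMPSIA",
    TRUE ~ "default"
  )
  parity <- vapply(parity_key, function(k) {
    band <- sample.int(3, 1, prob = cf$parity[[k]])
    switch(band, 0L, sample(1:2, 1), sample(3:6, 1))
  }, integer(1), USE.NAMES = FALSE)

  grp_key <- dplyr::case_when(
    outcome == "SPTB_LE32" ~ "SPTB_LE32",
    outcome == "PTB_LT37" ~ "PTB_LT37",
    TRUE ~ "other"
  )
  prior_ptb <- runif(n) < cf$prior_ptb[grp_key]
  parity[prior_ptb & parity == 0L] <- 1L  # a prior birth implies parity >= 1

  early <- runif(n) < cf$early_prior_le32[grp_key]
  earliest_prior_ptb_weeks <- ifelse(
    prior_ptb,
    ifelse(early, runif(n, 16, 32), runif(n, 32, 36)),
    40
  )

  cohort <- tibble::tibble(
    subject_id = sprintf("S%05d", seq_len(n)),
    ga_sampling_days = ga_sampling_days,
    weight_kg = weight_kg,
    race_nhb = race_nhb,
    smoker = smoker,
    parity = parity,
    prior_ptb = prior_ptb,
    earliest_prior_ptb_weeks = earliest_prior_ptb_weeks,
    outcome = outcome
  )

  models <- published_median_models()
  effects <- spec$marker_effects
  for (m in all_markers()) {
    med_by_group <- unlist(effects[effects$marker == m, outcome_levels()])
    mu <- log10(med_by_group[outcome])
    log10_mom <- rnorm(n, mu, spec$log10_mom_sd[[m]])
    expected <- predict(models[[m]], cohort)
    cohort[[m]] <- 10^log10_mom * expected
  }

  for (m in c("CL_CM", "MAP_MMHG")) {
    frac <- spec$measured_frac[[m]]
    if (!is.null(frac) && frac < 1) {
      cohort[[m]][runif(n) >= frac] <- NA_real_
    }
  }

  for (m in rna_markers()) {
    flag <- rep(FALSE, n)
    frac <- spec$detection_censor_frac[m]
    if (!is.na(frac) && frac > 0) {
      k <- round(frac * n)
      if (k > 0) flag[order(cohort[[m]])[seq_len(k)]] <- TRUE
      cohort[[m]][flag] <- NA_real_
    }
    cohort[[paste0(m, "_below_detection")]] <- flag
  }

  cohort
}

#' Write / read a cohort table
#'
#' Cohorts are exchanged as UTF-8 comma-separated text with a header row and
#' empty fields for missing values. `write_cohort()` and [read_cohort()]
#' round-trip losslessly: write, read, write again gives a byte-identical
#' file.
#'
#' @param cohort A cohort tibble as produced by [simulate_cohort()] or
#'   [read_cohort()].
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (nrow(cohort) == 0) abort("Refusing to write an empty cohort.")
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}
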