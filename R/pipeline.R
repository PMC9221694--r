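cohort_schema <- function() {
  c(
    subject_id = "c", ga_sampling_days = "i", weight_kg = "d",
    race_nhb = "l", smoker = "l", parity = "i", prior_ptb = "l",
    earliest_prior_ptb_weeks = "d", outcome = "c",
    PSME2 = "d", NAMPT = "d", APOA1 = "d", APOA4 = "d", LET7G = "d",
    CL_CM = "d", MAP_MMHG = "d",
    PSME2_below_detection = "l", NAMPT_below_detection = "l",
    APOA1_below_detection = "l", APOA4_below_detection = "l",
    LET7G_below_detection = "l"
  )
}

#' Read a cohort table
#'
#' Reads the delimited cohort schema written by [write_cohort()]: typed
#' columns, empty fields as missing. Unknown outcome labels are rejected
#' with their row numbers; duplicate subject ids are an error; an empty data
#' section yields an empty cohort with a warning.
#'
#' @param path Path to a cohort CSV file.
#' @return A cohort tibble (see [simulate_cohort()] for the columns).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  schema <- cohort_schema()
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(names(schema)[1:9], header)
  if (length(missing_cols)) {
    abort(paste0("Cohort file lacks required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  present <- intersect(names(schema), header)
  # read everything as text, then convert with base R parsers: strtod is
  # correctly rounded, so numeric values survive write -> read bit-exactly
  cohort <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), na = "")
  for (col in header) {
    type <- schema[col]
    if (is.na(type)) next
    cohort[[col]] <- switch(type,
      d = as.numeric(cohort[[col]]),
      i = as.integer(cohort[[col]]),
      l = as.logical(cohort[[col]]),
      cohort[[col]]
    )
  }
  cohort <- cohort[, c(present, setdiff(header, present)), drop = FALSE]
  if (nrow(cohort) == 0) {
    warn("Cohort file has a header but no data rows.")
    return(cohort)
  }
  bad <- which(!cohort$outcome %in% outcome_levels())
  if (length(bad)) {
    abort(paste0("Unknown outcome label in data row(s) ",
                 paste(bad, collapse = ", "), ": ",
                 paste(unique(cohort$outcome[bad]), collapse = ", ")))
  }
  dup <- cohort$subject_id[duplicated(cohort$subject_id)]
  if (length(dup)) {
    abort(paste0("Duplicate subject_id: ", paste(unique(dup), collapse = ", ")))
  }
  cohort
}

#' Serialize / read a risk model
#'
#' Risk models (including missingness variants) round-trip through a
#' structured YAML file: outcome, intercept, term list and variants.
#'
#' @param model A `risk_model`.
#' @param path File path.
#' @return `write_risk_model()` returns `path` invisibly; `read_risk_model()`
#'   returns the `risk_model`.
#' @export
write_risk_model <- function(model, path) {
  as_list <- function(m) {
    list(
      outcome = m$outcome,
      intercept = m$intercept,
      terms = purrr::pmap(m$terms, function(predictor, transform, coefficient) {
        list(predictor = predictor, transform = transform,
             coefficient = coefficient)
      })
    )
  }
  obj <- as_list(model)
  if (length(model$variants)) {
    obj$variants <- purrr::map(model$variants, as_list)
  }
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  obj <- yaml::read_yaml(path)
  from_list <- function(d, label) {
    new_risk_model(d$outcome, d$intercept,
                   purrr::map_dfr(d$terms, tibble::as_tibble),
                   converged = TRUE, label = label)
  }
  model <- from_list(obj, label = basename(path))
  if (!is.null(obj$variants)) {
    model$variants <- purrr::imap(obj$variants, from_list)
  }
  model
}

#' Configure an end-to-end analysis run
#'
#' Bundles the settings of [run_full_analysis()]: exactly one input source
#' (a cohort file or a simulation [cohort_spec()]), the significance level
#' of the univariate screen, the FPR grid, whether expected medians come
#' from the packaged fixtures or are refit on the cohort's non-cases,
#' whether risk models are the published equations or refit, the seed and
#' an optional output directory.
#'
#' @param input Path to a cohort CSV, or `NULL` when simulating.
#' @param spec A [cohort_spec()], or `NULL` when reading a file.
#' @param alpha Univariate screen significance level (default 0.05).
#' @param fprs Fixed false-positive rates (default 10/20/30%).
#' @param median_mode `"fixtures"` (published median models) or `"fit"`
#'   (refit RNA medians on the cohort's non-cases; CL and MAP always use
#'   their published linear models).
#' @param equation_mode `"published"` (the four fixed equations) or `"fit"`
#'   (refit logistic models on screened predictors, with missingness
#'   variants).
#' @param seed Integer seed driving all randomness of the run.
#' @param output_dir Optional directory for report files.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, spec = NULL, alpha = 0.05,
                       fprs = c(0.10, 0.20, 0.30),
                       median_mode = c("fixtures", "fit"),
                       equation_mode = c("published", "fit"),
                       seed = 1L, output_dir = NULL) {
  if (is.null(input) == is.null(spec)) {
    abort("Provide exactly one input source: `input` file or simulation `spec`.")
  }
  if (any(fprs <= 0 | fprs >= 1)) abort("FPRs must lie in (0, 1).")
  structure(
    list(input = input, spec = spec, alpha = alpha, fprs = fprs,
         median_mode = match.arg(median_mode),
         equation_mode = match.arg(equation_mode),
         seed = as.integer(seed), output_dir = output_dir),
    class = "run_config"
  )
}

#' Read a run configuration file
#'
#' Flat key-value YAML with the fields of [run_config()]; a `spec: default`
#' entry (optionally with `n_subjects`) requests simulation from the default
#' cohort specification.
#'
#' @param path Path to a YAML config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  d <- yaml::read_yaml(path)
  spec <- NULL
  if (!is.null(d$spec)) {
    spec <- if (identical(d$spec, "default")) cohort_spec() else
      cohort_spec(n_subjects = d$spec$n_subjects %||% 289)
  }
  run_config(
    input = d$input, spec = spec,
    alpha = d$alpha %||% 0.05,
    fprs = unlist(d$fprs) %||% c(0.10, 0.20, 0.30),
    median_mode = d$median_mode %||% "fixtures",
    equation_mode = d$equation_mode %||% "published",
    seed = d$seed %||% 1L,
    output_dir = d$output_dir
  )
}

# Predictor sets considered per outcome stratum.
outcome_predictor_plan <- function() {
  list(
    SPTB_LE32 = list(markers = c(rna_markers(), "CL_CM"),
                     clinical = c("race_other", "earliest_prior_ptb_weeks")),
    PTB_LT37 = list(markers = c(rna_markers(), "CL_CM"),
                    clinical = c("race_other", "smoker",
                                 "earliest_prior_ptb_weeks")),
    PREECLAMPSIA = list(markers = c(rna_markers(), "MAP_MMHG"),
                        clinical = c("nulliparous", "parity_1_2")),
    EOP_LT34 = list(markers = c(rna_markers(), "MAP_MMHG"),
                    clinical = c("nulliparous", "parity_1_2"))
  )
}

#' Run the full screening analysis
#'
#' Executes the pipeline end to end: load or simulate the cohort, fill
#' CT-mode expression columns if present, fit or load median models,
#' convert to MoMs, run the univariate association screen per outcome
#' stratum, select significant markers, fit risk models (or apply the
#' published equations), and evaluate screening performance. When no marker
#' passes the screen, a clinical-covariates-only model is reported rather
#' than failing. Everything is reproducible from the input, the
#' configuration and the seed.
#'
#' @param config A [run_config()].
#' @return A list: `cohort`, `median_models`, `association` (one marker
#'   table per outcome stratum), `models` (named `risk_model` list),
#'   `performance` (tibble: AUC, CI and DR columns per model), `log`
#'   (character vector of run decisions). If `config$output_dir` is set the
#'   tables, models and log are also written there as delimited text/YAML.
#' @export
#' @examples
#' cfg <- run_config(spec = cohort_spec(n_subjects = 250), seed = 7)
#' res <- run_full_analysis(cfg)
#' res$performance
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  run_log <- c(
    paste0("momscreen version: ",
           as.character(utils::packageVersion("momscreen"))),
    paste0("seed: ", config$seed),
    paste0("alpha: ", config$alpha),
    paste0("median_mode: ", config$median_mode),
    paste0("equation_mode: ", config$equation_mode),
    paste0("fprs: ", paste(config$fprs, collapse = ", ")),
    "multiple-testing correction: none (per the source analysis)"
  )

  cohort <- if (!is.null(config$input)) read_cohort(config$input) else
    simulate_cohort(config$spec, seed = config$seed)
  run_log <- c(run_log, paste0("cohort: ", nrow(cohort), " subjects from ",
                       if (!is.null(config$input)) config$input else
                         "simulation"))
  cohort <- preprocess_ct(cohort)

  fixtures <- published_median_models()
  median_models <- fixtures
  if (config$median_mode == "fit") {
    noncases <- dplyr::filter(cohort, .data$outcome == "NONCASE")
    for (m in intersect(rna_markers(), names(cohort))) {
      fitted <- tryCatch(fit_median_model(noncases, m),
                         error = function(e) NULL)
      if (is.null(fitted)) {
        run_log <- c(run_log, paste0("median model ", m,
                             ": too few reference values; fixture kept"))
      } else {
        median_models[[m]] <- fitted
        run_log <- c(run_log, paste0("median model ", m, ": refit as ", fitted$form))
      }
    }
  }
  moms <- mom_normalize(cohort, median_models)

  plan <- outcome_predictor_plan()
  association <- list()
  models <- list()
  perf_rows <- list()
  for (grp in names(plan)) {
    markers_here <- intersect(plan[[grp]]$markers, names(moms))
    assoc <- associate_markers(moms, grp, markers = markers_here)
    association[[grp]] <- assoc
    sig <- select_significant_markers(
      dplyr::rename(assoc, comparison = "marker"), config$alpha
    )
    run_log <- c(run_log, paste0(grp, ": significant markers at alpha ",
                         config$alpha, ": ",
                         if (length(sig)) paste(sig, collapse = ", ")
                         else "(none; covariates-only model)"))

    model <- if (config$equation_mode == "published") {
      eq_name <- if (grp == "PREECLAMPSIA") "PE_ALL" else grp
      published_equation(eq_name)
    } else {
      predictors <- c(sig, plan[[grp]]$clinical)
      withCallingHandlers(
        tryCatch(
          fit_missingness_variants(moms, grp, predictors),
          error = function(e) {
            run_log <<- c(run_log, paste0(grp, ": fit skipped (", conditionMessage(e),
                                  ")"))
            NULL
          }
        ),
        warning = function(w) {
          run_log <<- c(run_log, paste0(grp, ": ", conditionMessage(w)))
          invokeRestart("muffleWarning")
        },
        message = function(m) {
          run_log <<- c(run_log, paste0(grp, ": ", trimws(conditionMessage(m))))
          invokeRestart("muffleMessage")
        }
      )
    }
    if (is.null(model)) next
    models[[grp]] <- model

    res <- withCallingHandlers(
      tryCatch(
        evaluate_model(moms, model, case_group = grp, fprs = config$fprs),
        error = function(e) {
          run_log <<- c(run_log, paste0(grp, ": evaluation skipped (",
                                conditionMessage(e), ")"))
          NULL
        }
      ),
      message = function(m) {
        run_log <<- c(run_log, paste0(grp, ": ", trimws(conditionMessage(m))))
        invokeRestart("muffleMessage")
      }
    )
    if (is.null(res)) next
    row <- glance(res)
    for (i in seq_len(nrow(res$rates))) {
      row[[paste0("dr_fpr", 100 * res$rates$fpr[i])]] <-
        res$rates$detection_rate[i]
    }
    perf_rows[[grp]] <- row
  }
  performance <- dplyr::bind_rows(perf_rows)

  out <- list(cohort = cohort, median_models = median_models,
              association = association, models = models,
              performance = performance, log = run_log)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (grp in names(association)) {
      readr::write_csv(association[[grp]],
                       file.path(config$output_dir,
                                 paste0("association_", grp, ".csv")))
    }
    if (nrow(performance) > 0) {
      readr::write_csv(performance,
                       file.path(config$output_dir, "performance.csv"))
    }
    for (grp in names(models)) {
      write_risk_model(models[[grp]],
                       file.path(config$output_dir,
                                 paste0("model_", grp, ".yaml")))
    }
    writeLines(run_log, file.path(config$output_dir, "run_log.txt"))
  }
  out
}
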