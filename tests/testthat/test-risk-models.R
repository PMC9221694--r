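test_that("published equations reproduce hand arithmetic on a grid of inputs", {
  eq32 <- published_equation("SPTB_LE32")
  eq37 <- published_equation("PTB_LT37")
  eqe <- published_equation("EOP_LT34")
  eqp <- published_equation("PE_ALL")

  # the three worked single-point checks
  r1 <- score_risk(mom_fixture_row(), eq32)
  expect_equal(r1$x, 1.4677 - 0.1119 * 40, tolerance = 1e-12)
  expect_equal(r1$p, 0.047, tolerance = 1e-2)

  r2 <- score_risk(mom_fixture_row(parity = 0L), eqe)
  expect_equal(r2$x, -7.900 + 3.6091, tolerance = 1e-12)
  expect_equal(r2$p, 0.0135, tolerance = 1e-3)

  r3 <- score_risk(mom_fixture_row(parity = 0L), eqp)
  expect_equal(r3$x, -2.1134 + 0.8873, tolerance = 1e-12)
  expect_equal(r3$p, 0.227, tolerance = 1e-3)

  r4 <- score_risk(mom_fixture_row(), eq37)
  expect_equal(r4$x, 2.9733 - 0.1111 * 40, tolerance = 1e-12)
  expect_equal(r4$p, plogis(-1.4707), tolerance = 1e-6)

  # grid over MoMs, race, smoking, parity, history
  grid <- expand.grid(
    mom = c(0.25, 1, 3.7), race_other = c(0, 1), smoker = c(0, 1),
    parity = c(0L, 2L, 4L), earliest = c(22.5, 31, 40)
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    row <- mom_fixture_row(
      PSME2 = g$mom, NAMPT = g$mom * 1.3, APOA1 = g$mom / 2,
      LET7G = g$mom^2, MAP_MMHG = 1.07,
      race_nhb = g$race_other == 0, smoker = g$smoker == 1,
      parity = g$parity, prior_ptb = g$earliest < 40,
      earliest_prior_ptb_weeks = g$earliest
    )
    expect_equal(score_risk(row, eq32)$x,
                 hand_x_sptb_le32(g$mom, g$mom^2, g$race_other, g$earliest),
                 tolerance = 1e-9)
    expect_equal(score_risk(row, eq37)$x,
                 hand_x_ptb_lt37(g$mom, g$race_other, g$smoker, g$earliest),
                 tolerance = 1e-9)
    expect_equal(score_risk(row, eqe)$x,
                 hand_x_eop(g$mom * 1.3, g$mom / 2, g$parity == 0,
                            g$parity %in% 1:2),
                 tolerance = 1e-9)
    expect_equal(score_risk(row, eqp)$x,
                 hand_x_pe(g$mom * 1.3, 1.07, g$parity == 0,
                           g$parity %in% 1:2),
                 tolerance = 1e-9)
  }
})

test_that("risk scores respect the logistic link and are deterministic", {
  null_model <- momscreen:::new_risk_model(
    "SPTB_LE32", 0, tibble::tibble(predictor = character(0),
                                   transform = character(0),
                                   coefficient = numeric(0))
  )
  expect_equal(score_risk(mom_fixture_row(), null_model)$p, 0.5)

  eq <- published_equation("SPTB_LE32")
  x1 <- score_risk(mom_fixture_row(PSME2 = 1), eq)$x
  x2 <- score_risk(mom_fixture_row(PSME2 = 2), eq)$x
  expect_equal(x2 - x1, 0.5732 * log10(2), tolerance = 1e-12)
  # p strictly increasing in a positive-coefficient predictor
  expect_gt(score_risk(mom_fixture_row(PSME2 = 2), eq)$p,
            score_risk(mom_fixture_row(PSME2 = 1), eq)$p)
  # repeat scoring is exact arithmetic
  expect_identical(score_risk(mom_fixture_row(), eq),
                   score_risk(mom_fixture_row(), eq))
})

test_that("the logistic fit agrees with a textbook IRLS oracle to 6+ decimals", {
  withr::with_seed(12, {
    x <- rnorm(20)
    y <- rbinom(20, 1, plogis(0.3 + 0.8 * x))
  })
  data <- tibble::tibble(
    subject_id = as.character(1:20), ga_sampling_days = 130L,
    weight_kg = 80, race_nhb = TRUE, smoker = FALSE, parity = 1L,
    prior_ptb = FALSE, earliest_prior_ptb_weeks = 40,
    outcome = ifelse(y == 1, "SPTB_LE32", "NONCASE"),
    PSME2 = 10^x
  )
  fit <- fit_risk_model(data, "SPTB_LE32", "PSME2", min_cases = 3)
  oracle <- unname(irls_logistic_oracle(cbind(1, x), y))
  expect_equal(fit$intercept, oracle[1], tolerance = 1e-7)
  expect_equal(fit$terms$coefficient, oracle[2], tolerance = 1e-7)
})

test_that("fits on outcome-independent predictors find no signal", {
  withr::with_seed(13, {
    n <- 800
    data <- tibble::tibble(
      subject_id = as.character(1:n), ga_sampling_days = 130L,
      weight_kg = 80, race_nhb = runif(n) < 0.85, smoker = runif(n) < 0.3,
      parity = sample(0:4, n, TRUE), prior_ptb = FALSE,
      earliest_prior_ptb_weeks = 40,
      outcome = sample(c("SPTB_LE32", "NONCASE"), n, TRUE, prob = c(0.2, 0.8)),
      PSME2 = 10^rnorm(n, 0, 0.35),
      LET7G = 10^rnorm(n, 0, 0.35)
    )
  })
  fit <- fit_risk_model(data, "SPTB_LE32", c("PSME2", "LET7G"))
  expect_true(all(abs(fit$terms$coefficient) < 0.5))
  expect_false(fit$separation)
})

test_that("quasi-separation is reported and the ridge fallback stays finite", {
  withr::with_seed(14, {
    n <- 200
    parity <- sample(c(0L, 1L, 4L), n, TRUE)
    # no case ever has parity 1-2: separation in that indicator
    case <- rbinom(n, 1, ifelse(parity %in% 1:2, 0, 0.3)) == 1
    data <- tibble::tibble(
      subject_id = as.character(1:n), ga_sampling_days = 130L,
      weight_kg = 80, race_nhb = TRUE, smoker = FALSE, parity = parity,
      prior_ptb = FALSE, earliest_prior_ptb_weeks = 40,
      outcome = ifelse(case, "EOP_LT34", "NONCASE"),
      NAMPT = 10^rnorm(n, ifelse(case, 0.3, 0), 0.35)
    )
  })
  expect_warning(
    fit <- fit_risk_model(data, "EOP_LT34", c("NAMPT", "parity_1_2")),
    "separation"
  )
  expect_true(fit$separation)
  ridge <- fit_risk_model(data, "EOP_LT34", c("NAMPT", "parity_1_2"),
                          ridge = TRUE)
  expect_true(all(is.finite(ridge$terms$coefficient)))
  expect_lt(abs(ridge$terms$coefficient[2]), 50)
})

test_that("missingness variants are keyed by observed predictor patterns", {
  cohort <- simulate_cohort(cohort_spec(n_subjects = 2000), seed = 15)
  moms <- mom_normalize(cohort)
  model <- fit_missingness_variants(moms, "PREECLAMPSIA",
                                    c("NAMPT", "APOA1", "nulliparous"))
  expect_s3_class(model, "risk_model")
  expect_gt(length(model$variants), 0)
  expect_true(all(grepl("APOA1|NAMPT|nulliparous|covariates",
                        names(model$variants))))

  scored <- score_risk(moms, model)
  expect_equal(nrow(scored), nrow(moms))
  expect_false(any(is.na(scored$p)))
  # complete subjects are scored by the full model, exactly as if no
  # variants existed
  complete <- !is.na(moms$NAMPT) & !is.na(moms$APOA1)
  plain <- model
  plain$variants <- list()
  scored_plain <- score_risk(moms[complete, ], plain)
  expect_equal(scored$p[complete], scored_plain$p)

  # no missingness -> no variants
  clean <- moms[complete, ]
  single <- fit_missingness_variants(clean, "PREECLAMPSIA",
                                     c("NAMPT", "APOA1", "nulliparous"))
  expect_length(single$variants, 0)
})

test_that("scoring without a matching variant errors, drops or NAs as asked", {
  moms <- mom_normalize(simulate_cohort(cohort_spec(n_subjects = 300),
                                        seed = 16))
  eq <- published_equation("EOP_LT34")  # no variants shipped
  n_miss <- sum(is.na(moms$NAMPT) | is.na(moms$APOA1))
  expect_gt(n_miss, 0)
  expect_error(score_risk(moms, eq), "no model variant")
  expect_message(dropped <- score_risk(moms, eq, incomplete = "drop"))
  expect_equal(nrow(dropped), nrow(moms) - n_miss)
  expect_message(kept <- score_risk(moms, eq, incomplete = "na"))
  expect_equal(sum(is.na(kept$p)), n_miss)
})

test_that("risk models serialize to YAML and back unchanged", {
  dir <- withr::local_tempdir()
  moms <- mom_normalize(simulate_cohort(cohort_spec(n_subjects = 1000),
                                        seed = 17))
  model <- fit_missingness_variants(moms, "PTB_LT37",
                                    c("PSME2", "NAMPT", "race_other"))
  path <- file.path(dir, "model.yaml")
  write_risk_model(model, path)
  back <- read_risk_model(path)
  expect_equal(back$intercept, model$intercept, tolerance = 1e-12)
  expect_equal(back$terms, model$terms, tolerance = 1e-12)
  expect_setequal(names(back$variants), names(model$variants))
  scored_a <- score_risk(moms, model)
  scored_b <- score_risk(moms, back)
  expect_equal(scored_a$p, scored_b$p, tolerance = 1e-12)
})

test_that("coefficients simulated from the published equation are recovered", {
  # moderate n keeps the default suite quick; the full-scale (n = 5000)
  # recovery check runs in the acceptance suite
  data <- simulate_from_equation32(seed = 18, n = 3000)
  fit <- fit_risk_model(data, "SPTB_LE32",
                        c("PSME2", "LET7G", "race_other",
                          "earliest_prior_ptb_weeks"))
  truth <- c(0.5732, 0.8268, -1.8931, -0.1119)
  expect_true(all(abs(fit$terms$coefficient - truth) / abs(truth) < 0.15))
})
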