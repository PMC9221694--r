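ref_frame <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      subject_id = sprintf("R%04d", seq_len(n)),
      ga_sampling_days = sample(112:146, n, replace = TRUE),
      weight_kg = runif(n, 40, 180),
      outcome = "NONCASE"
    )
  })
}

test_that("trendless reference data yield the constant overall median", {
  df <- ref_frame(50, seed = 1)
  df$PSME2 <- rep(0.85, 50)
  m <- fit_median_model(df, "PSME2")
  expect_s3_class(m, "median_model")
  expect_equal(m$form, "constant")
  expect_equal(unname(m$coefficients["intercept"]), 0.85)
  expect_equal(predict(m, df), rep(0.85, 50))
})

test_that("log-linear median parameters are recovered from simulated data", {
  n <- 1000
  df <- ref_frame(n, seed = 2)
  truth <- c(intercept = -0.515, ga_days = 0.0106, weight = -0.232)
  withr::with_seed(3, {
    mu <- truth["intercept"] + truth["ga_days"] * df$ga_sampling_days +
      truth["weight"] * log10(df$weight_kg)
    df$LET7G <- 10^(mu + rnorm(n, 0, 0.05))
  })
  m <- fit_median_model(df, "LET7G", weight_transform = "log10")
  expect_equal(m$form, "log_linear")
  for (term in names(truth)) {
    expect_lt(abs(m$coefficients[[term]] - truth[[term]]) / abs(truth[[term]]),
              0.10)
  }
})

test_that("the covariate gate keeps the constant form on trend-free data", {
  nsim <- 200
  n_const <- 0
  for (i in seq_len(nsim)) {
    df <- ref_frame(200, seed = 100 + i)
    withr::with_seed(300 + i, df$PSME2 <- 10^rnorm(200, log10(0.85), 0.3))
    m <- fit_median_model(df, "PSME2")
    n_const <- n_const + (m$form == "constant")
  }
  # under no trend, a spurious log-linear form needs one of two independent
  # slope tests to fire: P(constant) = (1 - alpha)^2 = 0.9025
  p0 <- (1 - 0.05)^2
  se <- sqrt(p0 * (1 - p0) / nsim)
  expect_lt(abs(n_const / nsim - p0), 3 * se)
})

test_that("CL and MAP MoMs match arithmetic on the published linear medians", {
  row <- mom_fixture_row(CL_CM = 3.34, MAP_MMHG = 86.4)
  row$weight_kg <- 70
  moms <- mom_normalize(row)
  expect_equal(moms$CL_CM, 3.34 / (3.14 + 0.00287 * 70), tolerance = 1e-12)
  expect_equal(moms$CL_CM, 0.9997, tolerance = 1e-4)
  expect_equal(moms$MAP_MMHG, 86.4 / (75.4 + 0.0409 * 70), tolerance = 1e-12)
  expect_equal(moms$MAP_MMHG, 1.104, tolerance = 1e-3)
})

test_that("raw value equal to the expected median gives MoM exactly 1", {
  row <- mom_fixture_row()
  models <- published_median_models()
  row$PSME2 <- predict(models$PSME2, row)
  row$LET7G <- predict(models$LET7G, row)
  moms <- mom_normalize(row, models)
  expect_equal(moms$PSME2, 1)
  expect_equal(moms$LET7G, 1)
})

test_that("non-case median MoM is 1 after constant normalization, near 1 after regression", {
  df <- ref_frame(201, seed = 4)
  withr::with_seed(5, df$PSME2 <- 10^rnorm(201, 0, 0.35))
  const <- fit_median_model(df, "PSME2", covariates = character(0))
  moms <- mom_normalize(df, list(PSME2 = const))
  expect_equal(reference_median_mom(moms, "PSME2"), 1.0)

  # even n exercises midpoint interpolation
  df2 <- df[1:200, ]
  const2 <- fit_median_model(df2, "PSME2", covariates = character(0))
  expect_equal(reference_median_mom(mom_normalize(df2, list(PSME2 = const2)),
                                    "PSME2"), 1.0)

  # single subject: MoM itself
  expect_equal(
    reference_median_mom(mom_normalize(df[1, ], list(PSME2 = const)), "PSME2"),
    df$PSME2[1] / const$coefficients[["intercept"]]
  )

  # regressed median centres its own training group within 0.02 of 1
  n <- 1000
  dfl <- ref_frame(n, seed = 6)
  withr::with_seed(7, {
    mu <- -0.515 + 0.0106 * dfl$ga_sampling_days - 0.232 * log10(dfl$weight_kg)
    dfl$LET7G <- 10^(mu + rnorm(n, 0, 0.2))
  })
  ml <- fit_median_model(dfl, "LET7G", weight_transform = "log10")
  expect_equal(ml$form, "log_linear")
  momsl <- mom_normalize(dfl, list(LET7G = ml))
  expect_lt(abs(reference_median_mom(momsl, "LET7G") - 1), 0.02)
})

test_that("MoMs are equivariant to rescaling the raw marker values", {
  df <- ref_frame(151, seed = 8)
  withr::with_seed(9, df$PSME2 <- 10^rnorm(151, 0, 0.3))
  m1 <- fit_median_model(df, "PSME2", covariates = character(0))
  moms1 <- mom_normalize(df, list(PSME2 = m1))

  df_k <- df
  df_k$PSME2 <- df$PSME2 * 7.3
  m2 <- fit_median_model(df_k, "PSME2", covariates = character(0))
  moms2 <- mom_normalize(df_k, list(PSME2 = m2))
  expect_equal(moms2$PSME2, moms1$PSME2)
  # rank order among identical covariates is preserved
  expect_identical(order(moms1$PSME2), order(df$PSME2))
})

test_that("fitting guards reject unusable reference data", {
  df <- ref_frame(10, seed = 10)
  df$PSME2 <- 10^rnorm(10)
  expect_error(fit_median_model(df, "PSME2"), "at least 20")

  df2 <- ref_frame(30, seed = 11)
  df2$PSME2 <- 10^rnorm(30)
  df2$PSME2_below_detection <- TRUE
  expect_error(fit_median_model(df2, "PSME2"), "at least 20")
})

test_that("published median fixtures load with the printed constants", {
  models <- published_median_models()
  expect_setequal(names(models), all_markers())
  expect_equal(models$PSME2$coefficients[["intercept"]], 0.85)
  expect_equal(models$NAMPT$coefficients[["intercept"]], 2.34)
  expect_equal(models$APOA1$coefficients[["intercept"]], 0.16)
  expect_equal(models$APOA4$coefficients[["intercept"]], 2.44)
  expect_equal(models$LET7G$form, "log_linear")
  expect_equal(models$LET7G$weight_transform, "log10")
  # Let-7g median at 129 days, 80 kg is on a plausible expression scale
  med <- predict(models$LET7G,
                 tibble::tibble(ga_sampling_days = 129, weight_kg = 80))
  expect_gt(med, 0.5)
  expect_lt(med, 20)
})
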