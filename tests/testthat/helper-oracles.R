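# Independent small-scale oracles used to cross-check the package's
# statistics. These deliberately use brute force / textbook formulas, not the
# code paths they verify.

# Exact two-sided Wilcoxon rank-sum p-value by enumerating every assignment
# of the pooled ranks to the case group (tie-free data only).
enumerate_wilcoxon_p <- function(case, noncase, tails = 2) {
  pooled <- c(case, noncase)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(case)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  if (tails == 2) {
    mean(abs(w_all - mu) >= abs(w_obs - mu))
  } else {
    mean(w_all >= w_obs)
  }
}

# AUC by exhaustive counting over all case x control pairs, ties half credit.
pairwise_auc <- function(case, control) {
  total <- 0
  for (s in case) {
    total <- total + sum(s > control) + 0.5 * sum(s == control)
  }
  total / (length(case) * length(control))
}

# Textbook Newton/IRLS logistic regression on a design matrix with
# intercept; convergence on max coefficient change.
irls_logistic_oracle <- function(X, y, maxit = 200, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- drop(solve(crossprod(X, X * w), crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

# Hand evaluation of a published risk equation's linear predictor, written
# out term by term, independently of risk_term_values()/score_risk().
hand_x_sptb_le32 <- function(psme2_mom, let7g_mom, race_other, earliest_wk) {
  1.4677 + 0.5732 * log10(psme2_mom) + 0.8268 * log10(let7g_mom) -
    1.8931 * race_other - 0.1119 * earliest_wk
}
hand_x_ptb_lt37 <- function(psme2_mom, race_other, smoker, earliest_wk) {
  2.9733 + 0.1964 * log10(psme2_mom) - 1.3671 * race_other -
    0.8335 * smoker - 0.1111 * earliest_wk
}
hand_x_eop <- function(nampt_mom, apoa1_mom, nulliparous, parity_1_2) {
  -7.900 + 2.2726 * log10(nampt_mom) + 0.8267 * log10(apoa1_mom) +
    3.6091 * nulliparous - 7.9772 * parity_1_2
}
hand_x_pe <- function(nampt_mom, map_mom, nulliparous, parity_1_2) {
  -2.1134 + 1.0161 * log10(nampt_mom) + 21.5283 * log10(map_mom) +
    0.8873 * nulliparous - 0.8217 * parity_1_2
}

# Cohort simulated from the published early-sPTB equation: case status drawn
# Bernoulli(p(x)) from hand_x_sptb_le32 over a wide, well-conditioned
# predictor design (marker log10 MoMs ~ N(1.5, 1.5), balanced race and
# prior-PTB history). Used for coefficient-recovery checks.
simulate_from_equation32 <- function(seed, n) {
  withr::with_seed(seed, {
    prior <- runif(n) < 0.6
    data <- tibble::tibble(
      subject_id = sprintf("E%05d", seq_len(n)), ga_sampling_days = 130L,
      weight_kg = 80, race_nhb = runif(n) < 0.5, smoker = FALSE,
      parity = 1L, prior_ptb = prior,
      earliest_prior_ptb_weeks = ifelse(prior, runif(n, 16, 30), 40),
      PSME2 = 10^rnorm(n, 1.5, 1.5), LET7G = 10^rnorm(n, 1.5, 1.5)
    )
    x <- hand_x_sptb_le32(data$PSME2, data$LET7G, !data$race_nhb,
                          data$earliest_prior_ptb_weeks)
    data$outcome <- ifelse(runif(n) < stats::plogis(x), "SPTB_LE32", "NONCASE")
    data
  })
}

# Minimal MoM-scale cohort rows for scoring tests: markers already in MoM.
mom_fixture_row <- function(PSME2 = 1, NAMPT = 1, APOA1 = 1, APOA4 = 1,
                            LET7G = 1, CL_CM = 1, MAP_MMHG = 1,
                            race_nhb = TRUE, smoker = FALSE, parity = 3L,
                            prior_ptb = FALSE, earliest_prior_ptb_weeks = 40,
                            outcome = "NONCASE") {
  tibble::tibble(
    subject_id = "X", ga_sampling_days = 130L, weight_kg = 80,
    race_nhb = race_nhb, smoker = smoker, parity = parity,
    prior_ptb = prior_ptb,
    earliest_prior_ptb_weeks = earliest_prior_ptb_weeks,
    outcome = outcome,
    PSME2 = PSME2, NAMPT = NAMPT, APOA1 = APOA1, APOA4 = APOA4,
    LET7G = LET7G, CL_CM = CL_CM, MAP_MMHG = MAP_MMHG
  )
}
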