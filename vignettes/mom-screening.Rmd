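---
title: "MoM normalization and risk models for plasma cell-free RNA screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MoM normalization and risk models for plasma cell-free RNA screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momscreen)
library(dplyr)
```

## The screening problem

Spontaneous preterm birth (sPTB) and early-onset preeclampsia (EOP) are the
leading causes of perinatal death and disability, and both are largely
"set" early in pregnancy. A panel of five maternal plasma cell-free RNAs
(*PSME2*, *NAMPT*, *APOA1*, *APOA4*, *Hsa-Let-7g*) measured at 16–20 weeks'
gestation, combined with clinical history, can be turned into per-pregnancy
risk scores for four outcome strata: sPTB at or before 32 weeks, all sPTB
before 37 weeks, all preeclampsia, and EOP delivered before 34 weeks.
`momscreen` implements that analysis end to end — expression preprocessing,
multiple-of-the-median (MoM) normalization, univariate association screens,
logistic risk modelling with missingness-pattern sub-models, and screening
performance summaries — together with a synthetic cohort generator so the
whole pipeline is testable without access to patient data.

The package follows prenatal-screening conventions throughout: marker
levels are expressed as MoMs, model performance is reported as the area
under the ROC curve (AUC) and as detection rates (DR) at fixed
false-positive rates (FPR), and the comparator ("non-case") group contains
pregnancies with neither preterm birth nor preeclampsia.

## From threshold cycles to expression

qPCR threshold cycles convert to relative expression by the delta-delta CT
method,

$$\mathrm{expression} = 2^{-\Delta\Delta C_T},\qquad
\Delta\Delta C_T = (C_T^{\text{marker}} - C_T^{\text{normalizer}}) -
\Delta C_T^{\text{reference}},$$

so one extra cycle halves expression. Constant offsets such as fixed
preamplification cycles cancel in the double difference, and any residual
constant factor cancels again in MoM normalization, so preamplification is
not modelled numerically. Measurements whose threshold cycle is missing or
reaches the instrument ceiling are flagged below detection; the default
ceiling `max_ct = 40` is the usual qPCR convention (the assay cutoff is
configurable).

## MoM normalization

Each marker is divided by its *expected median* in unaffected pregnancies
at the subject's own covariates (gestational age at sampling, maternal
weight), giving a dimensionless MoM. `fit_median_model()` regresses log10
levels on the two covariates in the reference group; if neither slope is
significant at `alpha = 0.05` (two-tailed), the model collapses to the
constant overall median. The regression is least squares on log10 values —
for log-normal levels this estimates the median, reproducing the
`10^(a + b·days + c·w)` form of the published regressed medians — rather
than quantile regression.

Numerical conventions, chosen so the defining invariant ("non-case median
MoM = 1.00") is exact for the constant form:

* sample medians use midpoint interpolation for even *n*;
* MoMs are computed per subject at their own covariates;
* the published median models ship as a YAML fixture
  (`published_median_models()`), so published MoMs can be reproduced
  without refitting: constant medians for PSME2 (0.85), NAMPT (2.34),
  APOA1 (0.16), APOA4 (2.44); a log-linear model for Hsa-Let-7g; and
  linear maternal-weight models for cervical length (cm) and mean arterial
  pressure (mmHg).

The printed Hsa-Let-7g model, `10^(−0.515 + 0.0106·days − 0.232·kg)`, is
dimensionally ambiguous in its weight term: at −0.232 *per kilogram* the
predicted median at 80 kg would be ~10⁻¹⁸, absurd for a fold-change scale.
The package therefore enters maternal weight as `log10(kg)` by default
(−0.232·log10(80) ≈ −0.44, giving medians of order 1–3), with
`weight_transform = "identity"` available. This is a documented
interpretation, not a reconstruction; it is the only reading under which
the printed constant produces usable medians. Whether the published CL/MAP
medians were fit on non-cases only is likewise unstated; the package fits
median models on whatever reference rows the caller supplies and uses the
published fixtures verbatim.

No truncation limits are applied to extreme MoMs (some screening programs
truncate; the source analysis does not mention doing so).

## Univariate screens

Case/non-case differences in log MoMs use the Wilcoxon rank-sum test
(midranks for ties; exact enumeration for tie-free samples with
`min(n) ≤ 8`, otherwise the normal approximation with continuity and tie
corrections). Cervical length and MAP are tested one-tailed in their known
directions (cases shorter CL, higher MAP); RNAs two-tailed. Maternal
characteristics are compared with the plain Pearson chi-square (no
continuity correction), and marker–CL interactions with Pearson
correlation (Spearman available). Markers reaching `p < 0.05` proceed to
risk modelling; **no multiple-testing correction is applied** across the
five-marker panel, matching the source analysis, and the run log records
this.

## Risk models

Risk models are main-effects logistic regressions over log10 MoMs and
clinical terms:

$$x = \beta_0 + \sum_j \beta_j z_j,\qquad y = e^x,\qquad
p = \frac{e^x}{1 + e^x},$$

with predictors drawn from a small vocabulary: marker log10 MoMs; the
indicator of race other than non-Hispanic Black; smoking; nulliparity and
parity-1–2 indicators (parity 3+ is the reference level, coefficient 0);
and the earliest gestation of a prior preterm birth in weeks, set to 40
when there was none — a single continuous summary of obstetric history.
The source text prints the risk transform as `p = y/(1 − y)`, which
exceeds 1 for any x > 0 and is negative for y > 1; the package implements
the standard logistic form `p = y/(1 + y)`, reading the printed minus sign
as a typo. Prior-PTB gestation is taken in weeks (the `·40` sentinel only
makes sense on that scale), and MAP enters fitted models as log10 MoM.

The four published best-fit equations ship as fixed fixtures
(`published_equation()`); scoring them is exact arithmetic with no
randomness. Fitting uses maximum likelihood via iteratively reweighted
least squares (`stats::glm`, convergence tolerance 1e−12, up to 100
iterations). Quasi-complete separation — e.g. a parity level with no
events, which is how a coefficient like −7.9772 for parity 1–2 arises —
is flagged when any standardized coefficient exceeds 15 (indicators are
already unit-scale; continuous predictors are scaled by their SD), and a
lightly ridge-penalized fit (λ = 1e−4, intercept unpenalized) is available
as a fallback. The penalty is never applied to the published equations.

When a predictor is unmeasured or below detection, scoring dispatches to a
sub-model fit on the remaining predictors: `fit_missingness_variants()`
fits one variant per missingness pattern observed in training, each on the
subjects for whom that pattern's predictors are available; patterns with
fewer than 5 cases fall back to the clinical-covariates-only set (logged).
`score_risk()` raises an error for a pattern without a variant;
`evaluate_model()` drops such subjects with a message, mirroring the
reduced "available n" of published MAP-model rows.

## Screening performance

AUC is computed as the Mann–Whitney probability that a random case
outscores a random control, ties counted half; it is invariant under any
strictly increasing transform of the scores, so the linear predictor `x`
and the probability `p` give identical AUCs. The 95% CI uses the DeLong
paired-placement variance estimator by default (the source study names no
method; Hanley–McNeil is available), truncated to (0, 1).

Detection rates at fixed FPRs use control-score percentiles: the threshold
for FPR *f* is the (1 − *f*) empirical percentile of the control scores,
with linear interpolation between order statistics (`quantile` type 7),
and a case is detected when its score is **strictly above** the threshold.
This keeps the observed control exceedance at or below the nominal FPR up
to the granularity 1/n<sub>controls</sub>. Whether the source analysis
interpolated or used nearest-rank percentiles is unstated; interpolation
was chosen because it keeps the observed FPR conservative and is the R
default.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of the source
289-subject single-center cohort so every downstream stage can be
exercised: nested outcome prevalences (25.3% PTB < 37 w containing the
10.4% ≤ 32 w subset; 7.6% preeclampsia containing 2.1% EOP), covariate
frequencies (85% non-Hispanic Black, 27.3% smokers, 17% nulliparous),
prior-preterm-birth history drawn conditionally on outcome (83%/79%/43%
for early-sPTB cases / all-PTB cases / others, with the earliest prior
gestation ≤ 32 weeks with probability 0.92/0.74/0.65 and uniform within
its band), parity drawn per outcome group from the printed parity
distributions of the preeclampsia contrast, log10-normal marker MoMs
centred on the printed group medians, raw values reconstructed through the
published median models, detection-limit censoring of the lowest 5% of
NAMPT and 2% of APOA1 values, and partial availability of cervical length
(≈53%) and MAP (95%). Drawing a prior preterm birth for a nulliparous
subject bumps parity to 1, keeping records coherent at the cost of a
slightly reduced nulliparous fraction.

Free parameters the source study does not report, fixed once at plausible
values and configurable in `cohort_spec()`:

* **log10 MoM spreads** — 0.35 for RNAs, 0.10 for CL, 0.03 for MAP. No
  marker variances are published, so these are assumptions, not
  reconstructions. They control every downstream effect size: at 0.35 the
  printed early-sPTB group-median separations make the two-RNA model
  separate synthetic cohorts almost completely (AUC ≈ 0.99), far above
  the published 0.76 — which is why the published headline AUCs (0.76,
  0.83, 0.89, 0.96) are treated as context, not as reproduction targets.
  Passing tests on synthetic cohorts demonstrate the machinery, not the
  clinical performance.
* **maternal weight** — Normal(80, 18) kg truncated to [40, 180];
  sampling gestation uniform over days 112–146 (16.0–20.9 weeks).
* one marker-median column is used per nesting stratum (the "all PTB"
  medians for 33–36-week births), a simplification of the nested printed
  columns.

The generator does not attempt longitudinal biweekly sampling, umbilical
cord samples, progesterone-treatment effects, correlations between markers
within subject, or covariate-dependent prevalences — all features a real
cohort would add.

## Problem sizes and runtime choices

The test suite exercises: generator calibration and covariate frequencies
at n = 5000 (medians within ±10%, frequencies within 3 SE); median-model
parameter recovery at n = 1000 (±10%); coefficient recovery from the
published early-sPTB equation at n = 3000–5000 (predictor coefficients
within ±15%; the intercept is excluded because identifying it requires
extrapolating the prior-PTB-gestation term to 0 weeks, far outside the
observed 16–40-week range, which inflates its relative SE beyond 15% at
these n for any realistic design); test size under the null at 2000
replicates (within 2 Monte-Carlo SE of 0.05); and AUC/threshold oracles by
exhaustive pair counting. The recovery simulations use a deliberately
wide, balanced predictor design (marker log10 MoMs ~ N(1.5, 1.5), balanced
race and history) so the information matrix is well conditioned.

## Known limitations

* The synthetic spreads are free parameters; nothing here validates the
  published AUCs or detection rates.
* The delta-delta CT form assumes the panel's bespoke normalization scheme
  reduces to a constant calibrator offset; amplification-efficiency
  correction and melt-curve QC are out of scope.
* Published equations carry no published missingness variants, so subjects
  missing NAMPT/APOA1 cannot be scored by them and are dropped from their
  evaluation (reported in the log), as in the published reduced-n rows.
* Fitted EOP models on cohort-sized data (≈6 cases) are fragile; the
  pipeline logs and skips fits with too few cases rather than reporting
  unstable coefficients.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(spec = cohort_spec(), seed = 42)
res <- run_full_analysis(cfg)
res$association$SPTB_LE32   # marker-table-shaped screen
res$performance             # AUC [CI] and DR at 10/20/30% FPR per model
cat(res$log, sep = "\n")    # seed, settings, variant and separation notes
```
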