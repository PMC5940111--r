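---
title: "Phenotypic age and methylation clocks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic age and methylation clocks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoclock)
```

## The model

`phenoclock` estimates biological age in two layers.

The clinical layer scores a panel of nine routine blood biomarkers plus
chronological age through a Gompertz proportional-hazards mortality model.
The hazard is $h(t) = e^{xb}\,e^{\gamma t}$ with a linear predictor
$xb = b_0 + \sum_k w_k x_k$ over the panel (C-reactive protein enters as its
natural logarithm), so the probability of death within a horizon of $t$
months is

$$M = 1 - \exp\!\left(-e^{xb}\,\frac{e^{\gamma t}-1}{\gamma}\right).$$

That risk is then expressed in **years** by inverting an age-only Gompertz
model fit on the same data: the *phenotypic age* of a subject is the
chronological age at which an average person carries the same 120-month
mortality risk,

$$a \;=\; \frac{\log\!\big(\gamma\,(-\log(1-M))\,/\,(e^{\gamma\,120}-1)\big) - b_0^{(\mathrm{age})}}{b^{(\mathrm{age})}_{\mathrm{age}}}.$$

The epigenetic layer is a sparse linear clock over CpG beta values,
$\widehat{a} = c_0 + \sum_j \beta_j w_j$, trained to predict phenotypic age.
*Age acceleration* is the residual of the clock score regressed on
chronological age — by construction it has exactly zero correlation with
age, so a positive value means "epigenetically older than expected".

## The two training steps

**Step 1** (`build_phenoage_model()`): deaths from causes not labelled
aging-related are treated as censored; an elastic-net penalized Cox model
(glmnet; Breslow ties, predictors standardized internally, coefficients
reported on the original scale) screens the candidate biomarkers, with
chronological age never penalized away. The penalty is chosen by 10-fold
cross-validation of the partial-likelihood deviance under the
one-standard-error rule — the largest penalty whose mean CV loss is within
one SD of the minimum — which favours the sparse panel this estimator is
meant to be. The selected variables are then refit by full maximum
likelihood in the parametric Gompertz model (BFGS with the analytic
gradient, $\gamma$ kept positive through a log parameterization, Newton
polish until the gradient max-norm falls below $10^{-8}$), and an age-only
Gompertz fit on the same data supplies the risk-to-years conversion.

The phrase "mean-squared error" is sometimes used loosely for the Cox CV
loss; here the Cox path is cross-validated on partial-likelihood deviance
and the quantitative step 2 on MSE, and the 1-SE rule applies to whichever
loss the path carries.

**Step 2** (`fit_elastic_net_clock()`): phenotypic age is regressed on beta
values (optionally restricted to a cross-platform CpG universe via
`restrict_to_universe()`) by squared-error elastic net, penalty chosen by
the CV-MSE minimum rule. Training-set mean betas are stored with the clock
so missing CpGs can later be imputed deterministically.

Tunable parameters, with defaults and rationale:

| parameter | default | why |
|---|---|---|
| elastic-net mixing $\alpha$ | 0.5 | unreported upstream; an even L1/L2 compromise, exposed everywhere |
| CV folds / step-1 rule / step-2 rule | 10 / `"1se"` / `"min"` | sparsity is the point of step 1; accuracy the point of step 2 |
| $\lambda$ grid | 100 points, $\lambda_{\max}$ down to $10^{-4}\lambda_{\max}$ | glmnet's convention, fixed for reproducibility |
| risk horizon | 120 months | the scale on which the phenotypic age is defined |
| ties | Breslow | consistency between the penalized and unpenalized fits; Efron behind a flag |
| missing-CpG policy | error; opt-in training-mean imputation capped at 5% | deterministic, auditable scores |

Fold assignment is a seeded permutation stratified by event status, so the
whole pipeline is reproducible from one integer seed.

## The packaged published coefficients

`phenoage_model_published()` loads a transcription of the published
clinical model (the ten Table-style weights, intercept $-19.9067$,
$\gamma = 0.0076927$ per month, and the age-only conversion constants
stored as the triplet of the mapping
$a = 141.50225 + \log(-0.00553 \log(1-M))/0.090165$, from which
$(b_0, b_{\mathrm{age}})$ are derived exactly). Every operation also
accepts a model re-derived by `build_phenoage_model()` on synthetic data,
and no test outcome depends on the transcription.

## What the synthetic generator emulates — and what it does not

`generate_clinical_cohort()` emulates a nationally representative survey
population: ages uniform on 30–90, each named biomarker normal around a
population-representative mean with a fixed linear age trend and
population-scale dispersion (e.g. glucose SD 2.0 mmol/L, covering
diabetics; creatinine SD 25 µmol/L, covering renal impairment; CRP
lognormal). Follow-up defaults to 276 months, matching the two-decade
mortality follow-up of the kind of survey the step-1 training emulates,
with administrative censoring; event times are drawn by exact inverse-CDF
of the Gompertz survival function,
$T = \gamma^{-1}\log\!\big(1 + \gamma(-\log U)e^{-xb}\big)$. Events are
labelled aging-related with probability 0.63, the approximate share of
aging-related deaths among all deaths in the populations these scores are
validated on, collapsing the full cause list to a two-level factor. The
default intercept is calibrated so a 60-year-old with mean biomarkers has a
10% 120-month risk (a plausible mid-life mortality level given the
$\gamma = 0.0077$/month slope, a doubling time of roughly 7.5 years).

The generator makes **no claim** of matching real survey marginals or the
joint distribution of the 42 candidate markers: biomarkers are independent
given age, there is no survey weighting, no measurement batch structure,
and the methylome has no probe-correlation (LD-like) structure — signal
CpGs are conditionally independent given phenotypic age, with betas
`clip(b0 + slope * z + noise, 0, 1)` and slopes of 0.03–0.08 beta units per
SD. Passing the recovery tests therefore shows the estimators are correct
and well calibrated under a faithful Gompertz data-generating process; it
does not show robustness to the correlation structure, assay artefacts or
informative censoring of real cohorts.

## Numerical choices and degenerate inputs

- `expm1`/`log1p` forms are used throughout the Gompertz algebra, so risks
  and sampled times are accurate for small $\gamma t$ and risks near 0.
- The risk-to-years conversion requires $M$ strictly inside $(0,1)$ and
  errors otherwise (a risk of exactly 0 or 1 has no finite age).
- CRP must be strictly positive (its log enters the score); any `NA` or
  non-finite biomarker is an error, while finite out-of-range values score
  with a warning — population data are messy, and silent imputation is
  worse than a loud score.
- Betas outside $[0,1]$ by at most $10^{-6}$ are clamped; larger
  violations are errors, not data.
- A constant clock response returns the intercept-only clock rather than
  failing inside the penalized solver.
- The horizon ROC excludes subjects censored before the horizon (simple
  and stated, rather than inverse-probability-of-censoring weighting,
  which is out of scope); cases are observed events by the horizon,
  controls subjects still under follow-up beyond it.
- Biweight midcorrelation uses the unscaled MAD with the conventional
  factor 9; zero-MAD vectors fall back to Pearson with a warning.
- Stouffer combination converts two-sided p-values to signed z-scores via
  the reported effect direction, with $\sqrt{n}$ weights when sample sizes
  are given.

## Problem sizes used in the checks

The packaged checks run at sizes chosen to make Monte-Carlo noise small
relative to the assertions while staying desk-scale: step-1 recovery on a
10,000-subject cohort (about 4,800 events), step-2 recovery on 500
training / 500 test samples over 2,000 CpGs with 50 signal CpGs,
calibration of the test statistics over 500 null replicates, and
meta-analysis of five 2,000-subject studies with a true per-year hazard
ratio of 1.045.

## Known limitations

- Cause-specific hazards are modelled by censoring competing events;
  subdistribution (Fine–Gray) hazards are not implemented.
- The generator's biomarker independence means step-1 selection is easier
  than in collinear real panels; selection frequencies reported on
  synthetic data are optimistic in that specific sense.
- The elastic-net mixing and the exact published penalty are not
  recoverable from public information; the published 513-CpG weights are
  therefore applied, never re-derived.
- Scores for arrays missing many clock CpGs depend on the training-mean
  imputation cap; the 5% default is this package's choice.
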