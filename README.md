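# phenoclock

Biological-age estimation from clinical chemistry and DNA methylation, for
researchers building or validating aging biomarkers.

Chronological age is the strongest single risk factor for death, but people
of the same age differ widely in risk. `phenoclock` implements the
two-layer approach to quantifying that difference:

1. **Phenotypic Age** — nine routine blood biomarkers (albumin, creatinine,
   glucose, log CRP, lymphocyte %, mean cell volume, red cell distribution
   width, alkaline phosphatase, white cell count) plus chronological age
   are combined through a Gompertz proportional-hazards mortality model,
   hazard `h(t) = exp(xb) exp(γt)`. The 120-month mortality risk

   `M = 1 − exp(−exp(xb) (exp(120γ) − 1)/γ)`

   is converted into **years** by inverting an age-only Gompertz model:
   phenotypic age is the age at which an average person carries the same
   risk.

2. **DNAm phenotypic age** — a sparse linear clock over CpG beta values,
   `score = intercept + Σ βⱼ wⱼ`, trained by elastic net to predict
   phenotypic age. Its residual on chronological age ("age acceleration",
   exactly uncorrelated with age by construction) separates fast from slow
   agers among people born the same year.

The package covers the full cycle: a seeded synthetic cohort generator
(age-trending biomarkers, exact inverse-CDF Gompertz event times, planted
CpG clock signal), the two-step training pipeline (penalized Cox selection
→ parametric Gompertz refit → elastic-net clock), clock application and
coefficient-file I/O, and the validation battery: age-adjusted Cox hazard
ratios (Breslow ties), cause-specific hazards, fixed-effect and Stouffer
meta-analysis, Kaplan–Meier curves, predicted survival with median life
expectancy, time-horizon ROC, biweight midcorrelation and hypergeometric
set-overlap enrichment.

## Worked example

```r
library(phenoclock)

# clinical phenotypic age of one subject, using the packaged published model
panel <- data.frame(albumin = 42, creatinine = 75, glucose = 5.2, crp = 0.15,
                    lymphocyte_pct = 31, mcv = 89, rdw = 12.8, alp = 65,
                    wbc = 6.1, age = 55)
phenotypic_age(panel, phenoage_model_published())
#>          xb mortality_score phenoage
#> 1 -8.642505      0.03419957  46.6122
```

This 55-year-old has the 10-year mortality risk (3.4%) of an average
46.6-year-old — biologically about eight years younger than the calendar
says.

```r
# synthetic cohort -> methylation study -> train and validate a clock
cohort <- generate_clinical_cohort(cohort_spec(n_subjects = 2000, seed = 1))
pa     <- phenotypic_age(cohort, phenoage_model_published())$phenoage
meth   <- generate_methylation_study(cohort, pa, methylome_spec(seed = 1))

train <- 1:1000; test <- 1001:2000
clock <- fit_elastic_net_clock(meth$betas[train, ], pa[train], seed = 1)
clock
#> Trained clock: 1000 samples, 50 nonzero CpGs, lambda = 0.2219

scores <- apply_clock(meth$betas[test, ], clock$clock)
cor(scores$dnam_phenoage, pa[test])        # 0.999 out of sample

accel <- age_acceleration(scores$dnam_phenoage, cohort$age[test])
cox_hr_per_year(accel, cohort$age[test], cohort$time[test], cohort$event[test])
#> HR = 1.0925 per unit (log HR 0.0885, se 0.0067, p = 1.66e-39; n = 1000, events = 467)

hazard_contrast(1.0925, 11, 0)             # 2.65: an 11-year-faster ager vs average
```

Each year of age acceleration multiplies the mortality hazard by 1.09 in
this simulation, independent of chronological age; a subject 11 years
"older" than predicted faces 2.65 times the average hazard.

The step-1 pipeline is `build_phenoage_model(cohort)`: penalized Cox
selection of the informative biomarkers (age always kept, one-SE rule),
Gompertz maximum-likelihood refit, and the age-only conversion model — see
the methods vignette (`vignettes/phenoclock-methods.Rmd`) for the model,
defaults and design choices. A thin command-line wrapper lives at
`inst/cli/phenoclock.R` (`simulate`, `phenoage`, `train-step1`,
`train-step2`, `dnamage`, `validate`).

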