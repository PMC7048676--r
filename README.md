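# nodulerisk

Clinical calculators for the probability that a pulmonary nodule found on CT
is malignant, and the statistical toolkit for externally validating them on a
local population.

Most incidentally detected lung nodules are benign, but early-stage lung
cancer is highly curable, so clinicians lean on published risk models to
decide between surveillance and invasive work-up. Four such models are widely
used — **Mayo Clinic**, **Department of Veterans Affairs (VA)**, **Peking
University People's Hospital (PKUPH)** and **Brock University** — yet each
was derived in a different population, and their discrimination can degrade
badly when transported elsewhere. This package is for biostatisticians and
clinical researchers who need to (a) score patients with these calculators
exactly as published and (b) measure, on their own cohort, which model
discriminates and calibrates best.

## The models

Each model is a logistic calculator: a linear predictor

```
x = constant + Σ βᵢ · covariateᵢ,      p = eˣ / (1 + eˣ)
```

over demographic covariates (age, sex, smoking, cancer history) and CT
features (diameter, upper-lobe location, spiculation, border, calcification).
Binary covariates are coded 0/1 (1 = presence; sex coded female = 1). The
Brock model enters diameter through the decreasing power transform
`(d/10)^-0.5 − 1.5811`, which combined with its negative coefficient still
makes risk increase with size. `nodule_models()` holds the coefficients
exactly as tabulated in the validation study the package follows, including
two values that differ from earlier printings (VA quit-years +0.0567, Mayo
constant −6.872); see `?nodule_models`.

Validation metrics:

* **Discrimination** — AUC as the pairwise case–control concordance
  probability (ties = ½), with Hanley–McNeil 95% confidence intervals, on
  four diagnostic strata: benign vs malignant, early (I/II) vs late (III/IV)
  stage, squamous vs benign, adenocarcinoma vs benign.
* **Calibration** — decile calibration curves (observed event fraction vs
  mean predicted probability in quantile bins).
* **Univariate screening** — one-way ANOVA per characteristic across outcome
  groups, with a Levene gate falling back to Welch's t-test.
* **Multivariate refits** — logistic regression (IRLS) with Wald statistics,
  odds ratios and separation flagging, including the head-to-head regression
  of the outcome on all four models' predictions at once.

Because real validation cohorts are rarely shareable, the package includes a
seeded synthetic cohort generator (`simulate_cohort()`) that emulates a
496-patient surgical series — 425 malignant / 71 benign, ages 29–89, diameter
strata 1.9–8 / 8–30 / 30–124 mm — with the malignant outcome planted from a
chosen truth model, so the entire pipeline is testable end to end
(`plant_and_recover()`).

## Worked example

Score one patient — a 65-year-old male ever-smoker, 14 mm spiculated
upper-lobe nodule — with all four calculators:

```r
library(nodulerisk)

patient <- tibble::tibble(
  id = "nodule-1", age = 65, sex_female = 0, ever_smoker = 1,
  quit_years = 5, cancer_history = 0, family_history_cancer = 0,
  lung_cancer_history = 0, diameter_mm = 14, upper_lobe = 1,
  spiculation = 1, smooth_border = 0, clear_border = 1, calcification = 0,
  lobulation = 0, ground_glass = 0, air_bronchogram = 0
)
score_cohort(patient)
#> # A tibble: 4 × 6
#>   id       model linear_predictor probability applicable warnings
#>   <chr>    <chr>            <dbl>       <dbl> <lgl>      <list>
#> 1 nodule-1 mayo            0.0693       0.517 TRUE       <chr [0]>
#> 2 nodule-1 va              0.572        0.639 TRUE       <chr [0]>
#> 3 nodule-1 pkuph           1.74         0.850 TRUE       <chr [0]>
#> 4 nodule-1 brock          -0.987        0.271 TRUE       <chr [0]>
```

The four models disagree substantially (27%–85% malignancy risk for the same
nodule) — precisely why local validation matters. `probability` is the
logistic of `linear_predictor`; `warnings` collects applicability notes (e.g.
a 5 mm nodule is below the VA model's 7–30 mm range) without blocking
scoring.

Validate all four models on a synthetic cohort whose outcome is planted from
the PKUPH linear predictor:

```r
cohort <- simulate_cohort(cohort_params(seed = 7))
preds  <- score_cohort(cohort)
evaluate_models_on_stratum(preds, cohort, "benign_vs_malignant")
#> # A tibble: 4 × 10
#>   stratum             model   auc     se ci_lower ci_upper n_pos n_neg auc_rank
#>   <chr>               <chr> <dbl>  <dbl>    <dbl>    <dbl> <int> <int>    <int>
#> 1 benign_vs_malignant brock 0.694 0.0300    0.635    0.752   424    72        4
#> 2 benign_vs_malignant mayo  0.758 0.0262    0.706    0.809   424    72        3
#> 3 benign_vs_malignant pkuph 0.896 0.0151    0.866    0.925   424    72        1
#> 4 benign_vs_malignant va    0.789 0.0241    0.742    0.836   424    72        2
```

The planted truth (PKUPH) ranks first, the models sharing covariates with it
(Mayo, VA) trail, and Brock — sharing only diameter, spiculation and lobe —
comes last. `run_pipeline(pipeline_config(...))` chains
simulate/read → score → evaluate → report and writes CSV/JSON reports plus a
reproducible run manifest; a command-line wrapper with `simulate`, `score`,
`evaluate` and `run` verbs ships in `inst/cli/nodulerisk`.

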