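---
title: "Validating pulmonary-nodule malignancy models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating pulmonary-nodule malignancy models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulerisk)
```

## The problem

A pulmonary nodule is a focal lung lesion of up to about 30 mm on CT (larger
lesions are masses, and usually malignant). Several published logistic
calculators estimate the probability that such a nodule is cancer from
demographic and CT-report features. Their coefficients were estimated in
very different source populations — a US tertiary-referral series (Mayo), a
US veterans series that is almost entirely male smokers (VA), a Chinese
surgical series (PKUPH) and a Canadian low-prevalence screening series
(Brock) — so none of them can be assumed to transport. This package
implements the four calculators exactly as published and the statistical
pipeline used to compare them on a local cohort: batch scoring, ROC/AUC on
diagnostic strata, calibration curves, univariate screening, and
multivariate logistic refits.

## The models and their encoding

Every model is a generalized linear model with logistic link: a linear
predictor $x = \beta_0 + \sum_i \beta_i z_i$ mapped to a probability
$p = e^x/(1+e^x)$. The covariates $z_i$ are binary indicators (0/1,
1 = presence; sex coded female = 1), age in years, diameter in mm, and for
the VA model years since quitting smoking (0 for never- and current
smokers, so the term vanishes additively for them). The Brock model uses the
transformed diameter $(d/10)^{-0.5} - 1.5811$; the transform is decreasing
in $d$ and its coefficient is negative, so malignancy probability still
rises with diameter — a property the test suite checks for all four models.

Two registry values differ from earlier printings of the same models (the
VA quit-years coefficient is positive here, and the Mayo constant is
−6.872). The package deliberately encodes the tabulated values of the
validation study it follows, treating that table as the specification of
record; re-deriving the original publications' coefficients is out of scope.

Applicability is advisory, not blocking. Each model carries its published
diameter range (Mayo 4–30 mm, VA 7–30 mm, PKUPH 9–28 mm, Brock 1–86 mm) and,
for Mayo and PKUPH, the exclusion of patients with a prior malignancy within
five years. Violations produce warnings on the prediction row, but scoring
proceeds: validation practice scores every nodule with every model, and the
warnings let the analyst stratify afterwards. Missing covariates, by
contrast, are an error — the reference behaviour for incomplete records is
exclusion at intake (`read_cohort()` tallies per-field exclusion counts),
never silent imputation.

## Discrimination: AUC as pairwise concordance

`compute_auc()` computes the AUC as the probability that a random case
outscores a random control, counting ties one half — the Mann–Whitney
statistic over $n_+ n_-$ pairs. The implementation uses midranks, but the
result object also carries the explicit concordant/tied pair counts, and the
test suite verifies exact equality against an independent brute-force double
loop over all pairs on hundreds of random instances (including heavily tied
ones), as well as against a third-party ROC implementation.

The 95% interval uses the Hanley–McNeil variance

$$\mathrm{var}(A) = \frac{A(1-A) + (n_+-1)(Q_1-A^2) + (n_--1)(Q_2-A^2)}{n_+ n_-},
\quad Q_1 = \frac{A}{2-A},\; Q_2 = \frac{2A^2}{1+A},$$

with normal quantiles, clamped to $[0,1]$. The method is cheap, standard in
clinical software, and adequate for the cohort sizes involved; a bootstrap
percentile interval is available via `ci_method = "bootstrap"` for skeptics
of the normal approximation. No formal AUC-difference test (DeLong) is part
of the headline pipeline: models are compared by AUC magnitude and rank,
which is how such validations are conventionally reported; the Hanley–McNeil
intervals convey the uncertainty.

Four built-in strata define the comparisons: all patients (benign vs
malignant), stage III/IV vs I/II among cancers, and squamous or
adenocarcinoma cases against controls. For the two histology strata the
control group is genuinely ambiguous — benign nodules only, or every
non-target patient. The default is benign controls, which asks the
clinically sharper question ("does the model separate this cancer type from
benign disease?"); `stratum()` lets the user encode the alternative
predicate in one line, and stratum predicates are checked for disjointness
and non-emptiness before any scoring.

## Calibration

`calibration_curve()` uses equal-count (quantile) bins, 10 by default.
Equal-width bins would leave most bins empty on a cohort with 86% prevalence
where predictions pile up; quantile bins keep every bin populated. When
predictions are heavily tied the quantile boundaries collapse and bins are
merged, so the effective bin count can be below the request — reported
honestly in `n_bins` rather than padded. Note that discrimination and
calibration dissociate by design in the synthetic cohorts: the planted
outcome mechanism shifts the truth model's intercept to hit the target
prevalence, so the *unshifted* published probabilities can discriminate well
while sitting far from the identity line. That mirrors the real phenomenon
of a transported model that ranks patients correctly but misstates absolute
risk until recalibrated.

## Univariate screening and logistic refits

`univariate_screen()` reports, per characteristic, the overall mean with SD,
SE and normal-theory 95% CI (for a binary characteristic this is its
prevalence and CI — the table's single-column shape is ambiguous about which
quantity the CI covers, and the mean is the only choice that is well-defined
for both binary and continuous characteristics), plus a one-way ANOVA F
across outcome groups. The variance-homogeneity precondition is gated by
Levene's test at $\alpha = 0.05$ (median-centred); on failure the two-group
contrast falls back to Welch's t-test, the standard unequal-variance
replacement. For two groups with equal variances, ANOVA F equals the squared
pooled t statistic — property-tested. No multiplicity correction is applied:
raw p-values at the 0.05 level, matching conventional reporting of such
screens.

`fit_logistic()` is a reporting layer over the binomial GLM fitted by
iteratively reweighted least squares (convergence tolerance $10^{-8}$, at
most 50 iterations): per term B, SE, Wald $\chi^2 = (B/SE)^2$ with 1 df,
p, OR $= e^B$ and 95% CI $e^{B \pm 1.96\,SE}$. Complete or quasi-separation
manifests as runaway estimates with enormous standard errors; rather than
printing those as if they were science, terms with $|B| > 15$ or $SE > 100$
(or aliased/collinear terms) are flagged and their Wald/p/OR withheld. The
thresholds are far beyond any plausible log-odds ratio on these covariate
scales and far below the $10^3$–$10^4$ magnitudes separation produces, so
the gap between the two regimes makes the cut insensitive to the exact
values. `combined_model_regression()` applies the same machinery to the
four models' predicted probabilities jointly — the head-to-head test of
which model carries independent information.

## The synthetic cohort generator

Real validation cohorts of this kind are not publicly deposited, so the
generator exists to make the pipeline testable end to end at the study's
scale. Its defaults emulate the structure of a 496-patient surgical series:

| parameter | default | basis |
|---|---|---|
| `n` | 496 | cohort size |
| `prevalence` | 425/496 ≈ 0.857 | malignant fraction of a surgical series |
| `age_range` | 29–89 y | reported range; uniform within |
| diameter strata | 1.9–8, 8–30, 30–124 mm with weights 126/219/151 ÷ 496 | reported bin counts; uniform within each stratum |
| `feature_prevalences` | e.g. upper lobe 0.575, ever-smoker 0.405, spiculation 0.205, calcification 0.47, family history 0.095, ground-glass 0.165, air bronchogram 0.05 | midpoints of reported interval estimates |
| `histology_mix` | adeno 150/425, squamous 56/425, other the remainder | reported histology counts |
| `stage_mix` | I 0.21, II 0.18, III 0.30, IV 0.31 | early/late split consistent with the reported regional stage distribution (61% III/IV, 21% I); II and the III/IV split are package choices |
| `quit_years` | uniform 0–20 y among ever-smokers | no distribution reported; a plausible clinical range |

Ages and within-stratum diameters are uniform because only ranges and bin
counts are reported — uniformity is the least-assumption choice and every
piece of it is a parameter. Binary features are drawn independently; no
covariance structure is reported, and none is invented. Features whose
prevalence is only vaguely reported (sex, border and lobulation fields,
cancer histories) use round mid-range values declared in
`cohort_params()`.

The outcome is planted: a truth model's linear predictor on the realised
covariates, intercept-shifted so the expected prevalence hits the target
(solved by root finding on $\bar{p}(s) = $ target, to $10^{-10}$), then a
Bernoulli draw per patient. The shift — rather than rejection sampling —
keeps the planted covariate effects exactly intact, which is what makes
coefficient-recovery checks meaningful. Histology and stage are assigned to
cases by the configured mixes, independently of covariates; consequently
the early-vs-late and histology strata carry no planted signal, and AUCs
there hover around 0.5 — the pipeline is being exercised, not the biology.

What passing tests on this generator do **not** show: that any of the four
models discriminates well on real patients from any particular region. The
generator has independent features, uniform shapes and a logistic truth by
construction; real cohorts have correlated CT features (spiculation with
diameter, calcification with benignity), non-uniform age and size
distributions, and an outcome mechanism no one hands you. The published
validation AUCs in the 0.6–0.7 range on real data are therefore not
reproducible here and are deliberately not targets of any test; what the
tests show is that the machinery is exact (AUC, logistic fits), calibrated
in the statistical sense (CI coverage), and able to recover a known planted
truth (`plant_and_recover()`: the truth model tops the AUC ranking in a
majority of seeded replicates, and refitted coefficients cover the planted
values at the nominal rate).

## Numerical and reproducibility choices

* Single global seed per cohort; replicate seeds in `plant_and_recover()`
  are fixed increments (`seed + 1, + 2, ...`), so one integer reproduces a
  whole report. Seeded draws are wrapped so the caller's RNG stream is left
  undisturbed.
* Worked-example tolerances: published worked arithmetic rounds the Brock
  example's linear predictor to −3.3869 where exact evaluation gives
  −3.38714; comparisons against published printed values use absolute
  tolerances 5×10⁻⁴ on $x$ and 5×10⁻⁵ on $p$.
* Degenerate inputs fail loudly and early: single-class labels (AUC
  undefined), empty cohort files, unknown columns or strata, overlapping
  stratum predicates, calibration bins exceeding $n$. Batch scoring is the
  one deliberate exception: per-row failures are collected into a `failures`
  attribute so one bad record cannot abort a cohort run.
* Ties: AUC counts tied pairs at ½ (midranks); ROC curves emit one point
  per distinct threshold; tied quantile boundaries merge calibration bins.
* Test problem sizes are chosen to make the checks sharp but quick: 1000
  random oracle instances at $n \le 200$; 20 replicates of $n = 496$ for
  planted-truth ranking; 200 replicates of $n = 5000$ for coverage;
  $n = 10^4$ for calibration; $n = 5 \times 10^4$ for generator convergence.

## Known limitations

* Coefficients are encoded as printed in the followed validation table;
  where that table disagrees with the models' original publications, the
  table wins by design, and the two known discrepancies are documented in
  `?nodule_models`.
* The Brock model's published exclusions that are not expressible from the
  cohort's fields (low-risk screening context, hilar/mediastinal
  lymphadenopathy) are documented but not checked.
* Hanley–McNeil intervals rely on a normal approximation that degrades for
  AUC near 1 or tiny group sizes; use the bootstrap option there.
* The separation heuristic flags by magnitude; it does not implement Firth
  penalisation or exact logistic regression, which would be the remedies if
  flagged terms were scientifically central.
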