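test_that("the same seed reproduces a byte-identical cohort", {
  params <- cohort_params(n = 2, prevalence = 0.5)
  a <- simulate_cohort(params, seed = 123)
  b <- simulate_cohort(params, seed = 123)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort(simulate_cohort(cohort_params(seed = 7)), f1)
  write_cohort(simulate_cohort(cohort_params(seed = 7)), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(a, simulate_cohort(params, seed = 124)))
})

test_that("the default cohort reproduces the study structure", {
  cohort <- simulate_cohort(cohort_params(seed = 7))
  expect_equal(nrow(cohort), 496L)
  expect_named(cohort, cohort_columns())

  malignant <- sum(cohort$outcome_malignant)
  bounds <- binom_bounds99(496, 425 / 496)
  expect_gte(malignant, bounds[1])
  expect_lte(malignant, bounds[2])

  bins <- table(cut(cohort$diameter_mm, c(1.9, 8, 30, 124),
                    include.lowest = TRUE))
  for (k in 1:3) {
    b <- binom_bounds99(496, c(126, 219, 151)[k] / 496)
    expect_gte(bins[[k]], b[1])
    expect_lte(bins[[k]], b[2])
  }

  expect_true(all(cohort$age >= 29 & cohort$age <= 89))
  expect_true(all(cohort$diameter_mm >= 1.9 & cohort$diameter_mm <= 124))
  expect_true(all(cohort$quit_years[cohort$ever_smoker == 0] == 0))
  expect_true(all((cohort$histology == "benign") ==
                    (cohort$outcome_malignant == 0)))
  expect_true(all(is.na(cohort$stage[cohort$outcome_malignant == 0])))
  expect_false(anyNA(cohort$stage[cohort$outcome_malignant == 1]))
})

test_that("empirical feature prevalences converge to the parameters", {
  params <- cohort_params(n = 50000, prevalence = 0.857)
  cohort <- simulate_cohort(params, seed = 19)
  # 4 SE per feature keeps the family-wise false-alarm rate negligible
  # across the 13 simultaneously checked features
  for (f in names(params$feature_prevalences)) {
    p <- params$feature_prevalences[[f]]
    se <- sqrt(p * (1 - p) / 50000)
    expect_lt(abs(mean(cohort[[f]]) - p), 4 * se + 1e-12)
  }
})

test_that("a planted positive diameter effect makes cases larger", {
  cohort <- simulate_cohort(cohort_params(seed = 3)) # pkuph truth
  expect_gt(mean(cohort$diameter_mm[cohort$outcome_malignant == 1]),
            mean(cohort$diameter_mm[cohort$outcome_malignant == 0]))
})

test_that("impossible parameter combinations are rejected", {
  expect_error(cohort_params(n = 1))
  expect_error(cohort_params(prevalence = 1), "prevalence")
  expect_error(cohort_params(n = 10, prevalence = 0.01), "prevalence")
  expect_error(cohort_params(histology_mix = c(adenocarcinoma = 0.5,
                                               benign = 0.5)), "benign")
  expect_error(cohort_params(stage_mix = c(I = 0.9, II = 0.9)), "sum")
})

test_that("the prevalence shift hits the target mean probability", {
  set.seed(8)
  x <- rnorm(1000, sd = 2)
  s <- nodulerisk:::prevalence_shift(x, 0.857)
  expect_equal(mean(plogis(x + s)), 0.857, tolerance = 1e-8)
})

test_that("planting a truth model makes it win the AUC comparison", {
  report <- plant_and_recover(cohort_params(seed = 500), n_reps = 5)
  expect_equal(report$top_counts$model[1], "pkuph")
  expect_gte(report$top_counts$n_top[1], 3)
  expect_true(all(report$coverage$term %in%
                    names(nodule_models("pkuph")[[1]]$coefficients)))
})

test_that("a zero-signal truth leaves every model near chance", {
  params <- cohort_params(truth_model = null_truth_model(), seed = 60)
  cohort <- simulate_cohort(params)
  preds <- score_cohort(cohort)
  ev <- evaluate_models_on_stratum(preds, cohort, "benign_vs_malignant")
  for (i in seq_len(nrow(ev))) {
    expect_lt(abs(ev$auc[i] - 0.5), 3 * ev$se[i])
  }
})
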