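test_that("Brock diameter transform matches its published form", {
  expect_equal(brock_diameter_transform(10), 1 - 1.5811)
  expect_equal(brock_diameter_transform(20), 2^(-0.5) - 1.5811,
               tolerance = 1e-10)
  # root of the transform: (d/10)^-0.5 = 1.5811 at d = 10 / 1.5811^2
  expect_equal(brock_diameter_transform(10 / 1.5811^2), 0, tolerance = 1e-12)
  expect_error(brock_diameter_transform(0))
  expect_error(brock_diameter_transform(-3))
})

test_that("linear predictor reproduces hand-computed examples", {
  # Brock worked example: man, lower lobe, no spiculation, 10 mm
  ex <- make_patient(diameter_mm = 10)
  x <- linear_predictor(ex, "brock")
  expect_equal(x, -(1 - 1.5811) * 5.5537 - 6.6144, tolerance = 1e-12)
  expect_equal(x, -3.3869, tolerance = 5e-4)

  # constant-only case: every covariate zero, identity diameter term zero
  # (diameter itself cannot be zero, so use a custom model)
  m0 <- nodule_model("toy", coefficients = c(age = 2, spiculation = -1),
                     constant = -1.25)
  expect_equal(linear_predictor(make_patient(), m0), -1.25)

  # PKUPH hand summation: age 60, 20 mm, family history, spiculation
  pk <- make_patient(age = 60, diameter_mm = 20, family_history_cancer = 1,
                     spiculation = 1)
  expect_equal(linear_predictor(pk, "pkuph"),
               -4.496 + 4.2 + 1.352 + 1.267 + 0.736, tolerance = 1e-9)
})

test_that("predicted probability applies the logistic link", {
  ex <- make_patient(diameter_mm = 10)
  pred <- predict_probability(ex, "brock")
  expect_equal(pred$probability, 0.0327, tolerance = 5e-5)
  expect_equal(pred$probability, plogis(pred$linear_predictor))
  expect_true(pred$applicable)

  pk <- make_patient(age = 60, diameter_mm = 20, family_history_cancer = 1,
                     spiculation = 1)
  expect_equal(predict_probability(pk, "pkuph")$probability,
               plogis(3.059), tolerance = 1e-6)
  expect_equal(plogis(3.059), 0.9552, tolerance = 5e-5)

  # x = 0 is the logistic midpoint
  m <- nodule_model("toy", coefficients = c(age = 0), constant = 0)
  expect_equal(predict_probability(make_patient(), m)$probability, 0.5)
})

test_that("missing covariates are an error naming field and model", {
  p <- make_patient()
  p$ever_smoker <- NA
  expect_error(linear_predictor(p, "mayo"), "ever_smoker")
  expect_error(linear_predictor(p, "mayo"), "mayo")
  expect_error(linear_predictor(dplyr::select(p, -diameter_mm), "va"),
               "diameter_mm")
})

test_that("applicability warnings follow the published ranges and exclusions", {
  expect_match(
    check_applicability(make_patient(diameter_mm = 5), "va")[[1]],
    "below VA applicability range \\(7-30 mm\\)"
  )
  expect_length(
    check_applicability(make_patient(diameter_mm = 15), "mayo")[[1]], 0
  )
  expect_length(
    check_applicability(make_patient(diameter_mm = 86), "brock")[[1]], 0
  )
  expect_match(
    check_applicability(make_patient(diameter_mm = 90), "brock")[[1]],
    "above BROCK applicability range"
  )
  # prior-malignancy exclusions are advisory for Mayo and PKUPH
  prior <- make_patient(diameter_mm = 15, cancer_history = 1)
  expect_match(check_applicability(prior, "mayo")[[1]], "prior")
  expect_match(check_applicability(prior, "pkuph")[[1]], "prior")
  expect_length(check_applicability(prior, "brock")[[1]], 0)
  # scoring still proceeds with a warning
  pred <- predict_probability(make_patient(diameter_mm = 5), "va")
  expect_false(pred$applicable)
  expect_true(is.finite(pred$probability))
})

test_that("score_cohort yields one row per patient x model, in order", {
  one <- make_patient(id = "solo", diameter_mm = 12, age = 60)
  out <- score_cohort(one)
  expect_equal(nrow(out), 4L)
  expect_setequal(out$model, c("mayo", "va", "pkuph", "brock"))

  brock_only <- score_cohort(make_patient(diameter_mm = 10), "brock")
  expect_equal(nrow(brock_only), 1L)
  expect_equal(brock_only$probability, 0.0327, tolerance = 5e-5)

  cohort <- simulate_cohort(cohort_params(n = 100, prevalence = 0.8,
                                          seed = 42))
  preds <- score_cohort(cohort)
  expect_equal(nrow(preds), 400L)
  expect_true(all(preds$probability > 0 & preds$probability < 1))
  # row order preserved within each model
  expect_equal(preds$id[preds$model == "va"], cohort$id)
})

test_that("score_cohort collects per-patient failures without aborting", {
  cohort <- simulate_cohort(cohort_params(n = 10, prevalence = 0.5, seed = 5))
  cohort$age[3] <- NA
  out <- score_cohort(cohort)
  fails <- attr(out, "failures")
  # age feeds mayo, va, pkuph but not brock
  expect_equal(sort(fails$model), sort(c("mayo", "va", "pkuph")))
  expect_true(all(grepl("age", fails$reason)))
  expect_equal(sum(is.na(out$probability)), 3L)
  expect_false(anyNA(out$probability[out$model == "brock"]))
})

test_that("probability is strictly monotone in each covariate's direction", {
  set.seed(101)
  for (i in 1:25) {
    base <- make_patient(
      age = sample(30:85, 1),
      sex_female = rbinom(1, 1, 0.5), ever_smoker = rbinom(1, 1, 0.5),
      quit_years = runif(1, 0, 15), cancer_history = rbinom(1, 1, 0.2),
      family_history_cancer = rbinom(1, 1, 0.2),
      diameter_mm = runif(1, 2, 100), upper_lobe = rbinom(1, 1, 0.5),
      spiculation = rbinom(1, 1, 0.3), smooth_border = rbinom(1, 1, 0.3),
      calcification = rbinom(1, 1, 0.4)
    )
    bigger <- dplyr::mutate(base, diameter_mm = diameter_mm + runif(1, 0.5, 10))
    for (m in names(nodule_models())) {
      expect_gt(predict_probability(bigger, m)$probability,
                predict_probability(base, m)$probability)
    }
    # turning on every positive-coefficient binary never lowers probability
    for (m in nodule_models()) {
      pos_bins <- names(m$coefficients)[m$coefficients > 0 &
                                          !names(m$coefficients) %in%
                                          c("age", "diameter", "quit_years")]
      raised <- base
      for (f in pos_bins) raised[[f]] <- 1
      lowered <- base
      for (f in pos_bins) lowered[[f]] <- 0
      expect_gte(predict_probability(raised, m)$probability,
                 predict_probability(lowered, m)$probability)
    }
  }
})

test_that("scoring is deterministic and order-independent", {
  cohort <- simulate_cohort(cohort_params(n = 60, prevalence = 0.7, seed = 9))
  a <- score_cohort(cohort)
  b <- score_cohort(cohort)
  expect_identical(a, b)
  shuffled <- cohort[sample(nrow(cohort)), ]
  c <- score_cohort(shuffled) |> dplyr::arrange(model, id)
  expect_equal(dplyr::arrange(a, model, id)$probability, c$probability)
})
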