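test_that("logistic fit reproduces the closed-form 2x2 log odds ratio", {
  # exposed cases a=20, exposed controls b=10, unexposed cases c=10,
  # unexposed controls d=20
  x <- rep(c(1, 1, 0, 0), c(20, 10, 10, 20))
  y <- rep(c(1, 0, 1, 0), c(20, 10, 10, 20))
  fit <- fit_logistic(data.frame(exposure = x), y)
  terms <- tidy(fit)
  b <- terms$estimate[terms$term == "exposure"]
  se <- terms$std_error[terms$term == "exposure"]
  expect_equal(b, log(4), tolerance = 1e-6)
  expect_equal(se, sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20), tolerance = 1e-6)
  expect_equal(terms$or[terms$term == "exposure"], 4, tolerance = 1e-6)
  expect_equal(terms$wald[terms$term == "exposure"], (b / se)^2)
  expect_equal(terms$ci_lower[terms$term == "exposure"],
               exp(b - 1.96 * se))
  expect_true(fit$converged)
  expect_length(fit$separation_flags, 0)
})

test_that("an outcome independent of the covariate fits near zero", {
  set.seed(42)
  x <- rbinom(4000, 1, 0.5)
  y <- rbinom(4000, 1, 0.4)
  terms <- tidy(fit_logistic(data.frame(x = x), y))
  expect_lt(abs(terms$estimate[terms$term == "x"]), 0.2)
  expect_equal(terms$or[terms$term == "x"], 1, tolerance = 0.25)
})

test_that("complete separation is flagged, not reported as an estimate", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- x # covariate perfectly predicts outcome
  fit <- fit_logistic(data.frame(sep = x), y)
  expect_true("sep" %in% fit$separation_flags)
  terms <- tidy(fit)
  expect_true(terms$flagged[terms$term == "sep"])
  expect_true(is.na(terms$or[terms$term == "sep"]))
  expect_true(is.na(terms$p[terms$term == "sep"]))
})

test_that("collinear designs raise a flag on the aliased term", {
  set.seed(11)
  x <- rnorm(200)
  y <- rbinom(200, 1, plogis(x))
  fit <- fit_logistic(data.frame(a = x, b = x), y)
  expect_true("b" %in% fit$separation_flags)
})

test_that("coefficient-recovery coverage reaches nominal level", {
  # known truth: intercept -1, slope 0.8, standard normal covariate
  set.seed(314)
  n_reps <- 200
  covered <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    x <- rnorm(5000)
    y <- rbinom(5000, 1, plogis(-1 + 0.8 * x))
    terms <- tidy(fit_logistic(data.frame(x = x), y))
    b <- terms$estimate[terms$term == "x"]
    se <- terms$std_error[terms$term == "x"]
    covered[i] <- (0.8 >= b - 1.96 * se) && (0.8 <= b + 1.96 * se)
  }
  expect_gte(mean(covered), 0.93)
})

test_that("combined four-model regression recovers the planted model", {
  set.seed(77)
  hits <- 0
  n_reps <- 12
  for (i in seq_len(n_reps)) {
    cohort <- simulate_cohort(cohort_params(seed = 1000 + i))
    preds <- score_cohort(cohort)
    fit <- combined_model_regression(preds, cohort)
    terms <- tidy(fit)
    p_pkuph <- terms$p[terms$term == "pkuph"]
    if (!is.na(p_pkuph) && p_pkuph < 0.05) hits <- hits + 1
  }
  expect_gt(hits, n_reps / 2)
})

test_that("constant predictions leave only the intercept informative", {
  cohort <- simulate_cohort(cohort_params(n = 200, prevalence = 0.75,
                                          seed = 21))
  preds <- score_cohort(cohort)
  preds$probability <- 0.4 # degenerate: every model says the same thing
  fit <- combined_model_regression(preds, cohort)
  terms <- tidy(fit)
  model_rows <- terms[terms$term != "Constant", ]
  # constant columns are collinear with the intercept: flagged or ~0
  expect_true(all(model_rows$flagged |
                    abs(model_rows$estimate) < 1e-6))
  const <- terms[terms$term == "Constant", ]
  prevalence <- mean(cohort$outcome_malignant)
  expect_equal(const$estimate, qlogis(prevalence), tolerance = 1e-6)
})

test_that("refitting a model's covariates gives the published table shape", {
  cohort <- simulate_cohort(cohort_params(seed = 4))
  fit <- model_covariate_refit(cohort, "pkuph")
  terms <- tidy(fit)
  expect_setequal(
    terms$term,
    c("(Intercept)", "age", "family_history_cancer", "diameter",
      "spiculation", "smooth_border", "calcification")
  )
  expect_named(terms, c("term", "estimate", "std_error", "wald", "df", "p",
                        "or", "ci_lower", "ci_upper", "flagged"))
})
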