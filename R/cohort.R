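# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Parameters of the synthetic validation cohort
#'
#' Bundles the structural parameters of the emulated hospital cohort: size,
#' malignancy prevalence, the age range, the three diameter strata with
#' their weights, prevalences of the binary CT/clinical features, and the
#' histology and stage mixes among malignant cases. Defaults reproduce the
#' structure of a 496-patient surgical validation cohort: 425 malignant /
#' 71 benign, ages 29-89, diameter strata 1.9-8 mm (weight 126/496),
#' 8-30 mm (219/496) and 30-124 mm (151/496), and 150 adenocarcinoma / 56
#' squamous among the malignant.
#'
#' The outcome is generated from a planted mechanism: the `truth_model`'s
#' linear predictor, with its intercept shifted so that the cohort's
#' expected prevalence matches `prevalence` (the shift is solved on the
#' realised covariates, keeping the planted covariate effects intact).
#'
#' @param n Cohort size (default 496).
#' @param prevalence Malignant fraction (default 425/496).
#' @param age_range Integer age range in years (default 29-89).
#' @param diameter_breaks Boundaries of the diameter strata in mm
#'   (default 1.9, 8, 30, 124).
#' @param diameter_bin_weights Mixing proportions of the strata
#'   (default 126/496, 219/496, 151/496).
#' @param feature_prevalences Named probabilities of the binary features.
#' @param histology_mix Proportions of adenocarcinoma / squamous / other
#'   among malignant cases (default 150/425, 56/425, remainder).
#' @param stage_mix Stage proportions among malignant cases.
#' @param truth_model The planted outcome mechanism: a [nodule_model] or a
#'   registry name (default `"pkuph"`). Use [null_truth_model()] for a
#'   zero-signal cohort.
#' @param quit_years_max Former/current smokers get `quit_years` uniform on
#'   `[0, quit_years_max]`; never-smokers get 0.
#' @param seed Integer seed; `NULL` means use the current RNG stream.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n = 496L,
                          prevalence = 425 / 496,
                          age_range = c(29L, 89L),
                          diameter_breaks = c(1.9, 8, 30, 124),
                          diameter_bin_weights = c(126, 219, 151) / 496,
                          feature_prevalences = c(
                            sex_female = 0.30,
                            ever_smoker = 0.405,
                            upper_lobe = 0.575,
                            spiculation = 0.205,
                            calcification = 0.47,
                            family_history_cancer = 0.095,
                            ground_glass = 0.165,
                            air_bronchogram = 0.05,
                            lung_cancer_history = 0.035,
                            cancer_history = 0.06,
                            smooth_border = 0.30,
                            clear_border = 0.50,
                            lobulation = 0.40
                          ),
                          histology_mix = c(adenocarcinoma = 150 / 425,
                                            squamous = 56 / 425,
                                            other_malignant = 219 / 425),
                          stage_mix = c(I = 0.21, II = 0.18,
                                        III = 0.30, IV = 0.31),
                          truth_model = "pkuph",
                          quit_years_max = 20,
                          seed = NULL) {
  stopifnot(n >= 2L)
  if (!(prevalence > 0 && prevalence < 1) ||
      n * prevalence < 1 || n * (1 - prevalence) < 1) {
    rlang::abort(paste("`prevalence` must give at least one expected case",
                       "and one expected control."))
  }
  stopifnot(length(age_range) == 2L, age_range[1] >= 0,
            age_range[1] <= age_range[2])
  stopifnot(length(diameter_breaks) >= 2L, all(diff(diameter_breaks) > 0),
            diameter_breaks[1] > 0)
  n_bins <- length(diameter_breaks) - 1L
  stopifnot(length(diameter_bin_weights) == n_bins,
            all(diameter_bin_weights >= 0))
  check_mix <- function(x, what) {
    if (any(x < 0) || any(x > 1) || abs(sum(x) - 1) > 1e-6) {
      rlang::abort(paste0("`", what, "` must be proportions summing to 1."))
    }
  }
  check_mix(diameter_bin_weights, "diameter_bin_weights")
  check_mix(histology_mix, "histology_mix")
  check_mix(stage_mix, "stage_mix")
  stopifnot(all(feature_prevalences >= 0), all(feature_prevalences <= 1))
  if ("benign" %in% names(histology_mix)) {
    rlang::abort("`histology_mix` describes malignant cases; it cannot contain 'benign'.")
  }
  truth_model <- as_nodule_model(truth_model)
  structure(
    list(n = as.integer(n), prevalence = prevalence, age_range = age_range,
         diameter_breaks = diameter_breaks,
         diameter_bin_weights = diameter_bin_weights,
         feature_prevalences = feature_prevalences,
         histology_mix = histology_mix, stage_mix = stage_mix,
         truth_model = truth_model, quit_years_max = quit_years_max,
         seed = seed),
    class = "cohort_params"
  )
}

#' A zero-signal truth model
#'
#' All covariate coefficients zero: the planted outcome is independent of
#' every covariate, so any model's discrimination is 0.5 up to Monte-Carlo
#' error. Useful as a negative control for the evaluation pipeline.
#'
#' @return A [nodule_model] named `"null"`.
#' @export
null_truth_model <- function() {
  nodule_model("null", coefficients = c(age = 0), constant = 0)
}

#' Generate a synthetic patient cohort
#'
#' Draws a cohort of the configured structure: diameters by stratum (uniform
#' within each stratum), integer ages uniform over the age range, binary
#' features as independent Bernoulli draws, `quit_years` uniform for
#' ever-smokers. The malignant outcome is Bernoulli at the truth model's
#' probability after an intercept shift that matches the target prevalence
#' on the realised covariates (solved by root finding, so the planted
#' covariate effects are untouched). Histology and stage are then assigned
#' to malignant cases by the configured mixes; benign patients get
#' `histology = "benign"` and missing stage.
#'
#' The same seed and parameters always reproduce the identical cohort.
#'
#' @param params A [cohort_params()] object.
#' @param seed Overrides `params$seed` when given.
#' @return A tibble with one row per patient and the standard cohort
#'   columns (see [cohort_columns()]).
#' @export
simulate_cohort <- function(params = cohort_params(), seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  seed <- seed %||% params$seed
  draw <- function() {
    n <- params$n
    n_bins <- length(params$diameter_breaks) - 1L
    stratum_idx <- sample.int(n_bins, n, replace = TRUE,
                              prob = params$diameter_bin_weights)
    lo <- params$diameter_breaks[stratum_idx]
    hi <- params$diameter_breaks[stratum_idx + 1L]
    diameter <- stats::runif(n, lo, hi)
    age <- sample(seq(params$age_range[1], params$age_range[2]), n,
                  replace = TRUE)
    features <- purrr::imap_dfc(as.list(params$feature_prevalences),
                                function(p, nm) {
      tibble::tibble(!!nm := stats::rbinom(n, 1L, p))
    })
    cohort <- tibble::tibble(
      id = sprintf("P%04d", seq_len(n)),
      age = age
    ) |>
      dplyr::bind_cols(features) |>
      dplyr::mutate(
        quit_years = ifelse(.data$ever_smoker == 1,
                            stats::runif(n, 0, params$quit_years_max), 0),
        diameter_mm = diameter
      )

    x0 <- linear_predictor(cohort, params$truth_model)
    shift <- prevalence_shift(x0, params$prevalence)
    p_malignant <- stats::plogis(x0 + shift)
    outcome <- stats::rbinom(n, 1L, p_malignant)

    histology <- rep("benign", n)
    stage <- rep(NA_character_, n)
    cases <- which(outcome == 1)
    if (length(cases)) {
      histology[cases] <- sample(names(params$histology_mix), length(cases),
                                 replace = TRUE, prob = params$histology_mix)
      stage[cases] <- sample(names(params$stage_mix), length(cases),
                             replace = TRUE, prob = params$stage_mix)
    }
    cohort |>
      dplyr::mutate(
        outcome_malignant = outcome,
        histology = histology,
        stage = stage
      ) |>
      dplyr::select(dplyr::all_of(cohort_columns()))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# intercept shift making mean plogis(x + s) equal the target prevalence
prevalence_shift <- function(x, prevalence) {
  f <- function(s) mean(stats::plogis(x + s)) - prevalence
  stats::uniroot(f, lower = -80, upper = 80, tol = 1e-10)$root
}

#' Plant a truth model and measure its recovery
#'
#' The end-to-end stress test of the pipeline: over `n_reps` seeded
#' replicates, generate a cohort whose outcome is planted from
#' `params$truth_model`, score it with all candidate models, measure each
#' model's benign-vs-malignant AUC, and refit the truth model's covariates
#' by logistic regression to check that the planted coefficients are
#' recovered (95% Wald CI coverage per coefficient).
#'
#' Replicate seeds are `params$seed + 1, + 2, ...` so the whole report is
#' reproducible from a single seed.
#'
#' @param params A [cohort_params()]; `params$seed` must be set.
#' @param n_reps Number of replicates.
#' @param models Candidate models to score (default all four).
#' @param stratum Stratum on which AUCs are compared.
#' @return An object of class `recovery_report`: `auc` (tibble of rep,
#'   model, auc), `top_counts` (how often each model ranked first),
#'   `coverage` (per planted coefficient: times the refit CI covered it),
#'   `truth` (truth model name), `n_reps`.
#' @export
plant_and_recover <- function(params = cohort_params(seed = 1),
                              n_reps = 20L,
                              models = nodule_models(),
                              stratum = "benign_vs_malignant") {
  stopifnot(inherits(params, "cohort_params"), n_reps >= 1L)
  if (is.null(params$seed)) {
    rlang::abort("`params$seed` must be set for a reproducible recovery run.")
  }
  models <- as_model_list(models)
  truth <- params$truth_model
  truth_beta <- truth$coefficients
  reps <- purrr::map(seq_len(n_reps), function(rep) {
    cohort <- simulate_cohort(params, seed = params$seed + rep)
    preds <- score_cohort(cohort, models)
    ev <- evaluate_models_on_stratum(preds, cohort, stratum)
    refit <- model_covariate_refit(cohort, truth)
    terms <- refit$terms[refit$terms$term %in% names(truth_beta), ]
    covered <- !terms$flagged &
      (truth_beta[terms$term] >= terms$estimate - 1.96 * terms$std_error) &
      (truth_beta[terms$term] <= terms$estimate + 1.96 * terms$std_error)
    list(
      auc = tibble::tibble(rep = rep, model = ev$model, auc = ev$auc,
                           auc_rank = ev$auc_rank),
      coverage = tibble::tibble(rep = rep, term = terms$term,
                                covered = covered)
    )
  })
  auc <- purrr::map_dfr(reps, "auc")
  coverage <- purrr::map_dfr(reps, "coverage") |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(n_covered = sum(.data$covered),
                     n_reps = dplyr::n(),
                     coverage = mean(.data$covered), .groups = "drop")
  top <- auc |>
    dplyr::filter(.data$auc_rank == 1L) |>
    dplyr::count(.data$model, name = "n_top") |>
    dplyr::arrange(dplyr::desc(.data$n_top))
  structure(
    list(auc = auc, top_counts = top, coverage = coverage,
         truth = truth$name, n_reps = n_reps),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> truth =", x$truth, "over", x$n_reps, "replicates\n")
  cat("Top-AUC counts:\n")
  print(x$top_counts)
  cat("Planted-coefficient 95% CI coverage:\n")
  print(x$coverage)
  invisible(x)
}

#' @exportS3Method
glance.recovery_report <- function(x, ...) {
  best <- x$top_counts$model[1]
  tibble::tibble(
    truth = x$truth, n_reps = x$n_reps,
    top_model = best,
    top_fraction = x$top_counts$n_top[1] / x$n_reps,
    min_coverage = if (nrow(x$coverage)) min(x$coverage$coverage) else NA_real_
  )
}
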