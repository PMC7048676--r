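#' Pipeline configuration
#'
#' Builds the configuration for an end-to-end run. Exactly one of
#' `cohort_file` or `simulate` must be supplied. CLI flags override a YAML
#' file, which overrides these defaults.
#'
#' @param cohort_file Path to a cohort CSV, or `NULL` to simulate.
#' @param simulate A [cohort_params()] object (or a list of arguments for
#'   it) when simulating.
#' @param models Model names to score.
#' @param strata Stratum names to evaluate.
#' @param n_bins Calibration bins.
#' @param out_dir Output directory for reports.
#' @param seed Seed recorded in the manifest and used for simulation.
#' @param strict Strict cohort validation (abort on first bad row).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_file = NULL,
                            simulate = NULL,
                            models = c("mayo", "va", "pkuph", "brock"),
                            strata = c("benign_vs_malignant", "early_vs_late",
                                       "squamous", "adenocarcinoma"),
                            n_bins = 10L,
                            out_dir = "nodulerisk-run",
                            seed = 1L,
                            strict = FALSE) {
  if (is.null(cohort_file) && is.null(simulate)) {
    simulate <- cohort_params(seed = seed)
  }
  if (!is.null(cohort_file) && !is.null(simulate)) {
    rlang::abort("Supply either `cohort_file` or `simulate`, not both.")
  }
  if (!is.null(simulate) && !inherits(simulate, "cohort_params")) {
    simulate <- do.call(cohort_params, simulate)
  }
  if (!is.null(simulate) && is.null(simulate$seed)) simulate$seed <- seed
  structure(
    list(cohort_file = cohort_file, simulate = simulate, models = models,
         strata = strata, n_bins = n_bins, out_dir = out_dir, seed = seed,
         strict = strict),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments; a `simulate` mapping is passed to [cohort_params()].
#' @param ... Overrides applied after the file (CLI-flag precedence).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n:` key as boolean false; map it back
  if (!is.null(y$simulate)) {
    names(y$simulate)[names(y$simulate) == "FALSE"] <- "n"
  }
  overrides <- list(...)
  y[names(overrides)] <- overrides
  do.call(pipeline_config, y)
}

#' Run the full validation pipeline
#'
#' Read or simulate a cohort, score it with the requested models, evaluate
#' AUCs on the requested strata, compute per-model calibration, the
#' univariate screen, per-model covariate refits and the combined four-model
#' regression, and write everything to `out_dir` together with a JSON run
#' manifest (seed, package version, configuration hash). Re-running an
#' identical configuration reproduces identical outputs.
#'
#' Configuration problems (an unknown model or stratum name, a missing
#' cohort file) abort before any scoring begins.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `validation`, `predictions`, `evaluation`, `calibration`, `screen`,
#'   `refits`, `combined`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  # fail-fast validation of names before any work
  models <- as_model_list(as.list(config$models))
  strata <- lapply(config$strata, as_stratum)
  names(strata) <- vapply(strata, `[[`, character(1), "name")
  if (!is.null(config$cohort_file) && !file.exists(config$cohort_file)) {
    rlang::abort(paste0("Cohort file not found: ", config$cohort_file))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("Pipeline stage '", name, "' failed: ",
                          conditionMessage(e)))
    })
  }

  if (!is.null(config$cohort_file)) {
    read <- stage("read_cohort",
                  read_cohort(config$cohort_file, strict = config$strict))
    cohort <- read$cohort
    validation <- read$report
  } else {
    cohort <- stage("simulate", simulate_cohort(config$simulate))
    validation <- structure(
      list(n_read = nrow(cohort), n_valid = nrow(cohort), n_excluded = 0L,
           exclusion_reasons = stats::setNames(integer(0), character(0))),
      class = "validation_report"
    )
  }

  predictions <- stage("score", score_cohort(cohort, models))
  evaluation <- stage("evaluate",
                      evaluate_models(predictions, cohort, strata))
  calib <- stage("calibration", {
    labelled <- dplyr::inner_join(
      predictions,
      dplyr::transmute(cohort, id = as.character(.data$id),
                       outcome = .data$outcome_malignant),
      by = "id"
    )
    labelled |>
      dplyr::filter(!is.na(.data$outcome), !is.na(.data$probability)) |>
      dplyr::group_by(.data$model) |>
      dplyr::group_modify(function(df, key) {
        tidy(calibration_curve(df$probability, df$outcome,
                               n_bins = min(config$n_bins, nrow(df))))
      }) |>
      dplyr::ungroup()
  })
  screen <- stage("univariate_screen", univariate_screen(cohort))
  refits <- stage("refit", purrr::map_dfr(models, function(m) {
    dplyr::mutate(tidy(model_covariate_refit(cohort, m)),
                  model = m$name, .before = 1L)
  }))
  combined <- stage("combined_regression",
                    combined_model_regression(predictions, cohort))

  # applicability warnings summarised per model
  warning_summary <- predictions |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(n_warnings = sum(lengths(.data$warnings)),
                     n_not_applicable = sum(!.data$applicable, na.rm = TRUE),
                     .groups = "drop")

  out <- function(f) file.path(config$out_dir, f)
  write_predictions(predictions, out("predictions.csv"))
  evaluation_flat <- dplyr::select(evaluation, -"roc")
  readr::write_csv(evaluation_flat, out("auc_by_stratum.csv"))
  readr::write_csv(calib, out("calibration.csv"))
  readr::write_csv(screen, out("univariate_screen.csv"))
  readr::write_csv(refits, out("model_refits.csv"))
  readr::write_csv(tidy(combined), out("combined_model_fit.csv"))
  jsonlite::write_json(
    list(evaluation = evaluation_flat, calibration = calib,
         combined = tidy(combined)),
    out("evaluation.json"), auto_unbox = TRUE, digits = NA, na = "null"
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("nodulerisk")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_read = validation$n_read,
    n_valid = validation$n_valid,
    n_excluded = validation$n_excluded,
    models = names(models),
    strata = names(strata),
    warning_summary = warning_summary
  )
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, validation = validation,
                 predictions = predictions, evaluation = evaluation,
                 calibration = calib, screen = screen, refits = refits,
                 combined = combined, manifest = manifest))
}
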