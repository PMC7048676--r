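#' Diagnostic strata
#'
#' A stratum names the case/control contrast on which model discrimination is
#' measured. The four built-in strata follow the validation design this
#' package implements:
#'
#' * `benign_vs_malignant` — all patients; cases are pathologically malignant
#'   nodules, controls benign.
#' * `early_vs_late` — malignant patients only; cases are stage III/IV,
#'   controls stage I/II.
#' * `squamous` — squamous-cell carcinoma cases against benign controls.
#' * `adenocarcinoma` — adenocarcinoma cases against benign controls.
#'
#' For the histology strata the choice of control group (benign nodules vs
#' all other patients) is a genuine design degree of freedom; benign controls
#' are the default, and custom predicates can encode the alternative.
#'
#' @param name Stratum name.
#' @param case,control Predicate functions taking the cohort data frame and
#'   returning a logical vector selecting cases / controls. The two must be
#'   disjoint.
#' @return An object of class `nodule_stratum`.
#' @export
stratum <- function(name, case, control) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(case), is.function(control))
  structure(list(name = name, case = case, control = control),
            class = "nodule_stratum")
}

#' @rdname stratum
#' @param names Which built-in strata to return.
#' @export
nodule_strata <- function(names = c("benign_vs_malignant", "early_vs_late",
                                    "squamous", "adenocarcinoma")) {
  names <- match.arg(names, several.ok = TRUE)
  all <- list(
    benign_vs_malignant = stratum(
      "benign_vs_malignant",
      case = function(d) !is.na(d$outcome_malignant) & d$outcome_malignant == 1,
      control = function(d) !is.na(d$outcome_malignant) & d$outcome_malignant == 0
    ),
    early_vs_late = stratum(
      "early_vs_late",
      case = function(d) !is.na(d$stage) & d$stage %in% c("III", "IV"),
      control = function(d) !is.na(d$stage) & d$stage %in% c("I", "II")
    ),
    squamous = stratum(
      "squamous",
      case = function(d) !is.na(d$histology) & d$histology == "squamous",
      control = function(d) !is.na(d$histology) & d$histology == "benign"
    ),
    adenocarcinoma = stratum(
      "adenocarcinoma",
      case = function(d) !is.na(d$histology) & d$histology == "adenocarcinoma",
      control = function(d) !is.na(d$histology) & d$histology == "benign"
    )
  )
  all[names]
}

as_stratum <- function(x) {
  if (inherits(x, "nodule_stratum")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!x %in% c("benign_vs_malignant", "early_vs_late", "squamous",
                  "adenocarcinoma")) {
      rlang::abort(paste0("Unknown stratum name: '", x, "'."))
    }
    return(nodule_strata(x)[[1L]])
  }
  rlang::abort("`stratum` must be a nodule_stratum or a built-in stratum name.")
}

#' Compare model discrimination on a diagnostic stratum
#'
#' Restricts the cohort to the patients selected by the stratum's case and
#' control predicates and computes one ROC/AUC per model from the predicted
#' probabilities. Patients outside the stratum never influence the result.
#'
#' @param predictions Long prediction table from [score_cohort()] (columns
#'   `id`, `model`, `probability`).
#' @param cohort The cohort the predictions were computed from.
#' @param stratum A [stratum()] object or built-in stratum name.
#' @param conf_level Confidence level for the AUC intervals.
#' @return A tibble with one row per model: `stratum`, `model`, `auc`,
#'   `se`, `ci_lower`, `ci_upper`, `n_pos`, `n_neg`, `auc_rank` (1 = best),
#'   and a `roc` list-column of `roc_result` objects.
#' @export
evaluate_models_on_stratum <- function(predictions, cohort, stratum,
                                       conf_level = 0.95) {
  stratum <- as_stratum(stratum)
  is_case <- stratum$case(cohort)
  is_control <- stratum$control(cohort)
  if (any(is_case & is_control)) {
    rlang::abort(paste0("Stratum '", stratum$name,
                        "': case and control predicates overlap."))
  }
  if (!any(is_case) || !any(is_control)) {
    rlang::abort(paste0("Stratum '", stratum$name, "' is empty: ",
                        sum(is_case), " case(s), ", sum(is_control),
                        " control(s)."))
  }
  members <- tibble::tibble(
    id = as.character(cohort$id[is_case | is_control]),
    label = as.integer(is_case[is_case | is_control])
  )
  scored <- dplyr::inner_join(predictions, members, by = "id")
  out <- scored |>
    dplyr::group_by(.data$model) |>
    dplyr::group_modify(function(df, key) {
      roc <- compute_auc(df$probability, df$label, conf_level = conf_level)
      g <- glance(roc)
      g$roc <- list(roc)
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      stratum = stratum$name,
      auc_rank = rank(-.data$auc, ties.method = "min"),
      .before = 1L
    ) |>
    dplyr::relocate("stratum", "model")
  dplyr::select(out, "stratum", "model", "auc", "se", "ci_lower", "ci_upper",
                "n_pos", "n_neg", "auc_rank", "roc")
}

#' Evaluate models on several strata at once
#'
#' @inheritParams evaluate_models_on_stratum
#' @param strata A list of strata (objects or names); defaults to all four
#'   built-in strata.
#' @return Row-bound tibble of [evaluate_models_on_stratum()] results.
#' @export
evaluate_models <- function(predictions, cohort, strata = nodule_strata(),
                            conf_level = 0.95) {
  strata <- lapply(strata, as_stratum)
  purrr::map_dfr(strata, function(s) {
    evaluate_models_on_stratum(predictions, cohort, s,
                               conf_level = conf_level)
  })
}

#' Dot-and-interval plot of AUCs by stratum and model
#'
#' @param evaluation Result of [evaluate_models()] or
#'   [evaluate_models_on_stratum()].
#' @return A ggplot.
#' @export
plot_auc_comparison <- function(evaluation) {
  ggplot2::ggplot(
    evaluation,
    ggplot2::aes(x = .data$model, y = .data$auc,
                 ymin = .data$ci_lower, ymax = .data$ci_upper)
  ) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange() +
    ggplot2::facet_wrap(ggplot2::vars(.data$stratum)) +
    ggplot2::labs(x = NULL, y = "AUC (95% CI)") +
    ggplot2::theme_minimal()
}
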