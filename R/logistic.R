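#' Multivariate logistic regression with Wald/odds-ratio reporting
#'
#' Fits a binomial GLM by iteratively reweighted least squares (via
#' [stats::glm()], convergence tolerance 1e-8, at most 50 iterations) and
#' assembles the coefficient table in the conventional clinical-report shape:
#' B, standard error, Wald chi-square `(B/SE)^2`, df, p, odds ratio `exp(B)`
#' and its 95% CI `exp(B +/- 1.96 SE)`.
#'
#' Complete or quasi-separation (a covariate pattern perfectly predicting the
#' outcome) drives estimates toward infinity; such terms are detected by
#' runaway magnitude (`|B| > 15` or `SE > 100`) and flagged rather than
#' reported as meaningful: their Wald statistic, p and odds ratio are set to
#' `NA` and the term name is listed in `separation_flags`. Covariates dropped
#' by the fit for collinearity (aliased coefficients) are flagged the same
#' way.
#'
#' @param design Data frame of covariates (numeric columns), one row per
#'   subject. An intercept is always added.
#' @param outcome Binary vector (0/1 or logical) of the same length.
#' @return An object of class `logistic_fit` with a `terms` tibble
#'   (`term`, `estimate`, `std_error`, `wald`, `df`, `p`, `or`, `ci_lower`,
#'   `ci_upper`, `flagged`), plus `converged`, `separation_flags`, `n`,
#'   `deviance`, `null_deviance`, `aic` and the underlying `glm` object.
#' @examples
#' x <- rep(c(1, 1, 0, 0), c(20, 10, 10, 20))
#' y <- rep(c(1, 0, 1, 0), c(20, 10, 10, 20))
#' fit <- fit_logistic(data.frame(exposure = x), y)
#' tidy(fit) # estimate = log(4), SE = sqrt(1/20 + 1/10 + 1/10 + 1/20)
#' @export
fit_logistic <- function(design, outcome) {
  design <- as.data.frame(design)
  if (is.logical(outcome)) outcome <- as.integer(outcome)
  stopifnot(nrow(design) == length(outcome))
  if (!all(outcome %in% c(0, 1))) rlang::abort("`outcome` must be binary (0/1).")
  if (nrow(design) < ncol(design) + 2L) {
    rlang::abort("Not enough observations to fit the requested terms.")
  }
  dat <- cbind(design, .outcome = outcome)
  fit <- suppressWarnings(stats::glm(
    .outcome ~ ., data = dat, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 50)
  ))
  smry <- summary(fit)
  coefs <- stats::coef(fit) # includes NA for aliased terms
  terms <- tibble::tibble(
    term = names(coefs),
    estimate = unname(coefs),
    std_error = NA_real_
  )
  est_tab <- smry$coefficients
  terms$std_error[match(rownames(est_tab), terms$term)] <- est_tab[, "Std. Error"]
  terms <- terms |>
    dplyr::mutate(
      aliased = is.na(.data$estimate),
      runaway = !.data$aliased &
        (abs(.data$estimate) > 15 | .data$std_error > 100),
      flagged = .data$aliased | .data$runaway,
      wald = ifelse(.data$flagged, NA_real_,
                    (.data$estimate / .data$std_error)^2),
      df = 1L,
      p = ifelse(.data$flagged, NA_real_,
                 stats::pchisq(.data$wald, df = 1, lower.tail = FALSE)),
      or = ifelse(.data$flagged, NA_real_, exp(.data$estimate)),
      ci_lower = ifelse(.data$flagged, NA_real_,
                        exp(.data$estimate - 1.96 * .data$std_error)),
      ci_upper = ifelse(.data$flagged, NA_real_,
                        exp(.data$estimate + 1.96 * .data$std_error))
    ) |>
    dplyr::select("term", "estimate", "std_error", "wald", "df", "p",
                  "or", "ci_lower", "ci_upper", "flagged")
  structure(
    list(
      terms = terms,
      converged = fit$converged,
      separation_flags = terms$term[terms$flagged],
      n = nrow(design),
      deviance = fit$deviance,
      null_deviance = fit$null.deviance,
      aic = fit$aic,
      fit = fit
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> n =", x$n,
      if (!x$converged) "(did not converge)" else "", "\n")
  print(x$terms, n = Inf)
  if (length(x$separation_flags)) {
    cat("Flagged (separation/collinearity):",
        paste(x$separation_flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method
tidy.logistic_fit <- function(x, ...) x$terms

#' @exportS3Method
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, converged = x$converged,
    n_flagged = length(x$separation_flags),
    deviance = x$deviance, null_deviance = x$null_deviance, aic = x$aic
  )
}

#' Head-to-head logistic comparison of the four models
#'
#' Regresses the pathological outcome on the four models' predicted
#' probabilities simultaneously (plus a constant). A model whose prediction
#' carries independent information about the outcome, beyond what the other
#' three predictions already encode, gets a significant coefficient.
#'
#' @param predictions Long prediction table from [score_cohort()].
#' @param cohort Cohort data frame carrying `id` and `outcome_malignant`.
#' @return A `logistic_fit`; term order follows the order models appear in
#'   `predictions`, intercept last (reported as `Constant`).
#' @export
combined_model_regression <- function(predictions, cohort) {
  wide <- predictions |>
    dplyr::select("id", "model", "probability") |>
    tidyr::pivot_wider(names_from = "model", values_from = "probability")
  merged <- dplyr::inner_join(
    wide,
    dplyr::select(
      dplyr::mutate(cohort, id = as.character(.data$id)),
      "id", "outcome_malignant"
    ),
    by = "id"
  )
  merged <- merged[stats::complete.cases(merged), , drop = FALSE]
  model_cols <- setdiff(names(wide), "id")
  fit <- fit_logistic(merged[model_cols], merged$outcome_malignant)
  # present the intercept last, named as in clinical reports
  terms <- fit$terms
  is_const <- terms$term == "(Intercept)"
  terms$term[is_const] <- "Constant"
  fit$terms <- dplyr::bind_rows(terms[!is_const, ], terms[is_const, ])
  fit$separation_flags <- fit$terms$term[fit$terms$flagged]
  fit
}

#' Refit a model's covariates against the local outcome
#'
#' Multivariate logistic regression of the pathological outcome on the
#' covariates a published model uses (with the Brock diameter transform
#' applied where relevant), giving the locally re-estimated coefficient/OR
#' table to set against the published coefficients.
#'
#' @param cohort Cohort data frame with `outcome_malignant`.
#' @param model A [nodule_model] or registry name.
#' @return A `logistic_fit`.
#' @export
model_covariate_refit <- function(cohort, model) {
  model <- as_nodule_model(model)
  check_model_columns(cohort, model)
  design <- purrr::map_dfc(names(model$coefficients), function(term) {
    col <- if (term == "diameter") "diameter_mm" else term
    v <- cohort[[col]]
    if (term == "diameter" && model$diameter_transform == "brock_power") {
      v <- brock_diameter_transform(v)
    }
    tibble::tibble(!!term := v)
  })
  keep <- stats::complete.cases(design) & !is.na(cohort$outcome_malignant)
  fit_logistic(design[keep, , drop = FALSE], cohort$outcome_malignant[keep])
}
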