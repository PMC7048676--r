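#' Published pulmonary-nodule malignancy models
#'
#' Constructors and a built-in registry for the four published logistic
#' calculators that estimate the probability a pulmonary nodule seen on CT is
#' malignant: Mayo Clinic, Department of Veterans Affairs (VA), Peking
#' University People's Hospital (PKUPH) and Brock University. Each model is a
#' linear predictor `x = constant + sum(coefficient_i * covariate_i)` mapped to
#' a probability through the logistic link `p = exp(x) / (1 + exp(x))`.
#'
#' The Brock model enters nodule diameter through the decreasing power
#' transform `(diameter/10)^-0.5 - 1.5811`; all other models use diameter in
#' millimetres directly. Binary covariates are coded 0/1 with 1 = presence;
#' sex is coded female = 1.
#'
#' @param name Model name, one of `"mayo"`, `"va"`, `"pkuph"`, `"brock"`, or
#'   any string for a custom model.
#' @param coefficients Named numeric vector of coefficients. Names must be
#'   cohort column names, except `"diameter"` which refers to `diameter_mm`
#'   passed through the model's diameter transform.
#' @param constant The model constant (intercept), a single number.
#' @param diameter_transform Either `"identity"` or `"brock_power"`.
#' @param diameter_range_mm Closed applicability interval for diameter in mm,
#'   length-2 numeric; diameters outside it trigger an advisory warning but do
#'   not block scoring.
#' @param exclusions Character vector of names of built-in exclusion
#'   predicates; currently `"prior_cancer"` (any prior malignancy flagged via
#'   `cancer_history` or `lung_cancer_history`).
#' @return An object of class `nodule_model`.
#' @examples
#' m <- nodule_models()[["brock"]]
#' patient <- tibble::tibble(
#'   id = "example", age = 60, sex_female = 0, upper_lobe = 0,
#'   spiculation = 0, diameter_mm = 10
#' )
#' predict_probability(patient, m)
#' @export
nodule_model <- function(name, coefficients, constant,
                         diameter_transform = c("identity", "brock_power"),
                         diameter_range_mm = c(0, Inf),
                         exclusions = character()) {
  diameter_transform <- match.arg(diameter_transform)
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            all(nzchar(names(coefficients))),
            is.numeric(constant), length(constant) == 1L,
            is.numeric(diameter_range_mm), length(diameter_range_mm) == 2L,
            diameter_range_mm[1] <= diameter_range_mm[2])
  structure(
    list(
      name = name,
      coefficients = coefficients,
      constant = unname(constant),
      diameter_transform = diameter_transform,
      diameter_range_mm = diameter_range_mm,
      exclusions = exclusions
    ),
    class = "nodule_model"
  )
}

#' @export
print.nodule_model <- function(x, ...) {
  cat("<nodule_model> ", x$name, "\n", sep = "")
  cat("  constant: ", format(x$constant), "\n", sep = "")
  coefs <- paste0(names(x$coefficients), " = ", format(x$coefficients))
  cat("  coefficients: ", paste(coefs, collapse = ", "), "\n", sep = "")
  cat("  diameter transform: ", x$diameter_transform, "\n", sep = "")
  cat("  diameter range: ", x$diameter_range_mm[1], "-",
      x$diameter_range_mm[2], " mm\n", sep = "")
  invisible(x)
}

#' Registry of the four published models
#'
#' Returns the built-in models with their published coefficients, constants,
#' diameter transforms and applicability ranges. Coefficients are kept exactly
#' as tabulated in the validation study this package follows, including the
#' positive VA quit-years coefficient (+0.0567) and the Mayo constant
#' (-6.872), which differ from some earlier printings of those models.
#'
#' @param names Which models to return; any subset of
#'   `c("mayo", "va", "pkuph", "brock")`.
#' @return A named list of [nodule_model] objects.
#' @export
nodule_models <- function(names = c("mayo", "va", "pkuph", "brock")) {
  names <- match.arg(names, several.ok = TRUE)
  registry <- list(
    mayo = nodule_model(
      "mayo",
      coefficients = c(age = 0.0391, ever_smoker = 0.7917,
                       cancer_history = 1.3388, upper_lobe = 0.7838,
                       diameter = 0.1274, spiculation = 1.0407),
      constant = -6.872,
      diameter_range_mm = c(4, 30),
      exclusions = "prior_cancer"
    ),
    va = nodule_model(
      "va",
      coefficients = c(age = 0.0779, ever_smoker = 2.061,
                       quit_years = 0.0567, diameter = 0.112),
      constant = -8.404,
      diameter_range_mm = c(7, 30)
    ),
    pkuph = nodule_model(
      "pkuph",
      coefficients = c(age = 0.07, family_history_cancer = 1.267,
                       diameter = 0.0676, spiculation = 0.736,
                       smooth_border = -1.408, calcification = -1.615),
      constant = -4.496,
      diameter_range_mm = c(9, 28),
      exclusions = "prior_cancer"
    ),
    brock = nodule_model(
      "brock",
      coefficients = c(sex_female = 0.6467, upper_lobe = 0.6092,
                       diameter = -5.5537, spiculation = 0.9309),
      constant = -6.6144,
      diameter_transform = "brock_power",
      diameter_range_mm = c(1, 86)
    )
  )
  registry[names]
}

# resolve a model given by name or object; used throughout the package
as_nodule_model <- function(model) {
  if (inherits(model, "nodule_model")) return(model)
  if (is.character(model) && length(model) == 1L) {
    if (!model %in% c("mayo", "va", "pkuph", "brock")) {
      rlang::abort(paste0("Unknown model name: '", model, "'."))
    }
    return(nodule_models(model)[[1L]])
  }
  rlang::abort("`model` must be a nodule_model or one of \"mayo\", \"va\", \"pkuph\", \"brock\".")
}

as_model_list <- function(models) {
  if (inherits(models, "nodule_model")) models <- list(models)
  models <- lapply(models, as_nodule_model)
  names(models) <- vapply(models, `[[`, character(1), "name")
  models
}

#' Brock diameter transform
#'
#' The Brock model enters nodule size through
#' `(diameter_mm / 10)^-0.5 - 1.5811`, a decreasing function of diameter that
#' is 0 near 4 mm and negative for larger nodules. Paired with the negative
#' diameter coefficient, the malignancy probability still increases with
#' diameter.
#'
#' @param diameter_mm Nodule diameter in millimetres; must be positive.
#' @return The transformed diameter (dimensionless), same length as input.
#' @examples
#' brock_diameter_transform(10) # -0.5811
#' @export
brock_diameter_transform <- function(diameter_mm) {
  if (!is.numeric(diameter_mm) || any(!is.finite(diameter_mm)) ||
      any(diameter_mm <= 0)) {
    rlang::abort("`diameter_mm` must be positive and finite.")
  }
  (diameter_mm / 10)^(-0.5) - 1.5811
}

# columns a model needs on the cohort, with the diameter alias resolved
model_required_columns <- function(model) {
  nm <- names(model$coefficients)
  replace(nm, nm == "diameter", "diameter_mm")
}

check_model_columns <- function(data, model, call = rlang::caller_env()) {
  required <- model_required_columns(model)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("Cohort is missing column(s) required by the ", model$name,
             " model: ", paste(missing_cols, collapse = ", "), "."),
      call = call
    )
  }
  invisible(required)
}

#' Linear predictor of a malignancy model
#'
#' Computes `x = constant + sum(coefficient_i * covariate_i)` for each row of
#' a cohort, applying the model's diameter transform to `diameter_mm` first.
#' Missing values in a required covariate are an error: the reference
#' behaviour for incomplete records is exclusion, never silent imputation
#' (use [read_cohort()] to exclude such rows up front, or [score_cohort()]
#' which collects per-row failures).
#'
#' @param data Cohort data frame; one row per patient with the covariate
#'   columns the model requires (see [cohort_columns()]).
#' @param model A [nodule_model], or a registry name.
#' @return Numeric vector of linear predictors, one per row.
#' @export
linear_predictor <- function(data, model) {
  model <- as_nodule_model(model)
  check_model_columns(data, model)
  x <- rep_len(model$constant, nrow(data))
  for (term in names(model$coefficients)) {
    col <- if (term == "diameter") "diameter_mm" else term
    v <- data[[col]]
    if (anyNA(v)) {
      bad <- which(is.na(v))
      rlang::abort(paste0(
        "Missing value in `", col, "` (required by the ", model$name,
        " model) for row(s) ", paste(utils::head(bad, 5), collapse = ", "),
        if (length(bad) > 5) ", ..." else "", "."
      ))
    }
    if (term == "diameter" && model$diameter_transform == "brock_power") {
      v <- brock_diameter_transform(v)
    }
    x <- x + model$coefficients[[term]] * v
  }
  x
}

#' Applicability warnings for a model on a patient
#'
#' Checks each patient against the model's published applicability rules:
#' the diameter range the model was developed for, and (for the Mayo and
#' PKUPH models) the exclusion of patients with a prior malignancy within
#' five years. Warnings are advisory: scoring proceeds regardless, mirroring
#' validation practice where every nodule is scored by every model.
#'
#' @inheritParams linear_predictor
#' @return A list of character vectors, one per row; empty when the model is
#'   fully applicable.
#' @export
check_applicability <- function(data, model) {
  model <- as_nodule_model(model)
  if (!"diameter_mm" %in% names(data)) {
    rlang::abort("Cohort must contain `diameter_mm` for applicability checks.")
  }
  n <- nrow(data)
  warnings <- rep(list(character()), n)
  d <- data$diameter_mm
  rng <- model$diameter_range_mm
  range_lab <- paste0("(", rng[1], "-", rng[2], " mm)")
  below <- !is.na(d) & d < rng[1]
  above <- !is.na(d) & d > rng[2]
  lab <- toupper(model$name)
  for (i in which(below)) {
    warnings[[i]] <- c(warnings[[i]],
                       paste("below", lab, "applicability range", range_lab))
  }
  for (i in which(above)) {
    warnings[[i]] <- c(warnings[[i]],
                       paste("above", lab, "applicability range", range_lab))
  }
  if ("prior_cancer" %in% model$exclusions) {
    prior <- rep(FALSE, n)
    for (col in c("cancer_history", "lung_cancer_history")) {
      if (col %in% names(data)) {
        prior <- prior | (!is.na(data[[col]]) & data[[col]] == 1)
      }
    }
    for (i in which(prior)) {
      warnings[[i]] <- c(warnings[[i]],
                         paste(lab, "model excludes patients with a prior",
                               "malignancy within 5 years"))
    }
  }
  warnings
}

#' Predicted malignancy probability
#'
#' Applies the logistic link `p = exp(x) / (1 + exp(x))` to the model's
#' linear predictor and attaches applicability warnings.
#'
#' @inheritParams linear_predictor
#' @return A tibble with one row per patient: `id` (if present), `model`,
#'   `linear_predictor`, `probability`, `applicable` and a `warnings`
#'   list-column. `applicable` is `FALSE` exactly when `warnings` is
#'   non-empty.
#' @examples
#' # worked example: man, lower lobe, no spiculation, 10 mm nodule
#' p <- tibble::tibble(id = "ex", sex_female = 0, upper_lobe = 0,
#'                     spiculation = 0, diameter_mm = 10)
#' predict_probability(p, "brock") # x ~ -3.387, probability ~ 0.0327
#' @export
predict_probability <- function(data, model) {
  model <- as_nodule_model(model)
  x <- linear_predictor(data, model)
  warns <- check_applicability(data, model)
  out <- tibble::tibble(
    model = model$name,
    linear_predictor = x,
    probability = stats::plogis(x),
    applicable = lengths(warns) == 0L,
    warnings = warns
  )
  if ("id" %in% names(data)) {
    out <- tibble::add_column(out, id = as.character(data$id), .before = 1L)
  }
  out
}

#' Score a cohort with a set of models
#'
#' Batch application of one or more malignancy models to a cohort table.
#' Rows that cannot be scored by a model (a missing required covariate) do
#' not abort the batch: they get `NA` predictions and the failure is recorded
#' in the `failures` attribute of the result.
#'
#' @param data Cohort data frame, one row per patient, with an `id` column.
#' @param models A list of [nodule_model] objects or registry names; defaults
#'   to all four published models.
#' @return A tibble with `nrow(data) * length(models)` rows and columns
#'   `id`, `model`, `linear_predictor`, `probability`, `applicable`,
#'   `warnings` (list-column), plus an attribute `"failures"` (tibble of
#'   `id`, `model`, `reason`). Row order: patients in input order within each
#'   model, models in the order given.
#' @export
score_cohort <- function(data, models = nodule_models()) {
  models <- as_model_list(models)
  if (nrow(data) == 0L) rlang::abort("Cohort is empty; nothing to score.")
  if (!"id" %in% names(data)) {
    data <- tibble::add_column(data, id = as.character(seq_len(nrow(data))),
                               .before = 1L)
  }
  failures <- list()
  scored <- purrr::map(models, function(model) {
    check_model_columns(data, model)
    required <- model_required_columns(model)
    incomplete <- rowSums(is.na(data[required])) > 0
    out <- tibble::tibble(
      id = as.character(data$id),
      model = model$name,
      linear_predictor = NA_real_,
      probability = NA_real_,
      applicable = NA,
      warnings = rep(list(character()), nrow(data))
    )
    if (any(!incomplete)) {
      ok <- predict_probability(data[!incomplete, , drop = FALSE], model)
      out$linear_predictor[!incomplete] <- ok$linear_predictor
      out$probability[!incomplete] <- ok$probability
      out$applicable[!incomplete] <- ok$applicable
      out$warnings[!incomplete] <- ok$warnings
    }
    if (any(incomplete)) {
      bad_cols <- vapply(which(incomplete), function(i) {
        paste(required[is.na(unlist(data[i, required]))], collapse = ",")
      }, character(1))
      failures[[model$name]] <<- tibble::tibble(
        id = as.character(data$id[incomplete]),
        model = model$name,
        reason = paste0("missing covariate: ", bad_cols)
      )
    }
    out
  })
  result <- dplyr::bind_rows(scored)
  attr(result, "failures") <- dplyr::bind_rows(failures)
  result
}
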