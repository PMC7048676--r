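#' Cohort column dictionary
#'
#' The canonical column set of a cohort CSV, in order. Binary fields are
#' strictly 0/1 (1 = presence; `sex_female` 1 = female), missing values are
#' empty cells, the decimal separator is ".", and files are UTF-8 with a
#' header row.
#'
#' @return A tibble with `column`, `type` and `description`.
#' @export
cohort_dictionary <- function() {
  tibble::tribble(
    ~column, ~type, ~description,
    "id", "character", "Opaque patient identifier (unique)",
    "age", "integer", "Age in years, >= 0",
    "sex_female", "binary", "1 = female, 0 = male",
    "ever_smoker", "binary", "Ever smoked (current or former)",
    "quit_years", "numeric", "Years since quitting; 0 for never/current smokers",
    "cancer_history", "binary", "Prior extrathoracic cancer",
    "family_history_cancer", "binary", "Family history of cancer",
    "lung_cancer_history", "binary", "Personal history of lung cancer",
    "diameter_mm", "numeric", "Nodule diameter in mm, > 0",
    "upper_lobe", "binary", "Nodule in an upper lobe",
    "spiculation", "binary", "Spiculated margin on CT",
    "smooth_border", "binary", "Smooth nodule border on CT",
    "clear_border", "binary", "Clear (well-defined) border on CT",
    "calcification", "binary", "Calcification present",
    "lobulation", "binary", "Lobulated margin",
    "ground_glass", "binary", "Ground-glass change",
    "air_bronchogram", "binary", "Air bronchogram sign",
    "outcome_malignant", "binary", "Pathological outcome; may be missing",
    "histology", "enum", "adenocarcinoma | squamous | other_malignant | benign; may be missing",
    "stage", "enum", "I | II | III | IV; present only for malignant cases"
  )
}

#' @rdname cohort_dictionary
#' @export
cohort_columns <- function() cohort_dictionary()$column

cohort_col_types <- function() {
  readr::cols(
    id = readr::col_character(),
    age = readr::col_double(),
    sex_female = readr::col_double(),
    ever_smoker = readr::col_double(),
    quit_years = readr::col_double(),
    cancer_history = readr::col_double(),
    family_history_cancer = readr::col_double(),
    lung_cancer_history = readr::col_double(),
    diameter_mm = readr::col_double(),
    upper_lobe = readr::col_double(),
    spiculation = readr::col_double(),
    smooth_border = readr::col_double(),
    clear_border = readr::col_double(),
    calcification = readr::col_double(),
    lobulation = readr::col_double(),
    ground_glass = readr::col_double(),
    air_bronchogram = readr::col_double(),
    outcome_malignant = readr::col_double(),
    histology = readr::col_character(),
    stage = readr::col_character()
  )
}

binary_columns <- function() {
  dict <- cohort_dictionary()
  dict$column[dict$type == "binary"]
}

#' Read and validate a cohort CSV
#'
#' Reads a cohort file in the dialect of [cohort_dictionary()], validating
#' every row: required fields present, `diameter_mm > 0`, `age >= 0`,
#' `quit_years >= 0`, binary fields in 0/1, enum fields in their vocabulary,
#' and consistency between `histology = "benign"` and
#' `outcome_malignant = 0`. Invalid rows are excluded with a per-field tally
#' (the reference behaviour for incomplete clinical records), or abort the
#' run when `strict = TRUE`.
#'
#' @param path Path to the CSV.
#' @param strict Abort on the first invalid row instead of excluding it.
#' @return A list with `cohort` (tibble of valid rows) and `report` (a
#'   `validation_report`: `n_read`, `n_valid`, `n_excluded`,
#'   `exclusion_reasons` named integer vector).
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) rlang::abort(paste0("File not found: ", path))
  raw <- tryCatch(
    readr::read_csv(path, col_types = cohort_col_types(),
                    na = c("", "NA"), progress = FALSE),
    error = function(e) rlang::abort(paste0("Cannot read ", path, ": ",
                                            conditionMessage(e)))
  )
  if (nrow(raw) == 0L) rlang::abort(paste0("Empty cohort file: ", path))
  unknown <- setdiff(names(raw), cohort_columns())
  if (length(unknown)) {
    rlang::abort(paste0("Unknown column(s) in ", path, ": ",
                        paste(unknown, collapse = ", "), "."))
  }
  missing_cols <- setdiff(setdiff(cohort_columns(),
                                  c("outcome_malignant", "histology", "stage")),
                          names(raw))
  if (length(missing_cols)) {
    rlang::abort(paste0("Cohort header is missing column(s): ",
                        paste(missing_cols, collapse = ", "), "."))
  }
  for (opt in c("outcome_malignant", "histology", "stage")) {
    if (!opt %in% names(raw)) raw[[opt]] <- NA
  }
  validate_cohort(raw, strict = strict, source = path)
}

# row-wise validation shared by read_cohort and validate_cohort callers
validate_cohort <- function(raw, strict = FALSE, source = "cohort") {
  reason <- rep(NA_character_, nrow(raw))
  flag <- function(bad, field) {
    bad <- bad & is.na(reason)
    reason[bad] <<- field
  }
  required_num <- c("age", "quit_years", "diameter_mm")
  for (f in required_num) flag(is.na(raw[[f]]), f)
  flag(!is.na(raw$diameter_mm) & raw$diameter_mm <= 0, "diameter_mm")
  flag(!is.na(raw$age) & raw$age < 0, "age")
  flag(!is.na(raw$quit_years) & raw$quit_years < 0, "quit_years")
  for (f in binary_columns()) {
    v <- raw[[f]]
    if (f == "outcome_malignant") {
      flag(!is.na(v) & !v %in% c(0, 1), f)
    } else {
      flag(is.na(v) | !v %in% c(0, 1), f)
    }
  }
  flag(is.na(raw$id) | !nzchar(raw$id), "id")
  hist_ok <- is.na(raw$histology) |
    raw$histology %in% c("adenocarcinoma", "squamous", "other_malignant",
                         "benign")
  flag(!hist_ok, "histology")
  stage_ok <- is.na(raw$stage) | raw$stage %in% c("I", "II", "III", "IV")
  flag(!stage_ok, "stage")
  both <- !is.na(raw$histology) & !is.na(raw$outcome_malignant)
  flag(both & (raw$histology == "benign") != (raw$outcome_malignant == 0),
       "histology")
  flag(!is.na(raw$stage) & !is.na(raw$outcome_malignant) &
         raw$outcome_malignant == 0, "stage")

  bad <- !is.na(reason)
  if (strict && any(bad)) {
    first <- which(bad)[1]
    rlang::abort(paste0("Invalid row ", first, " in ", source,
                        " (field: ", reason[first], ") and strict = TRUE."))
  }
  reasons <- table(reason[bad])
  report <- structure(
    list(n_read = nrow(raw), n_valid = sum(!bad), n_excluded = sum(bad),
         exclusion_reasons = stats::setNames(as.integer(reasons),
                                             names(reasons))),
    class = "validation_report"
  )
  cohort <- raw[!bad, , drop = FALSE]
  cohort <- cohort[cohort_columns()]
  list(cohort = tibble::as_tibble(cohort), report = report)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> read", x$n_read, "rows:", x$n_valid, "valid,",
      x$n_excluded, "excluded\n")
  if (length(x$exclusion_reasons)) {
    for (f in names(x$exclusion_reasons)) {
      cat("  ", f, ": ", x$exclusion_reasons[[f]], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Write a cohort or prediction table to CSV
#'
#' `write_cohort()` writes the canonical cohort dialect; round-tripping a
#' valid cohort through `write_cohort()` and [read_cohort()] is lossless.
#' `write_predictions()` writes one row per patient x model with the
#' applicability warnings semicolon-joined.
#'
#' @param cohort Cohort tibble.
#' @param predictions Prediction tibble from [score_cohort()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- cohort[intersect(cohort_columns(), names(cohort))]
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_predictions <- function(predictions, path) {
  out <- predictions |>
    dplyr::mutate(warnings = vapply(.data$warnings, paste,
                                    character(1), collapse = "; "))
  readr::write_csv(out, path, na = "")
  invisible(path)
}
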