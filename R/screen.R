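#' Univariate screening of candidate predictors
#'
#' For each characteristic, compares its distribution across the outcome
#' groups (benign vs malignant) with a one-way analysis of variance. The
#' homogeneity-of-variance precondition is checked with Levene's test
#' (median-centred, alpha 0.05); when it fails, Welch's unequal-variance
#' t-test replaces the ANOVA p-value for two-group contrasts. Alongside the
#' test, the characteristic's overall mean, SD, SE and the normal-theory 95%
#' CI of the mean are reported, which for a 0/1 characteristic is its
#' prevalence. No multiplicity correction is applied; raw p-values are
#' reported at the conventional 0.05 level.
#'
#' @param cohort Cohort data frame with `outcome_malignant`.
#' @param characteristics Character vector of column names to screen;
#'   defaults to every numeric covariate column present.
#' @param conf_level Confidence level for the mean CI.
#' @param levene_alpha Significance level of the Levene gate.
#' @return A tibble with one row per characteristic: `characteristic`, `n`,
#'   `mean`, `sd`, `se`, `ci_lower`, `ci_upper`, `statistic`, `test`
#'   (`"anova"` or `"welch_t"`), `p`, `note` (`NA` or `"constant"`).
#' @export
univariate_screen <- function(cohort,
                              characteristics = NULL,
                              conf_level = 0.95,
                              levene_alpha = 0.05) {
  if (!"outcome_malignant" %in% names(cohort) ||
      anyNA(cohort$outcome_malignant)) {
    rlang::abort("`outcome_malignant` must be present and complete.")
  }
  if (is.null(characteristics)) {
    candidates <- c("sex_female", "age", "upper_lobe",
                    "family_history_cancer", "ever_smoker", "quit_years",
                    "diameter_mm", "spiculation", "calcification",
                    "ground_glass", "air_bronchogram", "lung_cancer_history",
                    "cancer_history", "clear_border", "smooth_border",
                    "lobulation")
    characteristics <- intersect(candidates, names(cohort))
  }
  missing_cols <- setdiff(characteristics, names(cohort))
  if (length(missing_cols)) {
    rlang::abort(paste0("Unknown characteristic(s): ",
                        paste(missing_cols, collapse = ", "), "."))
  }
  group <- factor(cohort$outcome_malignant)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  purrr::map_dfr(characteristics, function(ch) {
    v <- cohort[[ch]]
    ok <- !is.na(v)
    v <- v[ok]
    g <- droplevels(group[ok])
    n <- length(v)
    m <- mean(v)
    s <- stats::sd(v)
    se <- s / sqrt(n)
    row <- tibble::tibble(
      characteristic = ch, n = n, mean = m, sd = s, se = se,
      ci_lower = m - z * se, ci_upper = m + z * se,
      statistic = NA_real_, test = NA_character_, p = NA_real_,
      note = NA_character_
    )
    if (s == 0 || nlevels(g) < 2L) {
      row$note <- "constant"
      return(row)
    }
    # leveneTest warns on degenerate spreads; an NA p falls through to ANOVA
    lev_p <- suppressWarnings(car::leveneTest(v ~ g)[1, "Pr(>F)"])
    if (!is.na(lev_p) && lev_p < levene_alpha && nlevels(g) == 2L) {
      tt <- stats::t.test(v ~ g) # Welch
      row$statistic <- unname(tt$statistic)
      row$test <- "welch_t"
      row$p <- tt$p.value
    } else {
      a <- stats::anova(stats::aov(v ~ g))
      row$statistic <- a[["F value"]][1]
      row$test <- "anova"
      row$p <- a[["Pr(>F)"]][1]
    }
    row
  })
}
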