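# Independent oracle: AUC by explicit double loop over all case-control
# pairs (concordant = 1, tied = 1/2). Never shares code with compute_auc().
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# a single-patient tibble with all binary covariates absent (0) by default
make_patient <- function(id = "p1", age = 0, sex_female = 0, ever_smoker = 0,
                         quit_years = 0, cancer_history = 0,
                         family_history_cancer = 0, lung_cancer_history = 0,
                         diameter_mm = 10, upper_lobe = 0, spiculation = 0,
                         smooth_border = 0, clear_border = 0,
                         calcification = 0, lobulation = 0, ground_glass = 0,
                         air_bronchogram = 0, outcome_malignant = NA,
                         histology = NA_character_, stage = NA_character_) {
  tibble::tibble(
    id = id, age = age, sex_female = sex_female, ever_smoker = ever_smoker,
    quit_years = quit_years, cancer_history = cancer_history,
    family_history_cancer = family_history_cancer,
    lung_cancer_history = lung_cancer_history, diameter_mm = diameter_mm,
    upper_lobe = upper_lobe, spiculation = spiculation,
    smooth_border = smooth_border, clear_border = clear_border,
    calcification = calcification, lobulation = lobulation,
    ground_glass = ground_glass, air_bronchogram = air_bronchogram,
    outcome_malignant = outcome_malignant, histology = histology,
    stage = stage
  )
}

# random score/label instance with ties (scores on a coarse grid half the
# time) for oracle-equivalence checks
random_auc_instance <- function() {
  n <- sample(4:200, 1)
  labels <- integer(n)
  # guarantee both classes
  labels[sample(n, 2)] <- c(0L, 1L)
  labels[-sample(n, 2)] <- stats::rbinom(n - 2, 1, runif(1, 0.2, 0.8))
  n_pos <- sum(labels)
  if (n_pos == 0) labels[sample(n, 1)] <- 1L
  if (n_pos == n) labels[sample(n, 1)] <- 0L
  scores <- if (runif(1) < 0.5) {
    sample(seq(0, 1, by = 0.1), n, replace = TRUE) # heavy ties
  } else {
    stats::rnorm(n)
  }
  list(scores = scores, labels = labels)
}

# 99% two-sided binomial bounds used for cohort-structure checks
binom_bounds99 <- function(n, p) {
  c(stats::qbinom(0.005, n, p), stats::qbinom(0.995, n, p))
}
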