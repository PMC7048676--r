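#' ROC area under the curve with Hanley-McNeil confidence interval
#'
#' Computes the AUC as the pairwise concordance probability: the fraction of
#' case-control pairs in which the case scores higher, with ties counted
#' one half. Equivalently the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`. The 95% confidence interval uses the Hanley-McNeil
#' variance approximation
#' `(A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) / (n_pos n_neg)`
#' with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`, normal quantiles, clamped to
#' `[0, 1]`. A bootstrap percentile interval is available as an alternative.
#'
#' @param scores Numeric vector of scores (higher = more case-like). Any
#'   strictly increasing transform of the scores leaves the AUC unchanged.
#' @param labels Binary vector (0/1 or logical), same length as `scores`;
#'   1 marks cases.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param ci_method `"hanley-mcneil"` (default) or `"bootstrap"`.
#' @param boot_reps Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return An object of class `roc_result`: a list with `auc`, `n_pos`,
#'   `n_neg`, `concordant`, `tied`, `ci_lower`, `ci_upper`, `se`, and
#'   `curve` (a tibble of `fpr`, `tpr` from (0,0) to (1,1)).
#' @examples
#' r <- compute_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))
#' r$auc # 0.75
#' @export
compute_auc <- function(scores, labels, conf_level = 0.95,
                        ci_method = c("hanley-mcneil", "bootstrap"),
                        boot_reps = 2000L) {
  ci_method <- match.arg(ci_method)
  if (is.logical(labels)) labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  if (!all(labels %in% c(0, 1))) {
    rlang::abort("`labels` must be binary (0/1).")
  }
  if (any(!is.finite(scores))) rlang::abort("`scores` must be finite.")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    rlang::abort("AUC undefined: need at least one case and one control.")
  }

  # Mann-Whitney via midranks; tie mass recovered from the score ties table
  r <- rank(scores)
  u <- sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2
  tab <- table(scores, labels)
  tied <- if (ncol(tab) == 2L) sum(tab[, "1"] * tab[, "0"]) else 0
  concordant <- u - 0.5 * tied
  auc <- u / (n_pos * n_neg)

  if (ci_method == "hanley-mcneil") {
    se <- hanley_mcneil_se(auc, n_pos, n_neg)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- c(auc - z * se, auc + z * se)
  } else {
    idx_pos <- which(labels == 1)
    idx_neg <- which(labels == 0)
    boots <- vapply(seq_len(boot_reps), function(i) {
      bp <- sample(idx_pos, n_pos, replace = TRUE)
      bn <- sample(idx_neg, n_neg, replace = TRUE)
      s <- c(scores[bp], scores[bn])
      l <- rep(c(1L, 0L), c(n_pos, n_neg))
      rr <- rank(s)
      (sum(rr[l == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    }, numeric(1))
    se <- stats::sd(boots)
    ci <- unname(stats::quantile(boots, c((1 - conf_level) / 2,
                                          1 - (1 - conf_level) / 2)))
  }
  ci <- pmin(pmax(ci, 0), 1)

  structure(
    list(
      auc = auc, n_pos = n_pos, n_neg = n_neg,
      concordant = concordant, tied = tied,
      se = se, ci_lower = ci[1], ci_upper = ci[2],
      conf_level = conf_level, ci_method = ci_method,
      curve = roc_curve_points(scores, labels)
    ),
    class = "roc_result"
  )
}

hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  sqrt(max(v, 0))
}

# empirical ROC curve: one point per distinct threshold, scores descending
roc_curve_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  keep <- c(diff(s) != 0, TRUE) # last index of each tied block
  tpr <- cumsum(l)[keep] / sum(l)
  fpr <- cumsum(1 - l)[keep] / sum(1 - l)
  tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d%% CI %.4f-%.4f, %s)\n",
              x$auc, round(100 * x$conf_level), x$ci_lower, x$ci_upper,
              x$ci_method))
  cat(sprintf("  cases: %d, controls: %d, concordant pairs: %.1f, tied: %.1f\n",
              x$n_pos, x$n_neg, x$concordant, x$tied))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method
tidy.roc_result <- function(x, ...) x$curve

#' @exportS3Method
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, se = x$se,
    ci_lower = x$ci_lower, ci_upper = x$ci_upper,
    n_pos = x$n_pos, n_neg = x$n_neg,
    concordant = x$concordant, tied = x$tied
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object A `roc_result` from [compute_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate (1 - specificity)",
      y = "True-positive rate (sensitivity)",
      title = sprintf("ROC curve, AUC = %.3f (95%% CI %.3f-%.3f)",
                      object$auc, object$ci_lower, object$ci_upper)
    ) +
    ggplot2::theme_minimal()
}
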