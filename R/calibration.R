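#' Calibration curve by quantile bins
#'
#' Bins predicted probabilities into (approximately) equal-count quantile
#' bins and compares the mean predicted probability in each bin with the
#' observed event fraction. A well-calibrated model tracks the identity
#' line. Quantile bins are used rather than equal-width bins so that every
#' bin stays populated even when predictions cluster, as they do at high
#' prevalence; bins whose quantile boundaries coincide (heavily tied
#' predictions) are merged, so the effective number of bins can be smaller
#' than requested.
#'
#' @param probabilities Predicted probabilities in (0, 1).
#' @param outcomes Binary outcome vector (0/1 or logical), same length.
#' @param n_bins Number of quantile bins requested (default 10, deciles);
#'   must be at least 2 and at most the number of observations.
#' @return An object of class `calibration_result` with a `bins` tibble
#'   (`bin`, `n`, `mean_predicted`, `observed_fraction`) and `n_bins`
#'   (effective bin count).
#' @export
calibration_curve <- function(probabilities, outcomes, n_bins = 10L) {
  if (is.logical(outcomes)) outcomes <- as.integer(outcomes)
  stopifnot(length(probabilities) == length(outcomes))
  keep <- !is.na(probabilities) & !is.na(outcomes)
  probabilities <- probabilities[keep]
  outcomes <- outcomes[keep]
  if (!all(outcomes %in% c(0, 1))) {
    rlang::abort("`outcomes` must be binary (0/1).")
  }
  if (any(probabilities <= 0 | probabilities >= 1)) {
    rlang::abort("`probabilities` must lie strictly in (0, 1).")
  }
  if (n_bins < 2L) rlang::abort("`n_bins` must be at least 2.")
  if (n_bins > length(probabilities)) {
    rlang::abort("`n_bins` exceeds the number of observations.")
  }
  breaks <- unique(stats::quantile(probabilities,
                                   probs = seq(0, 1, length.out = n_bins + 1),
                                   type = 7))
  if (length(breaks) < 2L) {
    # all predictions identical: a single bin covering everything
    bin <- factor(rep(1L, length(probabilities)))
  } else {
    bin <- cut(probabilities, breaks = breaks, include.lowest = TRUE)
  }
  bins <- tibble::tibble(p = probabilities, y = outcomes, bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_predicted = mean(.data$p),
      observed_fraction = mean(.data$y),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mean_predicted) |>
    dplyr::mutate(bin = dplyr::row_number()) |>
    dplyr::select("bin", "n", "mean_predicted", "observed_fraction")
  structure(list(bins = bins, n_bins = nrow(bins),
                 n = length(probabilities)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>", x$n, "observations in", x$n_bins, "bins\n")
  print(x$bins, n = Inf)
  invisible(x)
}

#' @exportS3Method
tidy.calibration_result <- function(x, ...) x$bins

#' @exportS3Method
glance.calibration_result <- function(x, ...) {
  dev <- abs(x$bins$observed_fraction - x$bins$mean_predicted)
  tibble::tibble(
    n = x$n, n_bins = x$n_bins,
    max_abs_deviation = max(dev),
    mean_abs_deviation = stats::weighted.mean(dev, x$bins$n)
  )
}

#' Plot a calibration curve
#'
#' @param object A `calibration_result` from [calibration_curve()].
#' @param ... Unused.
#' @return A ggplot of observed event fraction against mean predicted
#'   probability, with the identity line for reference.
#' @export
autoplot.calibration_result <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$mean_predicted,
                               y = .data$observed_fraction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability",
                  y = "Observed event fraction", size = "Bin size") +
    ggplot2::theme_minimal()
}
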