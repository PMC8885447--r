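#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text geom_point
#'   geom_line geom_hline scale_fill_gradient2 labs theme_minimal
#'   facet_wrap stat_summary
#' @export
ggplot2::autoplot

#' Heatmap of an HSA synergy matrix
#'
#' Dose axes are labelled in uM; tile numerals are the mean synergy
#' scores across replicates (positive = combination effect beyond the
#' best monotherapy).
#'
#' @param object a [hsa_synergy()] matrix.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.synergy_matrix <- function(object, ...) {
  object$fa <- factor(object$dose_a, levels = sort(unique(object$dose_a)))
  object$fb <- factor(object$dose_b, levels = sort(unique(object$dose_b)))
  ggplot(object, aes(x = .data$fb, y = .data$fa, fill = .data$score)) +
    geom_tile(color = "grey30") +
    geom_text(aes(label = sprintf("%.0f", .data$score)), size = 3) +
    scale_fill_gradient2(low = "#b2182b", mid = "white", high = "#2166ac",
                         midpoint = 0, name = "HSA\nscore") +
    labs(x = "dose B (µM)", y = "dose A (µM)") +
    theme_minimal()
}

#' Dose-response curve with its 4PL fit
#'
#' @param object a [fit_dose_response()] fit.
#' @param n_curve points along the fitted curve.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.dose_response_fit <- function(object, n_curve = 200, ...) {
  lx <- seq(min(object$data$log10_conc), max(object$data$log10_conc),
            length.out = n_curve)
  curve <- tibble(log10_conc = lx, response = predict_4pl(object, lx))
  ggplot(object$data, aes(x = .data$log10_conc, y = .data$response)) +
    geom_point() +
    geom_line(data = curve, color = "#2166ac") +
    labs(x = "log10 concentration (µM)", y = "normalised response",
         subtitle = sprintf("IC50 = %.3g µM, hill = %.2f",
                            object$ic50, object$hill)) +
    theme_minimal()
}

#' Accuracy-vs-training-size curve from the review protocol
#'
#' @param object a [review_protocol()] result.
#' @param ... unused.
#' @return A ggplot of mean per-bin accuracy against training-set size,
#'   with the protocol's target accuracy as a dashed line.
#' @export
autoplot.review_protocol <- function(object, ...) {
  ggplot(object, aes(x = .data$train_size, y = .data$accuracy,
                     color = .data$bin)) +
    stat_summary(fun = mean, geom = "line") +
    stat_summary(fun = mean, geom = "point") +
    geom_hline(yintercept = attr(object, "target"), linetype = "dashed") +
    labs(x = "labelled training cells", y = "review accuracy (per bin)") +
    theme_minimal()
}

#' Relative-survival curve
#'
#' @param object a [relative_survival()] series.
#' @param ... unused.
#' @return A ggplot of relative survival against time.
#' @export
autoplot.survival_series <- function(object, ...) {
  ggplot(object, aes(x = .data$time_h, y = .data$relative)) +
    geom_line() + geom_point() +
    labs(x = "time (h)", y = "relative survival") +
    theme_minimal()
}
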