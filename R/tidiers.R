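#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted inclusion classifier
#'
#' One row per feature with its random-forest importance (mean decrease
#' in Gini impurity).
#'
#' @param x an `inclusion_classifier`.
#' @param ... unused.
#' @return Tibble `feature`, `importance`, sorted descending.
#' @export
tidy.inclusion_classifier <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble(feature = rownames(imp), importance = unname(imp[, 1])) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname tidy.inclusion_classifier
#' @return `glance`: one-row tibble with `n_trees`, `n_features`,
#'   `oob_accuracy`, `oob_accuracy_inclusion`, `oob_accuracy_no_inclusion`.
#' @export
glance.inclusion_classifier <- function(x, ...) {
  tibble(n_trees = x$n_trees, n_features = length(x$feature_names),
         oob_accuracy = x$oob_accuracy,
         oob_accuracy_inclusion = unname(x$oob_class_accuracy["inclusion"]),
         oob_accuracy_no_inclusion = unname(x$oob_class_accuracy["no_inclusion"]))
}

#' Tidy a 4PL dose-response fit
#'
#' @param x a `dose_response_fit`.
#' @param ... unused.
#' @return One row per parameter (`top`, `bottom`, `log10_ic50`, `ic50`,
#'   `hill`) with its estimate.
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble(term = c("top", "bottom", "log10_ic50", "ic50", "hill"),
         estimate = c(x$top, x$bottom, x$log10_ic50, x$ic50, x$hill))
}

#' @rdname tidy.dose_response_fit
#' @return `glance`: one-row tibble with `ic50`, `hill`, `sigma`,
#'   `converged`, `extrapolated`, `n`.
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble(ic50 = x$ic50, hill = x$hill, sigma = x$sigma,
         converged = x$converged, extrapolated = x$extrapolated,
         n = nrow(x$data))
}
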