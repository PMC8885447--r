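#' Relative survival of a GFP-positive count series
#'
#' Counts are first normalised to their own starting count, then divided
#' by the matched control series' normalised value at the same timepoint
#' (e.g. a mutant-transfected arm relative to the wildtype-transfected
#' arm under the same treatment). The first timepoint is exactly 1.
#'
#' @param data tibble with `time_h` and `count` for the arm of interest.
#' @param control tibble with `time_h` and `count` for the control arm;
#'   timepoints must match `data` exactly.
#' @return A `survival_series` tibble: `time_h`, `count`, `normalized`,
#'   `control_normalized`, `relative`.
#' @export
relative_survival <- function(data, control) {
  for (d in list(data, control))
    if (!all(c("time_h", "count") %in% names(d)))
      abort("series need `time_h` and `count` columns")
  data <- dplyr::arrange(as_tibble(data), .data$time_h)
  control <- dplyr::arrange(as_tibble(control), .data$time_h)
  if (!isTRUE(all.equal(data$time_h, control$time_h)))
    abort("series and control timepoints differ")
  if (is.unsorted(data$time_h, strictly = TRUE))
    abort("timepoints must be strictly increasing")
  if (data$count[1] <= 0 || control$count[1] <= 0)
    abort("starting counts must be > 0")
  out <- tibble(time_h = data$time_h, count = data$count,
                normalized = data$count / data$count[1],
                control_normalized = control$count / control$count[1])
  out$relative <- out$normalized / out$control_normalized
  class(out) <- unique(c("survival_series", class(out)))
  out
}

#' Trapezoid area under the relative-survival curve
#'
#' @param series a [relative_survival()] tibble (or any tibble with
#'   `time_h` and `relative`).
#' @return Area in relative-survival x hours.
#' @export
survival_auc <- function(series) {
  if (nrow(series) < 2) abort("need at least 2 timepoints for an AUC")
  pracma::trapz(series$time_h, series$relative)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL ("log(inhibitor) vs. normalised response, variable
#' slope") on log10 concentration:
#' `y = bottom + (top - bottom) / (1 + 10^(hill * (log10(c) - log10(IC50))))`.
#' Zero-dose points enter the log axis at `(min nonzero dose) /
#' zero_dose_divisor`. Starting values come from the data quantiles; a
#' non-converging fit is returned with `converged = FALSE` and a warning
#' rather than an error.
#'
#' @param data tibble with columns `conc` (uM) and `response`
#'   (normalised, e.g. % of untreated).
#' @param zero_dose_divisor zero doses are placed at
#'   `min(conc[conc > 0]) / zero_dose_divisor` on the log axis.
#' @return A `dose_response_fit`: parameters (`top`, `bottom`,
#'   `log10_ic50`, `ic50`, `hill`), `sigma` (residual sd), `converged`,
#'   `extrapolated` (IC50 outside the dosed range), the model frame and
#'   the underlying `nlsLM` fit.
#' @export
fit_dose_response <- function(data, zero_dose_divisor = 100) {
  if (!all(c("conc", "response") %in% names(data)))
    abort("data needs `conc` and `response` columns")
  if (length(unique(data$conc)) < 5)
    abort("need at least 5 distinct concentrations")
  conc <- data$conc; y <- data$response
  nz <- conc[conc > 0]
  lx <- log10(ifelse(conc > 0, conc, min(nz) / zero_dose_divisor))
  top0 <- max(y); bot0 <- min(y)
  mid <- (top0 + bot0) / 2
  l50 <- lx[which.min(abs(y - mid))]
  hill0 <- if (stats::cor(lx, y) < 0) 1 else -1
  df <- data.frame(lx = lx, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hill * (lx - l50))),
      data = df,
      start = list(top = top0, bottom = bot0, l50 = l50, hill = hill0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warn(sprintf("4PL fit failed to converge: %s", conditionMessage(fit)))
    pars <- c(top = top0, bottom = bot0, l50 = l50, hill = hill0)
    converged <- FALSE
    sigma <- NA_real_
  } else {
    pars <- stats::coef(fit)
    converged <- fit$convInfo$isConv
    if (!converged) warn("4PL fit did not converge; parameters are the last iterate")
    sigma <- sqrt(sum(stats::residuals(fit)^2) /
                    max(length(y) - 4, 1))
  }
  ic50 <- 10^pars[["l50"]]
  structure(list(
    top = pars[["top"]], bottom = pars[["bottom"]],
    log10_ic50 = pars[["l50"]], ic50 = ic50, hill = pars[["hill"]],
    sigma = sigma, converged = converged,
    extrapolated = ic50 < min(nz) || ic50 > max(nz),
    data = tibble(conc = conc, log10_conc = lx, response = y),
    fit = if (inherits(fit, "error")) NULL else fit),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> IC50 %.4g uM (hill %.2f, top %.1f, bottom %.1f)%s%s\n",
    x$ic50, x$hill, x$top, x$bottom,
    if (x$converged) "" else " [NOT CONVERGED]",
    if (x$extrapolated) " [IC50 extrapolated]" else ""))
  invisible(x)
}

predict_4pl <- function(x, lconc) {
  x$bottom + (x$top - x$bottom) /
    (1 + 10^(x$hill * (lconc - x$log10_ic50)))
}
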