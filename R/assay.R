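#' Linear calibration curve for colorimetric assays
#'
#' Represents a standard curve `absorbance = slope * concentration +
#' intercept` used to convert sample absorbances into equivalents of a
#' reference analyte (e.g. mg gallic-acid equivalents per g for total
#' phenolics, mg catechin equivalents per g for total flavonoids).
#'
#' @param slope,intercept Regression coefficients (slope != 0).
#' @param r2 Coefficient of determination of the standard fit (metadata).
#' @param analyte,units Labels.
#' @return An object of class `calibration_curve`.
#' @examples
#' tpc <- calibration_curve(0.0512, 0.0018, r2 = 0.9835, analyte = "gallic acid")
#' to_equivalents(tpc, 0.0530) # 1.000
#' @export
calibration_curve <- function(slope, intercept, r2 = NA_real_,
                              analyte = "", units = "mg equivalent/g") {
  if (slope == 0) stop("`slope` must be non-zero.", call. = FALSE)
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 analyte = analyte, units = units),
            class = "calibration_curve")
}

#' Fit a calibration curve from standards
#'
#' @param data Data frame with `concentration` and `absorbance` columns.
#' @inheritParams calibration_curve
#' @return A [calibration_curve()].
#' @export
fit_calibration <- function(data, analyte = "", units = "mg equivalent/g") {
  m <- stats::lm(absorbance ~ concentration, data = data)
  r2 <- suppressWarnings(summary(m)$r.squared) # warns on noise-free standards
  calibration_curve(unname(stats::coef(m)[2]), unname(stats::coef(m)[1]),
                    r2 = r2, analyte = analyte, units = units)
}

#' Convert absorbance to analyte equivalents (and back)
#'
#' `to_equivalents()` inverts the standard curve, `x = (y - intercept) /
#' slope`; `from_equivalents()` applies it forward. The two are exact
#' inverses.
#'
#' @param curve A [calibration_curve()].
#' @param absorbance,concentration Numeric vectors.
#' @return Numeric vector.
#' @export
to_equivalents <- function(curve, absorbance) {
  (absorbance - curve$intercept) / curve$slope
}

#' @rdname to_equivalents
#' @export
from_equivalents <- function(curve, concentration) {
  curve$slope * concentration + curve$intercept
}

#' Percent inhibition from paired absorbances
#'
#' `100 * (1 - abs_sample / abs_control)`. Values below 0 (pro-oxidant /
#' activating behaviour) are reported as-is, never clipped.
#'
#' @param abs_control Control absorbance (> 0).
#' @param abs_sample Sample absorbance.
#' @return Percent inhibition, vectorized.
#' @export
percent_inhibition <- function(abs_control, abs_sample) {
  if (any(abs_control <= 0)) stop("`abs_control` must be positive.", call. = FALSE)
  100 * (1 - abs_sample / abs_control)
}

four_pl_curve <- function(dose, ic50, hill, bottom, top) {
  bottom + (top - bottom) / (1 + (ic50 / dose)^hill)
}

#' Estimate the half-maximal inhibitory concentration (IC50)
#'
#' Two methods are available. `"four_pl"` (default) fits a four-parameter
#' logistic `y = bottom + (top - bottom) / (1 + (ic50/dose)^hill)` by
#' Levenberg-Marquardt least squares; the IC50 is the inflection dose.
#' Starting values are taken from the data (bottom/top from the response
#' range, IC50 from the dose whose response is nearest the half-maximum,
#' hill = 1), making the fit deterministic. `"interpolate"` linearly
#' interpolates log10(dose) between the two doses bracketing 50% inhibition
#' and fails explicitly when 50% is never reached. When the 4PL fit does not
#' converge the interpolation estimate is returned with a warning (method
#' recorded in the result).
#'
#' @param data Data frame with `dose` (strictly increasing, positive) and
#'   `inhibition` (percent) columns.
#' @param method `"four_pl"` or `"interpolate"`.
#' @return An object of class `ic50_fit`: list with `ic50`, `method`,
#'   `parameters` (4PL only), `converged`, `residual_se`.
#' @examples
#' dr <- simulate_dose_response(10^seq(0, 3, length.out = 6), ic50 = 100)
#' estimate_ic50(dr)$ic50
#' @export
estimate_ic50 <- function(data, method = c("four_pl", "interpolate")) {
  method <- match.arg(method)
  dose <- data$dose
  y <- data$inhibition
  if (any(dose <= 0)) stop("Doses must be positive.", call. = FALSE)
  if (is.unsorted(dose, strictly = TRUE)) {
    stop("Doses must be strictly increasing.", call. = FALSE)
  }

  interpolate <- function() {
    half <- 50
    cross <- which(y[-length(y)] < half & y[-1] >= half |
                     y[-length(y)] >= half & y[-1] < half)
    if (y[1] >= half) return(dose[1])
    if (!length(cross)) {
      stop("50% inhibition not reached; cannot interpolate an IC50.",
           call. = FALSE)
    }
    i <- cross[1]
    ld <- log10(dose[i]) + (half - y[i]) * diff(log10(dose[i + 0:1])) / diff(y[i + 0:1])
    10^ld
  }

  if (method == "interpolate") {
    return(structure(list(ic50 = interpolate(), method = "interpolate",
                          parameters = NULL, converged = TRUE,
                          residual_se = NA_real_),
                     class = "ic50_fit"))
  }
  if (length(dose) < 4) stop("4PL fitting needs at least 4 doses.", call. = FALSE)
  start <- list(
    bottom = min(y), top = max(y),
    ic50 = dose[which.min(abs(y - (min(y) + max(y)) / 2))],
    hill = 1
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      inhibition ~ bottom + (top - bottom) / (1 + (ic50 / dose)^hill),
      data = data.frame(dose = dose, inhibition = y),
      start = start,
      lower = c(bottom = -Inf, top = -Inf, ic50 = min(dose) / 1e3, hill = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("4PL fit did not converge; falling back to log-linear ",
            "interpolation.", call. = FALSE)
    ic <- interpolate()
    return(structure(list(ic50 = ic, method = "interpolate_fallback",
                          parameters = NULL, converged = FALSE,
                          residual_se = NA_real_),
                     class = "ic50_fit"))
  }
  est <- stats::coef(fit)
  structure(list(ic50 = unname(est["ic50"]), method = "four_pl",
                 parameters = est, converged = TRUE,
                 residual_se = summary(fit)$sigma, fit = fit),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat("IC50 =", format(x$ic50), "(", x$method, ")\n")
  if (!is.null(x$parameters)) print(round(x$parameters, 4))
  invisible(x)
}
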