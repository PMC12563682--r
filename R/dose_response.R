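#' Percent cell viability from absorbances
#'
#' MTT-style readout: `100 * A_sample / A_control`.
#'
#' @param abs_sample absorbance of the treated well.
#' @param abs_control absorbance of the untreated control (> 0).
#' @return viability in percent.
#' @export
viability_percent <- function(abs_sample, abs_control) {
  if (any(abs_control <= 0)) stop("control absorbance must be positive")
  100 * abs_sample / abs_control
}

#' Four-parameter logistic response (Hill slope fixed at 1)
#'
#' `Y = Bottom + (Top - Bottom) / (1 + 10^(logIC50 - X))` with X the log10
#' concentration. At X = logIC50 the response is the Bottom/Top midpoint.
#'
#' @param X log10 concentration (vectorized).
#' @param fit list/`dose_response_fit` with `Bottom`, `Top`, `logIC50`.
#' @return response (percent).
#' @export
four_pl <- function(X, fit) {
  fit$Bottom + (fit$Top - fit$Bottom) / (1 + 10^(fit$logIC50 - X))
}

#' Assemble a dose-response curve
#'
#' @param concentrations doses (µM, or percent for vehicle controls), >= 0.
#' @param responses matched responses in percent.
#' @param response_type `"inhibition"` or `"viability"`.
#' @return object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(concentrations, responses,
                                response_type = c("inhibition", "viability")) {
  response_type <- match.arg(response_type)
  stopifnot(length(concentrations) == length(responses),
            all(concentrations >= 0))
  if (length(unique(concentrations)) < 4)
    stop("need at least 4 distinct concentrations")
  structure(list(concentrations = concentrations, responses = responses,
                 response_type = response_type),
            class = "dose_response_curve")
}

#' Fit an IC50 by four-parameter logistic regression
#'
#' Least-squares fit of the fixed-slope logistic to a dose-response curve.
#' Viability input is converted to inhibition (`100 - viability`) so that
#' Bottom ~ 0 corresponds to no inhibition. Doses of zero anchor the control
#' level but cannot enter the log-dose fit and are excluded from it.
#' Initialization is deterministic: Bottom = min response, Top = max
#' response, logIC50 = the dose whose response is nearest the midpoint.
#'
#' Two refusal rules mirror assay-reporting practice: when maximal
#' inhibition stays below 50% across the tested range the fit aborts with a
#' "no-inhibition" error (the tabled ">max dose" convention), and a
#' converged IC50 outside the tested dose range is likewise refused rather
#' than extrapolated.
#'
#' @param curve a `dose_response_curve`.
#' @return object of class `dose_response_fit`: `Bottom`, `Top`, `logIC50`,
#'   `IC50`, `residual_sse`.
#' @export
fit_ic50 <- function(curve) {
  conc <- curve$concentrations
  resp <- curve$responses
  if (curve$response_type == "viability") resp <- 100 - resp
  keep <- conc > 0
  if (length(unique(conc[keep])) < 4)
    stop("need at least 4 distinct nonzero concentrations")
  x <- log10(conc[keep])
  y <- resp[keep]
  if (max(y) < 50)
    stop("no-inhibition: maximal inhibition ",
         sprintf("%.1f", max(y)), "% < 50% within the tested range (IC50 > ",
         max(conc), ")")
  # start just outside the observed range: starting exactly on min/max makes
  # the gradient singular for noise-free curves
  b0 <- min(y) - 1; t0 <- max(y) + 1
  mid <- (b0 + t0) / 2
  x0 <- x[which.min(abs(y - mid))]
  fit <- minpack.lm::nlsLM(
    y ~ Bottom + (Top - Bottom) / (1 + 10^(logIC50 - x)),
    start = list(Bottom = b0, Top = t0, logIC50 = x0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- as.list(stats::coef(fit))
  ic50 <- 10^est$logIC50
  if (ic50 > max(conc[keep]) || ic50 < min(conc[keep]))
    stop("no-inhibition: fitted IC50 (", sprintf("%.3g", ic50),
         ") lies outside the tested dose range [", min(conc[keep]), ", ",
         max(conc[keep]), "]")
  structure(list(Bottom = est$Bottom, Top = est$Top, logIC50 = est$logIC50,
                 IC50 = ic50, residual_sse = sum(stats::resid(fit)^2)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("4PL fit: IC50 = %.4g  (Bottom %.2f, Top %.2f, SSE %.3g)\n",
              x$IC50, x$Bottom, x$Top, x$residual_sse))
  invisible(x)
}
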