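#' Effective growth rate from the divider fraction
#'
#' The bistable divider-fraction model: if each division produces divider
#' daughters with probability `f`, the dividing subpopulation obeys
#' `N_d(t + tau) = 2 f N_d(t)` over one mean generation `tau`, so the
#' effective per-capita division rate is `ln(2 f) / tau`. At `f = 1/2`
#' production of dividers exactly balances conversion to non-dividers and
#' the population is stationary.
#'
#' @param f divider fraction, in (0, 1].
#' @param tau_bar_d mean division time (min).
#' @return Effective growth rate (1/h).
#' @export
effective_growth_from_fraction <- function(f, tau_bar_d) {
  if (any(!is.finite(f)) || any(f <= 0) || any(f > 1))
    stop("domain error: f must lie in (0, 1]")
  if (any(tau_bar_d <= 0)) stop("domain error: tau_bar_d must be > 0")
  log(2 * f) / (tau_bar_d / 60)
}

#' Divider fraction from the effective growth rate
#'
#' Inverse of [effective_growth_from_fraction()]:
#' `f = exp(eta_eff * tau) / 2`.
#'
#' @param eta_eff effective growth rate (1/h).
#' @param tau_bar_d mean division time (min).
#' @return Divider fraction in (0, 1].
#' @export
fraction_from_growth <- function(eta_eff, tau_bar_d) {
  if (any(tau_bar_d <= 0)) stop("domain error: tau_bar_d must be > 0")
  f <- exp(eta_eff * tau_bar_d / 60) / 2
  if (any(f > 1 + 1e-12))
    stop("inconsistent inputs: implied f > 1 ",
         "(growth faster than pure doubling at this division time)")
  pmin(f, 1)
}

#' Fit the mean division time of the divider-fraction model
#'
#' Least squares over `tau_bar_d` of the residuals
#' `eta_eff - ln(2 f) / tau_bar_d` across (f, eta_eff) pairs, fitted in
#' rate space (scalar minimization). A fraction-space alternative
#' minimizes `f - exp(eta_eff tau)/2` instead.
#'
#' @param pairs data.frame with columns `f` and `eta_eff` (1/h).
#' @param space `"rate"` (default) or `"fraction"` residuals.
#' @param interval search interval for `tau_bar_d` (min).
#' @return Object of class `growth_model_fit`: list `tau_bar_d` (min),
#'   `data`, `residuals` (in the fitted space), `fit_method`.
#' @export
fit_mean_division_time <- function(pairs, space = c("rate", "fraction"),
                                   interval = c(1, 1000)) {
  space <- match.arg(space)
  stopifnot(all(c("f", "eta_eff") %in% names(pairs)))
  usable <- pairs$f > 0.5 | pairs$eta_eff <= 0
  if (!any(pairs$f > 0.5))
    stop("infeasible fit: need at least one pair with f > 0.5 ",
         "(ln 2f <= 0 cannot produce positive growth)")
  obj <- function(tau) {
    pred_eta <- log(2 * pairs$f) / (tau / 60)
    if (space == "rate") sum((pairs$eta_eff - pred_eta)^2)
    else sum((pairs$f - exp(pairs$eta_eff * tau / 60) / 2)^2)
  }
  opt <- stats::optimize(obj, interval = interval, tol = 1e-10)
  tau <- opt$minimum
  res <- if (space == "rate") pairs$eta_eff - log(2 * pairs$f) / (tau / 60)
  else pairs$f - exp(pairs$eta_eff * tau / 60) / 2
  structure(list(tau_bar_d = tau, data = pairs, residuals = res,
                 fit_method = paste0("least-squares (", space, " space)"),
                 usable = usable),
            class = "growth_model_fit")
}

#' @export
print.growth_model_fit <- function(x, ...) {
  cat(sprintf("<growth_model_fit> tau_bar_d = %.2f min (%s, %d pairs)\n",
              x$tau_bar_d, x$fit_method, nrow(x$data)))
  invisible(x)
}
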