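#' One-compartment oral-absorption parameters
#'
#' First-order absorption into, and first-order elimination from, a single
#' central compartment (the Bateman profile). Only the apparent volume
#' `v_f = V/F` is identifiable after extravascular dosing, so dose is
#' carried separately and bioavailability is absorbed into `v_f`.
#'
#' @param ka absorption rate constant (1/min), > 0.
#' @param ke elimination rate constant (1/min), > 0, `ka != ke`.
#' @param v_f apparent volume of distribution V/F (mL per dose unit).
#' @param tlag absorption lag time (min), >= 0.
#' @return object of class `c("pk1c_params", "pk_params")`.
#' @export
pk1c_params <- function(ka, ke, v_f, tlag = 0) {
  if (ka <= 0 || ke <= 0 || v_f <= 0 || tlag < 0)
    md_stop("ka, ke, v_f must be > 0 and tlag >= 0", "pk_invalid_params")
  if (ka == ke)
    md_stop("ka = ke is degenerate; reparameterize", "pk_degenerate_rate")
  structure(list(ka = ka, ke = ke, v_f = v_f, tlag = tlag),
            class = c("pk1c_params", "pk_params"))
}

#' Two-compartment oral-absorption parameters (macro form)
#'
#' Biexponential disposition with first-order absorption, in the macro
#' parameterization `C(t) = A e^(-alpha t) + B e^(-beta t)
#' - (A + B) e^(-ka t)` with hybrid rate constants `alpha > beta`.
#' The macro-coefficients absorb dose and bioavailability.
#'
#' @param ka absorption rate constant (1/min).
#' @param alpha,beta hybrid distribution/elimination rate constants
#'   (1/min), `alpha > beta > 0`.
#' @param a_coef,b_coef macro-coefficients (ng/mL), > 0.
#' @param tlag absorption lag (min).
#' @return object of class `c("pk2c_params", "pk_params")`.
#' @export
pk2c_params <- function(ka, alpha, beta, a_coef, b_coef, tlag = 0) {
  if (ka <= 0 || beta <= 0 || a_coef <= 0 || b_coef <= 0 || tlag < 0)
    md_stop("rates and coefficients must be > 0", "pk_invalid_params")
  if (alpha <= beta)
    md_stop("need alpha > beta", "pk_invalid_params")
  structure(list(ka = ka, alpha = alpha, beta = beta,
                 a_coef = a_coef, b_coef = b_coef, tlag = tlag),
            class = c("pk2c_params", "pk_params"))
}

# Represent a PK model's concentration profile as a sum of exponentials:
# Cp(t) = sum(coef_i * exp(-rate_i * tau)), tau = max(t - tlag, 0).
# This form backs closed-form prediction, interval averaging, and the
# analytic effect-compartment solution.
exp_terms <- function(params, dose = 1) UseMethod("exp_terms")

#' @export
exp_terms.pk1c_params <- function(params, dose = 1) {
  A <- dose * params$ka / (params$v_f * (params$ka - params$ke))
  list(coef = c(A, -A), rate = c(params$ke, params$ka), tlag = params$tlag)
}

#' @export
exp_terms.pk2c_params <- function(params, dose = 1) {
  list(coef = c(params$a_coef, params$b_coef,
                -(params$a_coef + params$b_coef)),
       rate = c(params$alpha, params$beta, params$ka),
       tlag = params$tlag)
}

eval_exp_terms <- function(terms, times) {
  tau <- pmax(times - terms$tlag, 0)
  out <- numeric(length(tau))
  for (i in seq_along(terms$coef))
    out <- out + terms$coef[i] * exp(-terms$rate[i] * tau)
  pmax(out, 0)  # guard tiny negative round-off
}

# Closed-form running integral of the exponential-sum profile from the
# lag time to t: F(t) = sum(coef_i * (1 - exp(-rate_i * tau)) / rate_i).
integral_exp_terms <- function(terms, times) {
  tau <- pmax(times - terms$tlag, 0)
  out <- numeric(length(tau))
  for (i in seq_along(terms$coef))
    out <- out + terms$coef[i] * (1 - exp(-terms$rate[i] * tau)) / terms$rate[i]
  out
}

#' Predicted concentration of a compartmental model
#'
#' Closed-form solution of the one- or two-compartment oral-absorption
#' model at the requested times. For the one-compartment model
#' `C(t) = dose * ka / (v_f (ka - ke)) (e^(-ke tau) - e^(-ka tau))` with
#' `tau = max(t - tlag, 0)`; the two-compartment macro form absorbs dose
#' into its coefficients, so `dose` is ignored there.
#'
#' @param params [pk1c_params()] or [pk2c_params()].
#' @param times vector of times (min), >= 0.
#' @param dose administered dose (one-compartment model only).
#' @return concentrations (ng/mL), same length as `times`.
#' @export
predict_conc <- function(params, times, dose = 1) {
  stopifnot(inherits(params, "pk_params"))
  if (any(times < 0)) md_stop("times must be >= 0", "pk_invalid_times")
  eval_exp_terms(exp_terms(params, dose), times)
}

#' Interval-average concentration over collection windows
#'
#' Average of the model profile over each `[t0, t1]` window, the quantity
#' a microdialysis probe actually reports: the closed-form integral of the
#' exponential terms divided by the window width.
#'
#' @param params [pk1c_params()] or [pk2c_params()].
#' @param t0,t1 vectors of window starts/ends (min), `t1 > t0`.
#' @param dose administered dose (one-compartment model only).
#' @return average concentrations, one per window.
#' @export
predict_conc_interval <- function(params, t0, t1, dose = 1) {
  stopifnot(inherits(params, "pk_params"), length(t0) == length(t1))
  if (any(t1 <= t0)) md_stop("need t1 > t0", "pk_invalid_times")
  terms <- exp_terms(params, dose)
  (integral_exp_terms(terms, t1) - integral_exp_terms(terms, t0)) / (t1 - t0)
}

# number of structural parameters (used by AIC/BIC)
n_params <- function(params) {
  if (inherits(params, "pk1c_params")) 3L else 5L
}
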