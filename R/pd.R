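#' Sigmoid Emax / Imax pharmacodynamic parameters
#'
#' Hill-type concentration-effect model. Stimulatory mode:
#' `E(C) = e0 + emax * C^n / (ec50^n + C^n)`. Inhibitory mode uses a
#' multiplicative fractional maximum inhibition,
#' `E(C) = e0 * (1 - imax * C^n / (ic50^n + C^n))` with `imax` in (0, 1],
#' which keeps the effect nonnegative and makes `imax` independent of the
#' baseline scale.
#'
#' @param mode `"stimulation"` or `"inhibition"`.
#' @param e0 baseline effect (percent of baseline), > 0 for inhibition.
#' @param emax maximal stimulation above baseline (stimulation mode).
#' @param imax fractional maximal inhibition in (0, 1] (inhibition mode).
#' @param c50 concentration of half-maximal effect (EC50 / IC50, ng/mL).
#' @param hill_n Hill coefficient, > 0.
#' @return object of class `pd_params`.
#' @export
pd_params <- function(mode = c("stimulation", "inhibition"), e0,
                      emax = NULL, imax = NULL, c50, hill_n = 1) {
  mode <- match.arg(mode)
  if (c50 <= 0 || hill_n <= 0)
    md_stop("c50 and hill_n must be > 0", "pd_invalid_params")
  if (mode == "stimulation") {
    if (is.null(emax) || emax <= 0)
      md_stop("stimulation mode requires emax > 0", "pd_invalid_params")
    imax <- NULL
  } else {
    if (is.null(imax) || imax <= 0 || imax > 1)
      md_stop("inhibition mode requires imax in (0, 1]", "pd_invalid_params")
    if (e0 <= 0)
      md_stop("inhibition mode requires e0 > 0", "pd_invalid_params")
    emax <- NULL
  }
  structure(list(mode = mode, e0 = e0, emax = emax, imax = imax,
                 c50 = c50, hill_n = hill_n), class = "pd_params")
}

#' @export
print.pd_params <- function(x, ...) {
  if (x$mode == "stimulation")
    cat(sprintf("Sigmoid-Emax: E0 %.4g + Emax %.4g, EC50 %.4g ng/mL, n %.3g\n",
                x$e0, x$emax, x$c50, x$hill_n))
  else
    cat(sprintf("Sigmoid-Imax: E0 %.4g, Imax %.4g, IC50 %.4g ng/mL, n %.3g\n",
                x$e0, x$imax, x$c50, x$hill_n))
  invisible(x)
}

#' Predicted effect of the sigmoid PD model
#'
#' @param params a [pd_params()].
#' @param conc concentration(s), >= 0.
#' @return effect (percent of baseline), same length as `conc`.
#' @export
pd_predict <- function(params, conc) {
  stopifnot(inherits(params, "pd_params"))
  if (any(conc < 0)) md_stop("concentrations must be >= 0", "pd_invalid_conc")
  frac <- ifelse(conc == 0, 0,
                 conc^params$hill_n /
                   (params$c50^params$hill_n + conc^params$hill_n))
  if (params$mode == "stimulation") params$e0 + params$emax * frac
  else params$e0 * (1 - params$imax * frac)
}

#' Baseline-normalize a neurotransmitter dialysate series
#'
#' Expresses each sample as a percentage of the pre-dose baseline so that
#' the first basal sample maps to exactly 100. The default baseline is the
#' first pre-dose sample; `baseline = "window"` averages all pre-dose
#' samples inside `series$baseline_window` instead.
#'
#' @param series a [sample_series()] including at least one pre-dose sample.
#' @param baseline `"first"` (default) or `"window"`.
#' @return object of class `effect_series`: `times`, `effect`
#'   (percent of baseline), `baseline_raw` (ng/mL), `neurotransmitter`,
#'   `subject`, `dose_time`, `interval`.
#' @export
normalize_effect <- function(series, baseline = c("first", "window")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(series, "sample_series"))
  pre <- series$times < series$dose_time
  if (!is.null(series$baseline_window))
    pre <- pre & series$times >= series$baseline_window[1] &
      series$times <= series$baseline_window[2]
  if (!any(pre))
    md_stop("no pre-dose baseline sample", "pd_no_baseline")
  basal <- if (baseline == "first") series$conc[which(pre)[1]]
           else mean(series$conc[pre])
  if (!is.finite(basal) || basal <= 0)
    md_stop("baseline concentration must be > 0", "pd_invalid_baseline")
  structure(list(times = series$times, effect = 100 * series$conc / basal,
                 baseline_raw = basal, neurotransmitter = series$analyte,
                 subject = series$subject, dose_time = series$dose_time,
                 interval = series$interval),
            class = "effect_series")
}

#' @export
print.effect_series <- function(x, ...) {
  cat(sprintf("effect_series: %s, %d samples, baseline %.4g ng/mL\n",
              x$neurotransmitter, length(x$times), x$baseline_raw))
  invisible(x)
}

# transform/untransform PD parameters for optimization:
# theta = (log e0, log emax | qlogis(imax), log c50, log hill_n)
pd_theta_to_params <- function(theta, mode) {
  if (mode == "stimulation")
    pd_params(mode, e0 = exp(theta[1]), emax = exp(theta[2]),
              c50 = exp(theta[3]), hill_n = exp(theta[4]))
  else
    pd_params(mode, e0 = exp(theta[1]), imax = stats::plogis(theta[2]),
              c50 = exp(theta[3]), hill_n = exp(theta[4]))
}

pd_start_theta <- function(conc, effect, mode) {
  ord <- order(conc)
  e0_0 <- max(effect[ord[1]], 1e-6)
  c50_0 <- stats::median(conc[conc > 0])
  if (mode == "stimulation") {
    emax0 <- max(max(effect) - e0_0, 0.05 * e0_0)
    c(log(e0_0), log(emax0), log(c50_0), log(1))
  } else {
    imax0 <- min(max(1 - min(effect) / e0_0, 0.05), 0.95)
    c(log(e0_0), stats::qlogis(imax0), log(c50_0), log(1))
  }
}

# Hill coefficient is bounded to [0.1, 10] to keep the curve from
# collapsing to a step function. The half-maximal concentration is kept
# within a wide window around the observed concentration scale: outside
# it only the ratio emax/c50^n is identified (the classic Emax/EC50
# ridge) and estimates diverge without improving the fit.
pd_bounds <- function(conc_scale) {
  list(lower = c(-Inf, -Inf, log(conc_scale / 1000), log(0.1)),
       upper = c(Inf, Inf, log(conc_scale * 20), log(10)))
}

pd_param_names <- function(mode) {
  c("e0", if (mode == "stimulation") "emax" else "imax", "c50", "hill_n")
}

#' Fit a sigmoid Emax/Imax model to paired concentration-effect data
#'
#' Least squares in transformed parameter space (log e0, log emax or
#' logit imax, log EC50/IC50, log Hill coefficient bounded to [0.1, 10]),
#' Levenberg-Marquardt with jittered multi-start. The half-maximal
#' concentration is constrained to a wide window around the observed
#' concentration scale (outside it only `emax / c50^n` is identified);
#' a fit landing on that bound is flagged `"c50_at_bound"`. Scores as in
#' [fit_pk()].
#'
#' @param conc driving concentrations (ng/mL), >= 5 values spanning a
#'   nonzero range.
#' @param effect observed effects (percent of baseline), same length.
#' @param mode `"stimulation"` or `"inhibition"`.
#' @param n_restarts jittered restarts (default 4).
#' @param seed optional RNG seed for the jitter.
#' @return object of class `pd_fit`: `params` ([pd_params()]), `scores`,
#'   `predicted`.
#' @export
fit_pd <- function(conc, effect, mode = c("stimulation", "inhibition"),
                   n_restarts = 4, seed = NULL) {
  mode <- match.arg(mode)
  if (length(conc) != length(effect) || length(conc) < 5L)
    md_stop("need >= 5 paired (conc, effect) points", "pd_insufficient_data")
  if (diff(range(conc)) <= 0)
    md_stop("degenerate concentration range: PD parameters unidentifiable",
            "pd_unidentifiable")
  if (!is.null(seed)) set.seed(seed)

  resid_fn <- function(theta) {
    pd_predict(pd_theta_to_params(theta, mode), conc) - effect
  }
  start0 <- pd_start_theta(conc, effect, mode)
  starts <- c(list(start0),
              lapply(seq_len(n_restarts), function(i)
                start0 + stats::rnorm(length(start0), 0, 0.4)))
  b <- pd_bounds(max(conc))
  starts <- lapply(starts, function(s) pmin(pmax(s, b$lower), b$upper))
  best <- multi_start_lm(resid_fn, starts, lower = b$lower, upper = b$upper)
  if (is.null(best))
    md_stop("PD optimizer failed from every start", "pd_fit_failed")

  params <- pd_theta_to_params(best$par, mode)
  scores <- ls_scores(resid_fn, best$par, pd_param_names(mode))
  flags <- character(0)
  if (best$par[3] >= b$upper[3] - 1e-6 || best$par[3] <= b$lower[3] + 1e-6)
    flags <- c(flags, "c50_at_bound")
  structure(list(params = params, scores = scores,
                 predicted = pd_predict(params, conc),
                 conc = conc, effect = effect, mode = mode, seed = seed,
                 flags = flags),
            class = "pd_fit")
}

#' @export
print.pd_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("SSR %.6g | AIC %.4f | n = %d\n",
              x$scores$ssr, x$scores$aic, x$scores$n_obs))
  invisible(x)
}
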