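#' Effect-compartment concentration from a compartmental PK model
#'
#' Solves `dCe/dt = ke0 (Cp(t) - Ce(t))`, `Ce(0) = 0`, analytically for a
#' plasma profile that is a sum of exponentials: each term
#' `A e^(-lambda tau)` contributes
#' `A ke0 (e^(-lambda tau) - e^(-ke0 tau)) / (ke0 - lambda)`, with the
#' `lambda = ke0` coincidence handled by the limit
#' `A ke0 tau e^(-ke0 tau)`.
#'
#' @param params [pk1c_params()] or [pk2c_params()].
#' @param ke0 effect-compartment equilibration rate (1/min), > 0.
#' @param times times (min).
#' @param dose administered dose (one-compartment model only).
#' @return effect-site concentrations, same length as `times`.
#' @export
effect_compartment_conc <- function(params, ke0, times, dose = 1) {
  stopifnot(inherits(params, "pk_params"))
  if (ke0 <= 0) md_stop("ke0 must be > 0", "link_invalid_ke0")
  terms <- exp_terms(params, dose)
  ce_from_terms(terms, ke0, times)
}

ce_from_terms <- function(terms, ke0, times) {
  tau <- pmax(times - terms$tlag, 0)
  out <- numeric(length(tau))
  for (i in seq_along(terms$coef)) {
    lam <- terms$rate[i]
    A <- terms$coef[i]
    if (abs(ke0 - lam) < 1e-9 * ke0) {
      out <- out + A * ke0 * tau * exp(-ke0 * tau)
    } else {
      out <- out + A * ke0 * (exp(-lam * tau) - exp(-ke0 * tau)) / (ke0 - lam)
    }
  }
  pmax(out, 0)
}

#' Fit the effect-compartment (ke0) PK-PD link model
#'
#' Sequential (two-stage) estimation: the PK parameters are frozen at the
#' supplied fit and `(ke0, PD parameters)` are estimated by least squares
#' of the observed effect against `pd_predict(Ce(t))`. The optimizer is
#' multi-started over a log-spaced ke0 grid because the effect-delay
#' surface is multimodal in ke0.
#'
#' @param effect an `effect_series` (see [normalize_effect()]) or a
#'   numeric effect vector.
#' @param pk a `pk_fit` (see [fit_pk()]) or `pk_params` object providing
#'   the plasma concentration profile.
#' @param mode `"stimulation"` or `"inhibition"`.
#' @param times effect observation times (min); taken from the
#'   `effect_series` when omitted.
#' @param dose administered dose (one-compartment PK only).
#' @param dose_time dosing time; taken from the `effect_series` when
#'   omitted, else 0.
#' @param ke0_grid starting values for ke0 (1/min).
#' @param seed optional RNG seed (reserved; the grid start is deterministic).
#' @return object of class `link_fit`: `ke0`, `pd` ([pd_params()]),
#'   `scores`, `predicted` effect, `ce` (effect-site concentrations at the
#'   observation times).
#' @export
fit_link <- function(effect, pk, mode = c("stimulation", "inhibition"),
                     times = NULL, dose = 1, dose_time = NULL,
                     ke0_grid = 10^seq(-3, 0, length.out = 7), seed = NULL) {
  mode <- match.arg(mode)
  if (inherits(effect, "effect_series")) {
    if (is.null(times)) times <- effect$times
    if (is.null(dose_time)) dose_time <- effect$dose_time
    effect <- effect$effect
  }
  if (is.null(dose_time)) dose_time <- 0
  if (length(times) != length(effect))
    md_stop("times and effect lengths differ", "link_invalid_input")
  pk_params <- if (inherits(pk, "pk_fit")) pk$params else pk
  if (inherits(pk, "pk_fit") && missing(dose)) dose <- pk$dose
  stopifnot(inherits(pk_params, "pk_params"))
  if (diff(range(effect)) == 0)
    md_stop("flat effect series: link parameters unidentifiable",
            "link_unidentifiable")
  if (!is.null(seed)) set.seed(seed)

  terms <- exp_terms(pk_params, dose)
  tau <- times - dose_time
  resid_fn <- function(theta) {
    ke0 <- exp(theta[1])
    ce <- ce_from_terms(terms, ke0, tau + terms$tlag)
    pd_predict(pd_theta_to_params(theta[-1], mode), ce) - effect
  }
  # c50 is bounded around the plasma-concentration scale (the effect-site
  # peak cannot exceed the plasma peak), see pd_bounds()
  b <- pd_bounds(max(eval_exp_terms(terms, tau + terms$tlag)))
  lower <- c(-Inf, b$lower); upper <- c(Inf, b$upper)
  starts <- lapply(ke0_grid, function(k0) {
    ce0 <- ce_from_terms(terms, k0, tau + terms$tlag)
    if (diff(range(ce0)) <= 0) return(NULL)
    st <- pd_start_theta(ce0, effect, mode)
    c(log(k0), pmin(pmax(st, b$lower), b$upper))
  })
  starts <- Filter(Negate(is.null), starts)
  if (length(starts) == 0L)
    md_stop("no usable ke0 start produced a varying effect-site profile",
            "link_unidentifiable")
  best <- multi_start_lm(resid_fn, starts, lower = lower, upper = upper)
  if (is.null(best))
    md_stop("link optimizer failed from every start", "link_fit_failed")

  ke0 <- exp(best$par[1])
  pd <- pd_theta_to_params(best$par[-1], mode)
  ce <- ce_from_terms(terms, ke0, tau + terms$tlag)
  scores <- ls_scores(resid_fn, best$par, c("ke0", pd_param_names(mode)))
  flags <- character(0)
  if (best$par[4] >= upper[4] - 1e-6 || best$par[4] <= lower[4] + 1e-6)
    flags <- c(flags, "c50_at_bound")
  structure(list(ke0 = ke0, pd = pd, flags = flags, scores = scores,
                 predicted = pd_predict(pd, ce), ce = ce,
                 times = times, effect = effect, mode = mode,
                 pk_params = pk_params, dose = dose),
            class = "link_fit")
}

#' @export
print.link_fit <- function(x, ...) {
  cat(sprintf("Effect-compartment link: ke0 %.5g /min (t1/2,ke0 %.4g min)\n",
              x$ke0, log(2) / x$ke0))
  print(x$pd)
  cat(sprintf("SSR %.6g | AIC %.4f | n = %d\n",
              x$scores$ssr, x$scores$aic, x$scores$n_obs))
  invisible(x)
}

#' Signed area and direction of a concentration-effect hysteresis loop
#'
#' Treats the time-ordered `(concentration, effect)` trajectory as a
#' polygon (closed last-to-first) and computes its shoelace signed area,
#' with concentration on x and effect on y so that a counterclockwise
#' loop has positive area. The area is normalized by
#' `range(conc) * range(effect)` (the bounding box), giving a
#' dimensionless value in [-1, 1]; |normalized area| below `tol` is
#' classified as no hysteresis.
#'
#' @param conc concentrations (x-axis).
#' @param effect effects (y-axis), same length.
#' @param times optional times used to order the pairs.
#' @param tol direction tolerance on the normalized area (default 0.01).
#' @return object of class `hysteresis_result`: `signed_area`,
#'   `normalized_area`, `direction` (`"counterclockwise"`, `"clockwise"`,
#'   `"none"`), `n_points`, `flags` (may contain `"degenerate_range"`,
#'   `"open_loop"` when the closure chord exceeds 20% of the bounding-box
#'   diagonal).
#' @export
hysteresis_loop <- function(conc, effect, times = NULL, tol = 0.01) {
  if (length(conc) != length(effect))
    md_stop("conc and effect lengths differ", "loop_invalid_input")
  if (length(conc) < 4L)
    md_stop("need >= 4 points to assess a loop", "loop_insufficient_points")
  if (!is.null(times)) {
    ord <- order(times)
    conc <- conc[ord]; effect <- effect[ord]
  }
  x <- conc; y <- effect
  nxt <- c(seq_along(x)[-1], 1L)
  signed <- 0.5 * sum(x * y[nxt] - x[nxt] * y)
  rx <- diff(range(x)); ry <- diff(range(y))
  flags <- character(0)
  if (rx == 0 || ry == 0) {
    return(structure(list(signed_area = signed, normalized_area = 0,
                          direction = "none", n_points = length(x),
                          flags = "degenerate_range"),
                     class = "hysteresis_result"))
  }
  norm <- signed / (rx * ry)
  chord <- sqrt((x[length(x)] - x[1])^2 / rx^2 + (y[length(y)] - y[1])^2 / ry^2)
  if (chord > 0.2 * sqrt(2)) flags <- c(flags, "open_loop")
  direction <- if (norm > tol) "counterclockwise"
               else if (norm < -tol) "clockwise" else "none"
  structure(list(signed_area = signed, normalized_area = norm,
                 direction = direction, n_points = length(x), flags = flags),
            class = "hysteresis_result")
}

#' @export
print.hysteresis_result <- function(x, ...) {
  cat(sprintf("Hysteresis: %s (signed area %.6g, normalized %.4f, %d points)%s\n",
              x$direction, x$signed_area, x$normalized_area, x$n_points,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Interpret a hysteresis loop against the PD mode
#'
#' Maps loop direction and PD mode to the standard PK-PD reading: a
#' clockwise loop with an inhibitory response is a delayed suppression (the
#' excitatory-transmitter pattern of Asp/Glu), a counterclockwise loop with
#' a stimulatory response is a delayed enhancement (the Tau/Ach pattern);
#' any other combination, or no loop, is labelled atypical.
#'
#' @param result a [hysteresis_loop()] result.
#' @param mode `"stimulation"` or `"inhibition"`.
#' @return character label.
#' @export
classify_relationship <- function(result, mode = c("stimulation", "inhibition")) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "hysteresis_result"))
  if (result$direction == "clockwise" && mode == "inhibition")
    "delayed suppression (Asp/Glu pattern)"
  else if (result$direction == "counterclockwise" && mode == "stimulation")
    "delayed enhancement (Tau/Ach pattern)"
  else "atypical"
}
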