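# Independent oracles used across tests. These recompute expected values
# by routes that do not share code with the package implementation.

# Closed-form quantities of the one-compartment oral (Bateman) model.
bateman_conc <- function(t, ka, ke, v_f, dose = 1) {
  dose * ka / (v_f * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}
bateman_auc <- function(t, ka, ke, v_f, dose = 1) {
  A <- dose * ka / (v_f * (ka - ke))
  A * ((1 - exp(-ke * t)) / ke - (1 - exp(-ka * t)) / ka)
}
bateman_tmax <- function(ka, ke) log(ka / ke) / (ka - ke)

# Ordinary least squares by the normal equations, written out by hand.
ols_normal_equations <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  c(slope = slope, intercept = intercept)
}

# Numerical ODE oracle for the oral one-compartment system, optionally
# chained to an effect compartment (deSolve, independent of the package's
# closed forms).
ode_1c_oracle <- function(times, ka, ke, v_f, dose = 1, ke0 = NULL) {
  rhs <- function(t, y, p) {
    dgut <- -p$ka * y[1]
    dcen <- p$ka * y[1] - p$ke * y[2]
    if (is.null(p$ke0)) return(list(c(dgut, dcen)))
    dce <- p$ke0 * (y[2] / p$v_f - y[3])
    list(c(dgut, dcen, dce))
  }
  y0 <- if (is.null(ke0)) c(dose, 0) else c(dose, 0, 0)
  p <- list(ka = ka, ke = ke, v_f = v_f, ke0 = ke0)
  sol <- deSolve::ode(y0, c(0, times[times > 0]), rhs, p,
                      rtol = 1e-10, atol = 1e-12)
  sol <- sol[match(times, sol[, 1]), , drop = FALSE]
  list(cp = sol[, 3] / v_f, ce = if (is.null(ke0)) NULL else sol[, 4])
}

# 20-min collection grid over 480 min (plus optional baseline windows),
# returning midpoints.
paper_grid <- function(n_baseline = 0) {
  starts <- seq(-n_baseline * 20, 460, by = 20)
  data.frame(t0 = starts, t1 = starts + 20, mid = starts + 10)
}

# Interval-averaged noise-free Bateman series on the 20-min grid.
bateman_interval_series <- function(ka, ke, v_f, dose = 1, analyte = "x") {
  g <- paper_grid()
  avg <- (bateman_auc(g$t1, ka, ke, v_f, dose) -
            bateman_auc(pmax(g$t0, 0), ka, ke, v_f, dose)) / 20
  sample_series(g$mid, avg, analyte = analyte, interval = 20)
}
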