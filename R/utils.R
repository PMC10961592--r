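# Internal helpers shared across modules.

# Signal a classed error so callers can distinguish failure modes
# programmatically (tryCatch on the specific class).
md_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "mdpkpd_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

md_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "mdpkpd_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

# n-1 sample standard deviation; NA-free input assumed
sample_sd <- function(x) stats::sd(x)

# numeric check helpers
is_num_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Central-difference Jacobian of a residual function at a point.
# fn returns a numeric residual vector; used for asymptotic covariance
# at a least-squares optimum.
numeric_jacobian <- function(fn, par, eps = 1e-6) {
  r0 <- fn(par)
  J <- matrix(NA_real_, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1)
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (fn(up) - fn(dn)) / (2 * h)
  }
  J
}

# Deterministic 32-bit-safe string hash (polynomial, mod 2^31 - 1).
# Used to derive one RNG stream per (group, subject, analyte) so adding
# analytes to a simulation does not perturb existing series.
str_hash <- function(key) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  as.integer(h)
}

# Fixed-precision number formatting for text outputs (stable diffs).
fmt_num <- function(x, digits = 9) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}
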