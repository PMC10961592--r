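#' Area under the concentration-time curve to the last sample
#'
#' Three integration variants are available:
#' \describe{
#'   \item{`linear`}{linear trapezoidal rule on the observed points,
#'     anchored at `(dose_time, 0)` for extravascular dosing when the
#'     first sample falls after the dose.}
#'   \item{`interval`}{treats each sample as the average concentration
#'     over its collection window (width `series$interval`) and sums
#'     `conc * width`, clipping the first window at the dose time. For
#'     interval-averaged microdialysis data this reproduces the integral
#'     of the underlying profile exactly up to noise, whereas the
#'     trapezoid on window midpoints does not.}
#'   \item{`linear-log`}{linear trapezoid on rising segments, logarithmic
#'     trapezoid on falling segments (the "linear-up/log-down" rule).}
#' }
#' `auto` (the default) picks `interval` when the series carries a
#' collection-window width and `linear` otherwise.
#'
#' @param series a [sample_series()].
#' @param method one of `"auto"`, `"linear"`, `"interval"`, `"linear-log"`.
#' @return AUC from dose time to the last sample (ng.min/mL). For the
#'   interval method the upper limit is the end of the last collection
#'   window.
#' @export
auc_trapezoid <- function(series, method = c("auto", "linear", "interval",
                                             "linear-log")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "sample_series"))
  pd <- post_dose(series)
  if (length(pd$times) < 2L)
    md_stop("need at least 2 post-dose samples", "nca_insufficient_data")
  if (method == "auto")
    method <- if (is.finite(series$interval)) "interval" else "linear"

  if (method == "interval") {
    h <- series$interval
    if (!is.finite(h) || h <= 0)
      md_stop("interval method requires a positive collection-window width",
              "nca_no_interval")
    lo <- pmax(pd$times - h / 2, series$dose_time)
    hi <- pd$times + h / 2
    return(sum(pd$conc * (hi - lo)))
  }

  tt <- pd$times; cc <- pd$conc
  if (tt[1] > series$dose_time) {         # anchor at dose time, C = 0
    tt <- c(series$dose_time, tt)
    cc <- c(0, cc)
  }
  segs <- seq_len(length(tt) - 1L)
  if (method == "linear") {
    return(sum(diff(tt) * (cc[segs] + cc[segs + 1L]) / 2))
  }
  # linear-up/log-down
  sum(vapply(segs, function(i) {
    dt <- tt[i + 1L] - tt[i]
    c0 <- cc[i]; c1 <- cc[i + 1L]
    if (c1 < c0 && c1 > 0 && c0 > 0) dt * (c0 - c1) / log(c0 / c1)
    else dt * (c0 + c1) / 2
  }, numeric(1)))
}

#' Terminal elimination rate from log-linear regression
#'
#' Searches all contiguous terminal windows of at least 3 points that lie
#' strictly after Tmax (the Cmax point itself is excluded) and keeps the
#' window maximizing the adjusted R-squared of the log-linear fit; ties go
#' to the window with more points. Non-positive concentrations, and
#' concentrations below `loq` when given, are dropped from the regression.
#'
#' @param series a [sample_series()].
#' @param loq optional lower limit of quantification; post-Tmax values
#'   below it are excluded from the regression.
#' @return list with `lambda_z` (1/min), `t_half` (min), `points_used`,
#'   `adj_r2`, and logical `defined`. When no window yields a positive
#'   elimination rate, `defined` is `FALSE` and the estimates are `NA`.
#' @export
terminal_slope <- function(series, loq = NULL) {
  stopifnot(inherits(series, "sample_series"))
  pd <- post_dose(series)
  undefined <- list(lambda_z = NA_real_, t_half = NA_real_,
                    points_used = 0L, adj_r2 = NA_real_, defined = FALSE)
  if (length(pd$times) < 3L) return(undefined)

  i_max <- which.max(pd$conc)             # earliest maximum on ties
  tt <- pd$times[-seq_len(i_max)]
  cc <- pd$conc[-seq_len(i_max)]
  keep <- cc > 0
  if (!is.null(loq)) keep <- keep & cc >= loq
  tt <- tt[keep]; cc <- cc[keep]
  n <- length(tt)
  if (n < 3L) return(undefined)

  best <- NULL
  for (k in seq(3L, n)) {                 # suffix windows of k points
    idx <- seq(n - k + 1L, n)
    y <- log(cc[idx])
    fit <- stats::lm(y ~ tt[idx])
    slope <- stats::coef(fit)[2]
    if (!is.finite(slope) || slope >= 0) next
    sst <- sum((y - mean(y))^2)           # direct R^2 (summary.lm warns
    r2 <- 1 - sum(stats::residuals(fit)^2) / sst  # on exact fits)
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    # maximize adjusted R2; ties (within 1e-9) go to more points, and the
    # loop visits larger k last, so >= keeps the larger window
    if (is.null(best) || adj >= best$adj_r2 - 1e-9) {
      if (is.null(best) || adj > best$adj_r2 + 1e-9 || k > best$points_used)
        best <- list(lambda_z = -unname(slope),
                     t_half = log(2) / -unname(slope),
                     points_used = k, adj_r2 = adj, defined = TRUE)
    }
  }
  if (is.null(best)) undefined else best
}

#' Non-compartmental analysis of one concentration-time profile
#'
#' Computes the standard NCA parameter set for an extravascular profile:
#' Cmax and Tmax (earliest maximum on ties), AUC0-t, the terminal rate
#' lambda_z with its half-life (see [terminal_slope()]), AUC0-inf
#' (`AUC0-t + Clast / lambda_z`), AUMC with tail extrapolation
#' (`Clast * tlast / lambda_z + Clast / lambda_z^2`) and MRT0-inf
#' (`AUMC0-inf / AUC0-inf`). When lambda_z cannot be estimated the
#' extrapolated quantities are reported as `NA`.
#'
#' @param series a [sample_series()].
#' @param loq optional lower limit of quantification passed to
#'   [terminal_slope()]; below-LOQ values still enter the AUC as observed.
#' @param auc_method integration variant, see [auc_trapezoid()].
#' @return object of class `nca_result`.
#' @export
nca_full <- function(series, loq = NULL, auc_method = "auto") {
  stopifnot(inherits(series, "sample_series"))
  pd <- post_dose(series)
  if (length(pd$times) < 2L)
    md_stop("need at least 2 post-dose samples", "nca_insufficient_data")

  i_max <- which.max(pd$conc)
  cmax <- pd$conc[i_max]
  tmax <- pd$times[i_max]

  if (all(pd$conc == 0)) {
    return(structure(list(analyte = series$analyte, subject = series$subject,
                          cmax = 0, tmax = tmax, auc_0_t = 0,
                          auc_0_inf = NA_real_, lambda_z = NA_real_,
                          t_half = NA_real_, mrt_0_inf = NA_real_,
                          lambda_z_points = 0L, lambda_z_adj_r2 = NA_real_,
                          lambda_z_defined = FALSE),
                     class = "nca_result"))
  }

  auc_t <- auc_trapezoid(series, method = auc_method)
  ts <- terminal_slope(series, loq = loq)

  # AUMC over the sampled window, same variant as the AUC
  method <- if (identical(auc_method, "auto")) {
    if (is.finite(series$interval)) "interval" else "linear"
  } else auc_method
  if (method == "interval") {
    h <- series$interval
    lo <- pmax(pd$times - h / 2, series$dose_time)
    hi <- pd$times + h / 2
    aumc_t <- sum(pd$conc * pd$times * (hi - lo))
  } else {
    tt <- pd$times; cc <- pd$conc
    if (tt[1] > series$dose_time) {
      tt <- c(series$dose_time, tt); cc <- c(0, cc)
    }
    y <- tt * cc
    aumc_t <- sum(diff(tt) * (y[-length(y)] + y[-1]) / 2)
  }

  pos <- which(pd$conc > 0)
  c_last <- pd$conc[max(pos)]
  t_last <- pd$times[max(pos)]

  if (ts$defined) {
    lz <- ts$lambda_z
    auc_inf <- auc_t + c_last / lz
    aumc_inf <- aumc_t + c_last * t_last / lz + c_last / lz^2
    mrt <- aumc_inf / auc_inf
  } else {
    auc_inf <- NA_real_
    mrt <- NA_real_
  }

  structure(list(analyte = series$analyte, subject = series$subject,
                 cmax = cmax, tmax = tmax, auc_0_t = auc_t,
                 auc_0_inf = auc_inf, lambda_z = ts$lambda_z,
                 t_half = ts$t_half, mrt_0_inf = mrt,
                 lambda_z_points = ts$points_used,
                 lambda_z_adj_r2 = ts$adj_r2,
                 lambda_z_defined = ts$defined),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("NCA: %s%s\n", x$analyte,
              if (!is.na(x$subject)) paste0(" / ", x$subject) else ""))
  cat(sprintf("  Cmax %.4g ng/mL at Tmax %g min\n", x$cmax, x$tmax))
  cat(sprintf("  AUC0-t %.6g, AUC0-inf %.6g ng.min/mL\n",
              x$auc_0_t, x$auc_0_inf))
  if (x$lambda_z_defined)
    cat(sprintf("  lambda_z %.5g /min (t1/2 %.4g min, %d pts, adjR2 %.4f); MRT %.4g min\n",
                x$lambda_z, x$t_half, x$lambda_z_points, x$lambda_z_adj_r2,
                x$mrt_0_inf))
  else cat("  lambda_z undefined\n")
  invisible(x)
}

#' @export
as.data.frame.nca_result <- function(x, ...) {
  data.frame(analyte = x$analyte, subject = as.character(x$subject),
             cmax = x$cmax, tmax = x$tmax, auc_0_t = x$auc_0_t,
             auc_0_inf = x$auc_0_inf, lambda_z = x$lambda_z,
             t_half = x$t_half, mrt_0_inf = x$mrt_0_inf,
             lambda_z_points = x$lambda_z_points,
             lambda_z_adj_r2 = x$lambda_z_adj_r2)
}
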