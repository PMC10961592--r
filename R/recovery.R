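#' In-vitro microdialysis probe recovery
#'
#' Gain-mode relative recovery: the probe is immersed in a medium of known
#' concentration and the dialysate concentration is measured, so each
#' replicate's recovery is `dialysate_conc / nominal_conc`. Results are
#' aggregated per (analyte, flow_rate, nominal_conc) cell and per
#' (analyte, flow_rate).
#'
#' Recovery should be independent of medium concentration for a passive
#' probe; a linear trend of recovery against nominal concentration larger
#' than `trend_threshold` (relative to the mean recovery, per flow rate)
#' triggers a warning rather than an error.
#'
#' @param measurements data frame with columns `analyte`, `flow_rate`
#'   (uL/min), `nominal_conc` (ng/mL, > 0), `dialysate_conc` (ng/mL, >= 0)
#'   and optionally `replicate`.
#' @param trend_threshold relative recovery change across the tested
#'   concentration span above which a concentration-dependence warning is
#'   emitted (default 0.20).
#' @return An object of class `recovery_table`: list with
#'   `by_cell` (analyte, flow_rate, nominal_conc, mean_recovery, sd, n) and
#'   `by_flow` (analyte, flow_rate, mean_recovery, sd, n).
#' @export
compute_recovery <- function(measurements, trend_threshold = 0.20) {
  req <- c("analyte", "flow_rate", "nominal_conc", "dialysate_conc")
  stopifnot(is.data.frame(measurements), all(req %in% names(measurements)))
  m <- measurements
  if (any(m$nominal_conc <= 0))
    md_stop("nominal_conc must be > 0", "recovery_invalid_nominal")
  if (any(m$flow_rate <= 0))
    md_stop("flow_rate must be > 0", "recovery_invalid_flow")
  rec <- m$dialysate_conc / m$nominal_conc
  if (any(rec > 1.2))
    md_stop("replicate recovery > 1.2: implausible (unit mismatch?)",
            "recovery_implausible")

  key <- interaction(m$analyte, m$flow_rate, m$nominal_conc, drop = TRUE)
  if (any(tabulate(key) < 3L))
    md_stop("need >= 3 replicates per (analyte, flow_rate, nominal_conc) cell",
            "recovery_insufficient_replicates")

  agg <- function(df, by) {
    sp <- split(seq_len(nrow(df)), df[by], drop = TRUE)
    rows <- lapply(sp, function(idx) {
      cbind(df[idx[1], by, drop = FALSE],
            mean_recovery = mean(rec[idx]),
            sd = sample_sd(rec[idx]), n = length(idx))
    })
    out <- do.call(rbind, rows)
    out <- out[do.call(order, out[by]), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  by_cell <- agg(m, c("analyte", "flow_rate", "nominal_conc"))
  by_flow <- agg(m, c("analyte", "flow_rate"))

  # concentration-trend check per (analyte, flow_rate)
  sp <- split(by_cell, by_cell[c("analyte", "flow_rate")], drop = TRUE)
  for (cell in sp) {
    if (nrow(cell) < 2L) next
    tr <- stats::lm(mean_recovery ~ nominal_conc, data = cell)
    span <- diff(range(cell$nominal_conc))
    rel_change <- abs(stats::coef(tr)[2] * span) / mean(cell$mean_recovery)
    if (is.finite(rel_change) && rel_change > trend_threshold)
      md_warn(sprintf(
        "recovery of %s at %.3g uL/min varies %.0f%% across tested concentrations",
        cell$analyte[1], cell$flow_rate[1], 100 * rel_change),
        "recovery_concentration_trend")
  }

  structure(list(by_cell = by_cell, by_flow = by_flow),
            class = "recovery_table")
}

#' @export
print.recovery_table <- function(x, ...) {
  cat("Probe recovery by flow rate:\n")
  print(x$by_flow, row.names = FALSE)
  invisible(x)
}

#' Select the perfusion flow rate maximizing probe recovery
#'
#' Returns the flow rate with the highest mean recovery averaged over
#' analytes; exact ties go to the lower flow rate (less fluid consumed,
#' higher analyte concentration in the dialysate).
#'
#' @param table a [compute_recovery()] result.
#' @return scalar flow rate (uL/min).
#' @export
select_flow_rate <- function(table) {
  stopifnot(inherits(table, "recovery_table"))
  bf <- table$by_flow
  if (nrow(bf) == 0L) md_stop("empty recovery table", "recovery_no_data")
  means <- tapply(bf$mean_recovery, bf$flow_rate, mean)
  rates <- as.numeric(names(means))
  best <- max(means)
  min(rates[means >= best - 1e-12])  # tie -> lower flow rate
}

#' Correct a dialysate concentration for probe recovery
#'
#' Estimates the true extracellular concentration as
#' `measured / recovery` (the inverse of the attenuation the probe
#' membrane imposes).
#'
#' @param measured dialysate concentration(s), ng/mL.
#' @param recovery relative recovery fraction in (0, 1].
#' @return corrected concentration(s).
#' @export
correct_concentration <- function(measured, recovery) {
  if (!is.numeric(recovery) || any(recovery <= 0) || any(recovery > 1))
    md_stop("recovery must be in (0, 1]", "recovery_invalid")
  measured / recovery
}
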