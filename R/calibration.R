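#' Fit a (possibly dual-range) linear calibration curve
#'
#' Ordinary least-squares regression of detector response on nominal
#' concentration, fitted separately within each concentration range.
#' Bioanalytical LC-MS methods often use two overlapping ranges (a dense
#' low range and a wide high range); both are retained and back-calculation
#' picks a range at inversion time (see [invert_calibration()]).
#'
#' @param points data frame with columns `nominal_conc` (ng/mL, > 0) and
#'   `peak_area` (detector response). An optional `replicate` column is
#'   ignored by the fit.
#' @param ranges concentration ranges to fit. Either `NULL` (one range
#'   spanning the data), a list of `c(low, high)` pairs (overlap allowed,
#'   as in dual-range methods), or a numeric vector of interior break
#'   points partitioning the span.
#' @param weighting `"none"` (default) or `"1/x2"` for 1/concentration^2
#'   weighted regression.
#' @param lod,loq optional detection/quantification limits (ng/mL) to
#'   attach to the curve; see [detection_limits()].
#' @param analyte analyte name carried through to reports.
#'
#' @return An object of class `calibration_curve`: a list with `analyte`,
#'   `ranges` (data frame: `conc_low`, `conc_high`, `slope`, `intercept`,
#'   `r_squared`, `n`), `lod`, `loq`.
#'
#' @examples
#' pts <- data.frame(nominal_conc = c(1, 2, 4), peak_area = c(10, 20, 40))
#' fit_calibration(pts)
#' @export
fit_calibration <- function(points, ranges = NULL, weighting = c("none", "1/x2"),
                            lod = NA_real_, loq = NA_real_, analyte = "") {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(points),
            all(c("nominal_conc", "peak_area") %in% names(points)))
  x <- points$nominal_conc
  y <- points$peak_area
  if (any(!is.finite(x)) || any(!is.finite(y)))
    md_stop("non-finite calibration point", "calibration_invalid_point")
  if (any(x <= 0))
    md_stop("nominal concentrations must be > 0", "calibration_invalid_point")

  range_list <- normalize_ranges(ranges, x)

  rows <- lapply(range_list, function(rg) {
    sel <- x >= rg[1] & x <= rg[2]
    xs <- x[sel]; ys <- y[sel]
    if (length(unique(xs)) < 3L)
      md_stop(sprintf("range [%g, %g] has fewer than 3 distinct concentrations",
                      rg[1], rg[2]), "calibration_underdetermined")
    if (stats::var(xs) == 0)
      md_stop("zero concentration variance in range", "calibration_degenerate_design")
    w <- if (weighting == "1/x2") 1 / xs^2 else rep(1, length(xs))
    fit <- stats::lm(ys ~ xs, weights = w)
    cf <- stats::coef(fit)
    # R^2 computed directly (summary.lm warns on exact fits)
    ybar <- sum(w * ys) / sum(w)
    sst <- sum(w * (ys - ybar)^2)
    r2 <- if (sst > 0) 1 - sum(w * stats::residuals(fit)^2) / sst else 1
    data.frame(conc_low = rg[1], conc_high = rg[2],
               slope = unname(cf[2]), intercept = unname(cf[1]),
               r_squared = r2, n = length(xs))
  })
  ranges_df <- do.call(rbind, rows)
  ranges_df <- ranges_df[order(ranges_df$conc_low, ranges_df$conc_high), ,
                         drop = FALSE]
  rownames(ranges_df) <- NULL

  structure(list(analyte = analyte, ranges = ranges_df,
                 lod = lod, loq = loq, weighting = weighting),
            class = "calibration_curve")
}

# Resolve the user-facing `ranges` argument into a list of c(low, high).
normalize_ranges <- function(ranges, x) {
  if (is.null(ranges)) return(list(range(x)))
  if (is.list(ranges)) {
    out <- lapply(ranges, function(r) {
      if (length(r) != 2L || r[1] >= r[2])
        md_stop("each range must be c(low, high) with low < high",
                "calibration_invalid_range")
      as.numeric(r)
    })
    return(out)
  }
  # numeric vector of interior break points partitioning the span
  brk <- sort(as.numeric(ranges))
  edges <- unique(c(min(x), brk, max(x)))
  if (length(edges) < 2L)
    md_stop("break points do not partition the span", "calibration_invalid_range")
  lapply(seq_len(length(edges) - 1L), function(i) c(edges[i], edges[i + 1L]))
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve%s (%d range%s)\n",
              if (nzchar(x$analyte)) paste0(" for ", x$analyte) else "",
              nrow(x$ranges), if (nrow(x$ranges) > 1) "s" else ""))
  print(x$ranges, row.names = FALSE)
  if (is.finite(x$lod)) cat(sprintf("LOD %.4g, LOQ %.4g ng/mL\n", x$lod, x$loq))
  invisible(x)
}

#' Back-calculate a concentration from a detector response
#'
#' Inverts the calibration line: `conc = (peak_area - intercept) / slope`.
#' With overlapping dual ranges the unique range whose concentration
#' interval contains the back-calculated value is used; when both contain
#' it, the lower range wins (its low end is more densely calibrated) and
#' an `overlap` flag is set. Values below the LOQ are retained but
#' flagged; negative back-calculations are clamped to zero and flagged.
#'
#' @param curve a [fit_calibration()] result.
#' @param peak_area detector response (scalar).
#' @param hint_range optional range index overriding range selection.
#' @return list with `value` (ng/mL), `range_index`, and `flags`
#'   (character vector; possible flags: `"overlap"`, `"below_loq"`,
#'   `"clamped_negative"`, `"out_of_range"`).
#' @export
invert_calibration <- function(curve, peak_area, hint_range = NULL) {
  stopifnot(inherits(curve, "calibration_curve"), is_num_scalar(peak_area))
  rg <- curve$ranges
  cand <- (peak_area - rg$intercept) / rg$slope
  flags <- character(0)

  if (!is.null(hint_range)) {
    idx <- as.integer(hint_range)
    if (idx < 1L || idx > nrow(rg))
      md_stop("hint_range out of bounds", "calibration_invalid_range")
  } else {
    inside <- which(cand >= rg$conc_low & cand <= rg$conc_high)
    if (length(inside) == 0L) {
      # outside every range: use the nearest range (lowest if below all)
      idx <- if (all(cand < rg$conc_low)) 1L else nrow(rg)
      flags <- c(flags, "out_of_range")
    } else {
      idx <- inside[1L]  # ranges sorted ascending: lower range wins
      if (length(inside) > 1L) flags <- c(flags, "overlap")
    }
  }

  value <- cand[idx]
  if (value < 0) {
    value <- 0
    flags <- c(flags, "clamped_negative")
  }
  if (is.finite(curve$loq) && value < curve$loq) flags <- c(flags, "below_loq")
  list(value = value, range_index = idx, flags = flags)
}

#' Limits of detection and quantification from slope and blank noise
#'
#' Converts a blank-region response standard deviation into concentration
#' limits via the calibration slope: the LOD is the concentration giving a
#' signal-to-noise ratio of 3 and the LOQ the concentration giving S/N of
#' 10 (the conventional k factors, overridable).
#'
#' @param slope calibration slope (response per ng/mL), > 0.
#' @param noise_sd standard deviation of the blank response, >= 0.
#' @param k_lod,k_loq S/N multipliers (defaults 3 and 10).
#' @return named numeric vector `c(lod = , loq = )` in concentration units.
#' @export
detection_limits <- function(slope, noise_sd, k_lod = 3, k_loq = 10) {
  if (!is_num_scalar(slope) || slope <= 0)
    md_stop("slope must be a positive scalar", "calibration_invalid_slope")
  if (!is_num_scalar(noise_sd) || noise_sd < 0)
    md_stop("noise_sd must be >= 0", "calibration_invalid_noise")
  c(lod = k_lod * noise_sd / slope, loq = k_loq * noise_sd / slope)
}

#' Quality-control concentration levels from the quantification range
#'
#' Standard bioanalytical QC placement: low = 3 x LLOQ, medium = 40% of
#' the ULOQ, high = 80% of the ULOQ.
#'
#' @param lloq,uloq lower/upper limit of quantification (ng/mL), 0 < lloq < uloq.
#' @return named numeric vector `c(low =, medium =, high =)`; if the low
#'   level reaches or exceeds the medium level an `overlap` attribute is
#'   set to `TRUE` and a warning emitted.
#' @export
qc_levels <- function(lloq, uloq) {
  if (!is_num_scalar(lloq) || !is_num_scalar(uloq) || lloq <= 0 || lloq >= uloq)
    md_stop("need 0 < lloq < uloq", "qc_invalid_limits")
  out <- c(low = 3 * lloq, medium = 0.4 * uloq, high = 0.8 * uloq)
  overlap <- out[["low"]] >= out[["medium"]]
  if (overlap)
    md_warn("QC low level (3 x LLOQ) >= medium level (40% ULOQ)", "qc_overlap")
  attr(out, "overlap") <- overlap
  out
}

#' Replicate precision (RSD) and accuracy (RE)
#'
#' RSD = 100 * sd / mean over the replicates (n-1 sample standard
#' deviation); RE = 100 * (mean - nominal) / nominal.
#'
#' @param measured numeric vector of back-calculated concentrations (>= 3).
#' @param nominal nominal (spiked) concentration, > 0.
#' @return named numeric vector `c(rsd_percent =, re_percent =)`.
#' @export
precision_accuracy <- function(measured, nominal) {
  if (length(measured) < 3L)
    md_stop("need at least 3 replicates", "qc_insufficient_replicates")
  if (!is_num_scalar(nominal) || nominal <= 0)
    md_stop("nominal must be > 0", "qc_invalid_nominal")
  m <- mean(measured)
  if (m == 0) md_stop("mean of measurements is zero; RSD undefined",
                      "qc_undefined_rsd")
  c(rsd_percent = 100 * sample_sd(measured) / m,
    re_percent = 100 * (m - nominal) / nominal)
}

#' Matrix effect of a biological matrix on detector response
#'
#' Ratio (x100) of the mean analyte response in matrix (e.g. blank brain
#' dialysate) to the mean response in clean reference solvent (aCSF),
#' with the between-replicate spread of the per-replicate ratios.
#'
#' @param area_in_matrix,area_in_reference numeric response vectors
#'   (>= 3 each). When lengths match, per-replicate ratios pair up
#'   positionally; otherwise the ratio SD is computed against the
#'   reference mean.
#' @return named numeric vector `c(me_percent =, sd_percent =, n =)`.
#' @export
matrix_effect <- function(area_in_matrix, area_in_reference) {
  if (length(area_in_matrix) < 3L || length(area_in_reference) < 3L)
    md_stop("need at least 3 replicates in each condition",
            "qc_insufficient_replicates")
  ref_mean <- mean(area_in_reference)
  if (ref_mean <= 0)
    md_stop("reference mean response must be > 0", "qc_invalid_reference")
  ratios <- if (length(area_in_matrix) == length(area_in_reference)) {
    area_in_matrix / area_in_reference
  } else {
    area_in_matrix / ref_mean
  }
  c(me_percent = 100 * mean(area_in_matrix) / ref_mean,
    sd_percent = 100 * sample_sd(ratios),
    n = length(area_in_matrix))
}

#' QC precision/accuracy report over a tidy QC table
#'
#' Aggregates [precision_accuracy()] over (analyte, level, day) cells of a
#' quality-control table, the layout used for intra-/inter-day validation.
#'
#' @param qc data frame with columns `analyte`, `level`, `day`,
#'   `nominal_conc`, `measured_conc`.
#' @return data frame with one row per (analyte, level, day):
#'   `rsd_percent`, `re_percent`, `n_replicates`.
#' @export
qc_report <- function(qc) {
  stopifnot(is.data.frame(qc),
            all(c("analyte", "level", "day", "nominal_conc", "measured_conc")
                %in% names(qc)))
  keys <- unique(qc[c("analyte", "level", "day")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- qc$analyte == k$analyte & qc$level == k$level & qc$day == k$day
    pa <- precision_accuracy(qc$measured_conc[sel],
                             unique(qc$nominal_conc[sel])[1])
    cbind(k, rsd_percent = pa[["rsd_percent"]],
          re_percent = pa[["re_percent"]], n_replicates = sum(sel))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
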