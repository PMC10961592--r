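#' Construct a concentration-time sample series
#'
#' Container for one subject/analyte concentration-time profile.
#' Microdialysis samples are interval averages over the collection window;
#' each sample is assigned to its window midpoint, and the window width is
#' carried in `interval` so downstream AUC integration can treat samples
#' as interval averages (exact for piecewise integration) rather than
#' point observations.
#'
#' @param times sample times in minutes (interval midpoints), strictly
#'   increasing.
#' @param conc concentrations in ng/mL, all >= 0.
#' @param analyte analyte name.
#' @param subject subject/group identifier.
#' @param dose_time dosing time in minutes (default 0); must not exceed
#'   the first post-dose time.
#' @param interval collection-window width in minutes, or `NA` for point
#'   (instantaneous) samples.
#' @param baseline_window optional `c(t_start, t_end)` marking the
#'   pre-dose baseline collection.
#' @return object of class `sample_series`.
#' @export
sample_series <- function(times, conc, analyte = "", subject = NA,
                          dose_time = 0, interval = NA_real_,
                          baseline_window = NULL) {
  times <- as.numeric(times); conc <- as.numeric(conc)
  if (length(times) != length(conc))
    md_stop("times and conc lengths differ", "series_invalid")
  if (length(times) && any(diff(times) <= 0))
    md_stop("times must be strictly increasing", "series_invalid")
  if (any(!is.finite(conc)) || any(conc < 0))
    md_stop("concentrations must be finite and >= 0", "series_invalid")
  post <- times[times >= dose_time]
  if (length(post) == 0L && length(times))
    md_stop("no samples at or after dose_time", "series_invalid")
  structure(list(times = times, conc = conc, analyte = analyte,
                 subject = subject, dose_time = dose_time,
                 interval = interval, baseline_window = baseline_window),
            class = "sample_series")
}

#' @export
print.sample_series <- function(x, ...) {
  cat(sprintf("sample_series: %s%s, %d samples, t = [%g, %g] min%s\n",
              x$analyte, if (!is.na(x$subject)) paste0(" / ", x$subject) else "",
              length(x$times),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA,
              if (!is.na(x$interval)) sprintf(" (%g-min windows)", x$interval)
              else ""))
  invisible(x)
}

# Subset of a series at/after dose time, as a plain list.
post_dose <- function(series) {
  sel <- series$times >= series$dose_time
  list(times = series$times[sel], conc = series$conc[sel])
}

#' Read a tidy dialysate concentration table
#'
#' Expects the long CSV layout `analyte, group, subject, t_min,
#' conc_ng_ml` (extra columns are preserved). Errors name any missing
#' required column.
#'
#' @param path CSV file path.
#' @param required required column names.
#' @return data frame.
#' @export
read_dialysate_csv <- function(path,
                               required = c("analyte", "group", "subject",
                                            "t_min", "conc_ng_ml")) {
  if (!file.exists(path))
    md_stop(sprintf("file not found: %s", path), "io_missing_file")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    md_stop(sprintf("missing required column(s): %s",
                    paste(missing, collapse = ", ")), "io_schema_error")
  df
}

#' Write a data frame as CSV with stable numeric formatting
#'
#' Floating-point columns are written with 9 significant digits so that
#' re-runs under identical seeds produce byte-identical files.
#'
#' @param df data frame.
#' @param path output path.
#' @export
write_table_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
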