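# End-to-end analysis pipeline: recovery -> correction -> NCA ->
# compartmental PK -> baseline-normalized PD -> effect-compartment link ->
# hysteresis. Operates on group-mean profiles (the pooled time-average
# mode of the underlying study design); every stage is also exported on
# its own for per-subject work.

# Average a tidy long table into one sample_series per (analyte, group).
group_mean_series <- function(df, interval = NA_real_, dose_time = 0) {
  keys <- unique(df[c("analyte", "group")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- df$analyte == keys$analyte[i] & df$group == keys$group[i]
    sub <- df[sel, ]
    m <- tapply(sub$conc_ng_ml, sub$t_min, mean)
    out[[paste(keys$analyte[i], keys$group[i], sep = "|")]] <-
      sample_series(as.numeric(names(m)), as.numeric(m),
                    analyte = keys$analyte[i], subject = keys$group[i],
                    dose_time = dose_time, interval = interval)
  }
  out
}

# Infer the PD mode from the post-dose deviation of the normalized effect.
infer_pd_mode <- function(effect_series) {
  post <- effect_series$times >= effect_series$dose_time
  if (mean(effect_series$effect[post]) < 100) "inhibition" else "stimulation"
}

#' Run the full microdialysis PK-PD pipeline
#'
#' Stages, in order: (1) in-vitro probe recovery and flow-rate selection;
#' (2) recovery correction of dialysate lignan concentrations (optional,
#' on by default); (3) NCA per (lignan, group) on group-mean profiles;
#' (4) one- and two-compartment fits with AIC selection; (5) baseline
#' normalization of neurotransmitter series and effect-compartment link
#' fitting against the index lignan's selected PK model, with the PD mode
#' (stimulation/inhibition) inferred from the post-dose effect direction;
#' (6) hysteresis-loop quantification of each (index lignan,
#' neurotransmitter, group) concentration-effect trajectory.
#'
#' @param experiment a [generate_experiment()] result, or a list with
#'   elements `lignans`, `neurotransmitters`, `recovery` (tidy data
#'   frames as documented there) and `config` (needs `interval`, `dose`,
#'   `index_analyte`).
#' @param correct_recovery divide dialysate concentrations by the
#'   estimated probe recovery before PK analysis (default `TRUE`).
#' @param analytes optional subset of lignans to analyse.
#' @param weighting residual weighting for [fit_pk()].
#' @param n_restarts restarts per PK fit.
#' @param seed RNG seed for fit restarts.
#' @return list with `flow_rate`, `recovery_by_flow`, `recovery_used`,
#'   `nca` (data frame), `pk_fits` (list, selected fit per
#'   analyte|group), `pk_table`, `link_fits`, `link_table`,
#'   `hysteresis` (data frame) and `manifest`.
#' @export
run_pipeline <- function(experiment, correct_recovery = TRUE,
                         analytes = NULL, weighting = "uniform",
                         n_restarts = 4, seed = 1L) {
  cfg <- experiment$config
  interval <- cfg$interval
  dose <- cfg$dose
  index_analyte <- cfg$index_analyte

  rec <- compute_recovery(experiment$recovery)
  flow <- select_flow_rate(rec)
  bf <- rec$by_flow[rec$by_flow$flow_rate == flow, ]
  rec_used <- stats::setNames(bf$mean_recovery, bf$analyte)

  lig <- experiment$lignans
  if (!is.null(analytes)) lig <- lig[lig$analyte %in% analytes, ]
  if (correct_recovery) {
    lig$conc_ng_ml <- correct_concentration(
      lig$conc_ng_ml, rec_used[lig$analyte])
  }

  series <- group_mean_series(lig, interval = interval)
  message(sprintf("pipeline: %d lignan series (%d rows in), flow rate %g uL/min",
                  length(series), nrow(lig), flow))

  nca_rows <- list(); pk_fits <- list(); pk_rows <- list()
  for (key in names(series)) {
    s <- series[[key]]
    nca_rows[[key]] <- as.data.frame(nca_full(s))
    fits <- list(fit_pk(s, "1C", dose = dose, weighting = weighting,
                        n_restarts = n_restarts, seed = seed),
                 fit_pk(s, "2C", dose = dose, weighting = weighting,
                        n_restarts = n_restarts, seed = seed + 1L))
    best <- select_model(fits)
    pk_fits[[key]] <- best
    pk_rows[[key]] <- data.frame(
      analyte = s$analyte, group = s$subject, model_id = best$model_id,
      ka = best$params$ka,
      ke = if (best$model_id == "1C") best$params$ke else best$params$beta,
      aic = best$scores$aic, bic = best$scores$bic, ssr = best$scores$ssr)
  }
  nca_table <- do.call(rbind, c(nca_rows, list(make.row.names = FALSE)))
  names(nca_table)[names(nca_table) == "subject"] <- "group"
  pk_table <- do.call(rbind, c(pk_rows, list(make.row.names = FALSE)))

  # neurotransmitter link fits against the index lignan
  nt <- experiment$neurotransmitters
  nt_series <- group_mean_series(nt, interval = interval)
  link_fits <- list(); link_rows <- list(); hys_rows <- list()
  for (key in names(nt_series)) {
    s <- nt_series[[key]]
    grp <- s$subject
    eff <- normalize_effect(s)
    mode <- infer_pd_mode(eff)
    pk_key <- paste(index_analyte, grp, sep = "|")
    if (!pk_key %in% names(pk_fits)) next
    lf <- fit_link(eff, pk_fits[[pk_key]], mode = mode, dose = dose)
    link_fits[[key]] <- lf
    link_rows[[key]] <- data.frame(
      neurotransmitter = s$analyte, group = grp, lignan = index_analyte,
      mode = mode, ke0 = lf$ke0, e0 = lf$pd$e0,
      emax = if (mode == "stimulation") lf$pd$emax else NA_real_,
      imax = if (mode == "inhibition") lf$pd$imax else NA_real_,
      c50 = lf$pd$c50, hill_n = lf$pd$hill_n, aic = lf$scores$aic)

    # observed loop: group-mean index-lignan concentration vs effect
    ls <- series[[pk_key]]
    shared <- intersect(ls$times[ls$times >= 0], eff$times[eff$times >= 0])
    x <- ls$conc[match(shared, ls$times)]
    y <- eff$effect[match(shared, eff$times)]
    hl <- hysteresis_loop(x, y, times = shared)
    hys_rows[[key]] <- data.frame(
      neurotransmitter = s$analyte, group = grp, lignan = index_analyte,
      mode = mode, signed_area = hl$signed_area,
      normalized_area = hl$normalized_area, direction = hl$direction,
      label = classify_relationship(hl, mode))
  }
  link_table <- do.call(rbind, c(link_rows, list(make.row.names = FALSE)))
  hysteresis <- do.call(rbind, c(hys_rows, list(make.row.names = FALSE)))

  manifest <- list(
    package = "mdpkpd",
    version = as.character(utils::packageVersion("mdpkpd")),
    seed = seed,
    options = list(correct_recovery = correct_recovery,
                   weighting = weighting, n_restarts = n_restarts,
                   auc_method = "interval", baseline_rule = "first",
                   index_analyte = index_analyte),
    flow_rate = flow,
    recovery_used = as.list(rec_used))

  list(flow_rate = flow, recovery_by_flow = rec$by_flow,
       recovery_used = rec_used, nca = nca_table, pk_fits = pk_fits,
       pk_table = pk_table, link_fits = link_fits, link_table = link_table,
       hysteresis = hysteresis, manifest = manifest)
}

#' Write a pipeline run's tables and manifest to a directory
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(result$nca, file.path(dir, "nca.csv"))
  write_table_csv(result$pk_table, file.path(dir, "pk_fits.csv"))
  write_table_csv(result$link_table, file.path(dir, "link_fits.csv"))
  write_table_csv(result$hysteresis, file.path(dir, "hysteresis.csv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
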