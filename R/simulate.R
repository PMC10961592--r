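# Synthetic microdialysis experiments with known ground truth.
#
# The generator emulates the study design the analysis modules expect:
# oral dosing at t = 0, dialysate collected as consecutive 20-min
# interval averages over 480 min after one pre-dose baseline window,
# probe-recovery attenuation of every measured concentration, three
# animal groups (healthy control BLA, disease model ADM, treated SCH)
# with group-scaled exposure, and neurotransmitter effects produced by a
# sigmoid Emax/Imax response driven through an effect compartment.

default_lignan_truth <- function() {
  list(
    list(name = "schisandrol A",     ka = 0.045, ke = 0.009, v_f = 0.020),
    list(name = "schisandrol B",     ka = 0.040, ke = 0.010, v_f = 0.033),
    list(name = "schisantherin A",   ka = 0.035, ke = 0.008, v_f = 0.050),
    list(name = "schisantherin B",   ka = 0.050, ke = 0.012, v_f = 0.040),
    list(name = "angeloylgomisin H", ka = 0.030, ke = 0.007, v_f = 0.045),
    list(name = "angeloylgomisin Q", ka = 0.055, ke = 0.011, v_f = 0.080),
    list(name = "gomisin K",         ka = 0.038, ke = 0.009, v_f = 0.060),
    list(name = "schisanhenol",      ka = 0.042, ke = 0.010, v_f = 0.100)
  )
}

default_nt_truth <- function() {
  list(
    list(name = "Asp", mode = "inhibition",  e0 = 100, imax = 0.50,
         c50 = 30, hill_n = 1.5, ke0 = 0.020, baseline_raw = 250,
         group_baseline = c(BLA = 1.00, ADM = 1.40, SCH = 1.15)),
    list(name = "Glu", mode = "inhibition",  e0 = 100, imax = 0.40,
         c50 = 25, hill_n = 1.2, ke0 = 0.015, baseline_raw = 800,
         group_baseline = c(BLA = 1.00, ADM = 1.35, SCH = 1.10)),
    list(name = "Tau", mode = "stimulation", e0 = 100, emax = 60,
         c50 = 20, hill_n = 1.5, ke0 = 0.020, baseline_raw = 400,
         group_baseline = c(BLA = 1.00, ADM = 0.70, SCH = 0.85)),
    list(name = "Ach", mode = "stimulation", e0 = 100, emax = 80,
         c50 = 35, hill_n = 2.0, ke0 = 0.030, baseline_raw = 5,
         group_baseline = c(BLA = 1.00, ADM = 0.65, SCH = 0.80))
  )
}

default_recovery_truth <- function() {
  c("schisandrol A" = 0.28, "schisandrol B" = 0.24,
    "schisantherin A" = 0.21, "schisantherin B" = 0.26,
    "angeloylgomisin H" = 0.19, "angeloylgomisin Q" = 0.31,
    "gomisin K" = 0.23, "schisanhenol" = 0.29)
}

#' Configuration of a synthetic microdialysis experiment
#'
#' Defaults reproduce the study conditions the analysis pipeline targets:
#' 20-min collection windows over 480 min post dose with one pre-dose
#' baseline window, three groups (healthy control `BLA`, disease model
#' `ADM`, lignan-treated `SCH`), eight detectable lignans following
#' one-compartment oral-absorption kinetics, probe recoveries between 0.19
#' and 0.31, and four neurotransmitters (excitatory Asp/Glu suppressed,
#' Tau/Ach enhanced) responding to the effect-site concentration of the
#' index lignan. Group exposure multipliers give the disease model the
#' highest lignan exposure (`ADM > SCH > BLA`), and group baseline
#' multipliers raise Asp/Glu and lower Tau/Ach in the disease model.
#'
#' @param seed integer RNG seed; every per-series stream derives from it.
#' @param n_subjects subjects per group.
#' @param groups group labels.
#' @param interval collection-window width (min).
#' @param horizon post-dose sampling horizon (min); must be a multiple of
#'   `interval`.
#' @param n_baseline number of pre-dose baseline windows.
#' @param dose administered dose (arbitrary dose units; concentrations
#'   scale as dose / v_f).
#' @param lignans list of per-lignan truth (name, ka, ke, v_f).
#' @param neurotransmitters list of per-neurotransmitter truth (name,
#'   mode, e0, emax or imax, c50, hill_n, ke0, baseline_raw,
#'   group_baseline multipliers).
#' @param recovery named vector of per-lignan probe recovery fractions.
#' @param group_exposure named multipliers on lignan exposure
#'   (concentration scale) per group.
#' @param index_analyte lignan whose effect-site concentration drives the
#'   neurotransmitter responses.
#' @param noise_cv proportional noise coefficient of variation.
#' @param noise_floor additive noise standard deviation (ng/mL).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_subjects = 6L,
                              groups = c("BLA", "ADM", "SCH"),
                              interval = 20, horizon = 480,
                              n_baseline = 1L, dose = 1,
                              lignans = default_lignan_truth(),
                              neurotransmitters = default_nt_truth(),
                              recovery = default_recovery_truth(),
                              group_exposure = c(BLA = 1.0, ADM = 1.8,
                                                 SCH = 1.4),
                              index_analyte = "schisandrol A",
                              noise_cv = 0.10, noise_floor = 0.02) {
  if (horizon %% interval != 0)
    md_stop("interval must divide horizon", "sim_invalid_config")
  if (any(recovery <= 0) || any(recovery > 1))
    md_stop("recovery truth must lie in (0, 1]", "sim_invalid_config")
  lig_names <- vapply(lignans, `[[`, "", "name")
  if (!index_analyte %in% lig_names)
    md_stop("index_analyte must be one of the configured lignans",
            "sim_invalid_config")
  if (!all(lig_names %in% names(recovery)))
    md_stop("every lignan needs a recovery truth entry", "sim_invalid_config")
  if (!all(groups %in% names(group_exposure)))
    md_stop("every group needs an exposure multiplier", "sim_invalid_config")
  for (nt in neurotransmitters) {
    if (!all(groups %in% names(nt$group_baseline)))
      md_stop(sprintf("%s lacks a baseline multiplier for some group", nt$name),
              "sim_invalid_config")
  }
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 groups = groups, interval = interval, horizon = horizon,
                 n_baseline = as.integer(n_baseline), dose = dose,
                 lignans = lignans, neurotransmitters = neurotransmitters,
                 recovery = recovery, group_exposure = group_exposure,
                 index_analyte = index_analyte,
                 noise_cv = noise_cv, noise_floor = noise_floor),
            class = "simulation_config")
}

# seed for one simulated series, independent of the other series
series_seed <- function(seed, key) {
  as.integer((as.numeric(seed) * 100003 + str_hash(key)) %% 2147483647)
}

sampling_windows <- function(config) {
  h <- config$interval
  starts <- seq(-config$n_baseline * h, config$horizon - h, by = h)
  data.frame(t0 = starts, t1 = starts + h, mid = starts + h / 2)
}

#' Simulate one interval-averaged dialysate sample
#'
#' The probe reports the average concentration over the collection window
#' attenuated by its relative recovery; proportional and additive noise
#' are then applied (`value (1 + cv z) + floor z'`, truncated at zero).
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param params PK truth ([pk1c_params()] or [pk2c_params()]).
#' @param dose administered dose.
#' @param window `c(t0, t1)` collection window (min, relative to dose at 0).
#' @param recovery probe recovery fraction in (0, 1].
#' @param noise_cv,noise_floor noise magnitudes (0 for noise-free).
#' @return one dialysate concentration (ng/mL).
#' @export
simulate_pk_sample <- function(params, dose, window, recovery = 1,
                               noise_cv = 0, noise_floor = 0) {
  if (window[2] <= window[1]) md_stop("need t1 > t0", "sim_invalid_window")
  if (window[2] <= 0) return(apply_noise(0, noise_cv, noise_floor))
  t0 <- max(window[1], 0)
  avg <- predict_conc_interval(params, t0, window[2], dose) *
    (window[2] - t0) / (window[2] - window[1])
  apply_noise(avg * recovery, noise_cv, noise_floor)
}

apply_noise <- function(value, noise_cv, noise_floor) {
  if (noise_cv > 0) value <- value * (1 + noise_cv * stats::rnorm(1))
  if (noise_floor > 0) value <- value + noise_floor * stats::rnorm(1)
  max(value, 0)
}

#' Simulate one neurotransmitter effect sample
#'
#' Effect at the window midpoint under the effect-compartment link:
#' `pd_predict(pd, Ce(mid))` for post-dose windows, the baseline `e0` for
#' pre-dose windows, with multiplicative noise.
#'
#' @param pd PD truth ([pd_params()]).
#' @param ke0 effect-compartment rate (1/min).
#' @param pk_params PK truth of the driving analyte.
#' @param dose administered dose.
#' @param window `c(t0, t1)` collection window (min).
#' @param noise_cv proportional noise CV (0 for noise-free).
#' @return effect in percent of baseline.
#' @export
simulate_effect_sample <- function(pd, ke0, pk_params, dose, window,
                                   noise_cv = 0) {
  mid <- mean(window)
  e <- if (mid < 0) pd$e0
       else pd_predict(pd, effect_compartment_conc(pk_params, ke0, mid, dose))
  if (noise_cv > 0) e <- e * (1 + noise_cv * stats::rnorm(1))
  max(e, 0)
}

#' Generate a complete synthetic microdialysis experiment
#'
#' Produces every table the analysis pipeline consumes, in the tidy CSV
#' schemas of the analysis modules, plus the full ground truth:
#' \itemize{
#'   \item `lignans`: dialysate lignan concentrations (analyte, group,
#'     subject, t_min, conc_ng_ml), recovery-attenuated and noised;
#'   \item `neurotransmitters`: raw neurotransmitter dialysate
#'     concentrations whose baseline differs by group;
#'   \item `calibration`: peak-area calibration points per lignan over a
#'     dual range (1-100 and 10-1000 ng/mL);
#'   \item `recovery`: in-vitro probe-recovery measurements over flow
#'     rates 1, 2, 3 uL/min at 100/500/1000 ng/mL, with recovery maximal
#'     at 2 uL/min;
#'   \item `truth`: per-series PK truth (with closed-form Cmax/Tmax/AUC),
#'     normalized PD truth and recovery/flow-rate truth.
#' }
#' Each (group, subject, analyte) series draws from its own RNG stream
#' derived from the config seed, so regeneration is deterministic and
#' adding analytes does not perturb existing series.
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_experiment`.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  win <- sampling_windows(config)
  lig_rows <- list()
  nt_rows <- list()
  truth_pk <- list()

  for (g in config$groups) {
    mult <- config$group_exposure[[g]]
    for (s in seq_len(config$n_subjects)) {
      subj <- sprintf("%s_%02d", g, s)
      for (lg in config$lignans) {
        params <- pk1c_params(lg$ka, lg$ke, lg$v_f / mult)
        set.seed(series_seed(config$seed, paste("pk", g, s, lg$name)))
        conc <- vapply(seq_len(nrow(win)), function(i)
          simulate_pk_sample(params, config$dose, c(win$t0[i], win$t1[i]),
                             recovery = config$recovery[[lg$name]],
                             noise_cv = config$noise_cv,
                             noise_floor = config$noise_floor), numeric(1))
        lig_rows[[length(lig_rows) + 1L]] <- data.frame(
          analyte = lg$name, group = g, subject = subj,
          t_min = win$mid, conc_ng_ml = conc)
      }
      idx <- config$lignans[[
        which(vapply(config$lignans, `[[`, "", "name") == config$index_analyte)]]
      drive <- pk1c_params(idx$ka, idx$ke, idx$v_f / mult)
      for (nt in config$neurotransmitters) {
        pd <- pd_params(nt$mode, e0 = nt$e0, emax = nt$emax, imax = nt$imax,
                        c50 = nt$c50, hill_n = nt$hill_n)
        base <- nt$baseline_raw * nt$group_baseline[[g]]
        set.seed(series_seed(config$seed, paste("nt", g, s, nt$name)))
        eff <- vapply(seq_len(nrow(win)), function(i)
          simulate_effect_sample(pd, nt$ke0, drive, config$dose,
                                 c(win$t0[i], win$t1[i]),
                                 noise_cv = config$noise_cv), numeric(1))
        nt_rows[[length(nt_rows) + 1L]] <- data.frame(
          analyte = nt$name, group = g, subject = subj,
          t_min = win$mid, conc_ng_ml = base * eff / 100)
      }
    }
    # closed-form per-(lignan, group) truth
    for (lg in config$lignans) {
      vf <- lg$v_f / mult
      tmax <- log(lg$ka / lg$ke) / (lg$ka - lg$ke)
      A <- config$dose * lg$ka / (vf * (lg$ka - lg$ke))
      truth_pk[[paste(lg$name, g, sep = "|")]] <- list(
        analyte = lg$name, group = g, ka = lg$ka, ke = lg$ke, v_f = vf,
        tmax = tmax,
        cmax = A * (exp(-lg$ke * tmax) - exp(-lg$ka * tmax)),
        auc_0_inf = config$dose / (vf * lg$ke))
    }
  }

  structure(list(
    config = config,
    lignans = do.call(rbind, lig_rows),
    neurotransmitters = do.call(rbind, nt_rows),
    calibration = simulate_calibration_table(config),
    recovery = simulate_recovery_table(config),
    truth = list(pk = truth_pk,
                 pd = config$neurotransmitters,
                 recovery = config$recovery,
                 best_flow_rate = 2.0)),
    class = "synthetic_experiment")
}

# Dual-range calibration points (1-100 and 10-1000 ng/mL) per lignan;
# detector response noise is one tenth of the experiment's proportional
# noise (LC-MS response repeatability is much tighter than in-vivo
# sampling variability). Slope differs by analyte.
simulate_calibration_table <- function(config) {
  low <- c(1, 2, 5, 10, 50, 100)
  high <- c(10, 50, 100, 250, 500, 1000)
  rows <- list()
  for (k in seq_along(config$lignans)) {
    lg <- config$lignans[[k]]
    slope <- 40 + 10 * k
    set.seed(series_seed(config$seed, paste("cal", lg$name)))
    for (conc in c(low, high)) {
      for (rep in 1:3) {
        area <- slope * conc * (1 + 0.1 * config$noise_cv * stats::rnorm(1))
        rows[[length(rows) + 1L]] <- data.frame(
          analyte = lg$name, nominal_conc = conc, peak_area = area,
          replicate = rep,
          range = if (conc %in% low && !(conc %in% high)) "low"
                  else if (conc %in% high && !(conc %in% low)) "high"
                  else "both")
      }
    }
  }
  do.call(rbind, rows)
}

# In-vitro recovery measurements: recovery peaks at 2 uL/min (the probe's
# operating point) and falls off at 1 and 3 uL/min. Replicate scatter
# follows the experiment's proportional noise level.
simulate_recovery_table <- function(config) {
  flow_shape <- c(`1` = 0.80, `2` = 1.00, `3` = 0.60)
  nominals <- c(100, 500, 1000)
  rows <- list()
  for (lg in config$lignans) {
    r0 <- config$recovery[[lg$name]]
    set.seed(series_seed(config$seed, paste("rec", lg$name)))
    for (fr in c(1, 2, 3)) {
      for (nom in nominals) {
        for (rep in 1:3) {
          r <- r0 * flow_shape[[as.character(fr)]] *
            (1 + 0.4 * config$noise_cv * stats::rnorm(1))
          rows[[length(rows) + 1L]] <- data.frame(
            analyte = lg$name, flow_rate = fr, nominal_conc = nom,
            dialysate_conc = max(nom * r, 0), replicate = rep)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf(
    "Synthetic microdialysis experiment (seed %d): %d groups x %d subjects\n",
    x$config$seed, length(x$config$groups), x$config$n_subjects))
  cat(sprintf("  %d lignan series rows, %d neurotransmitter rows\n",
              nrow(x$lignans), nrow(x$neurotransmitters)))
  invisible(x)
}

#' Write all tables of a synthetic experiment to a directory
#'
#' @param experiment a [generate_experiment()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(experiment$lignans, file.path(dir, "lignans.csv"))
  write_table_csv(experiment$neurotransmitters,
                  file.path(dir, "neurotransmitters.csv"))
  write_table_csv(experiment$calibration, file.path(dir, "calibration.csv"))
  write_table_csv(experiment$recovery, file.path(dir, "recovery.csv"))
  cfg <- experiment$config
  cfg_json <- list(seed = cfg$seed, n_subjects = cfg$n_subjects,
                   groups = cfg$groups, interval = cfg$interval,
                   horizon = cfg$horizon, n_baseline = cfg$n_baseline,
                   dose = cfg$dose, index_analyte = cfg$index_analyte,
                   noise_cv = cfg$noise_cv, noise_floor = cfg$noise_floor)
  jsonlite::write_json(cfg_json, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
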