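small_config <- function(...) {
  simulation_config(seed = 11, n_subjects = 2, ...)
}

test_that("regeneration under the same seed is byte-identical", {
  e1 <- generate_experiment(small_config())
  e2 <- generate_experiment(small_config())
  expect_identical(e1$lignans, e2$lignans)
  expect_identical(e1$neurotransmitters, e2$neurotransmitters)
  expect_identical(e1$calibration, e2$calibration)
  expect_identical(e1$recovery, e2$recovery)

  d1 <- file.path(tempdir(), "exp_a"); d2 <- file.path(tempdir(), "exp_b")
  write_experiment(e1, d1); write_experiment(e2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("a different seed changes the noise realization", {
  e1 <- generate_experiment(small_config())
  e3 <- generate_experiment(simulation_config(seed = 12, n_subjects = 2))
  expect_false(identical(e1$lignans$conc_ng_ml, e3$lignans$conc_ng_ml))
})

test_that("the sampling design matches the study layout", {
  e <- generate_experiment(small_config())
  one <- subset(e$lignans, analyte == "schisandrol A" & subject == "BLA_01")
  expect_equal(sum(one$t_min > 0), 24L)         # 480 / 20 post-dose windows
  expect_equal(sum(one$t_min < 0), 1L)          # one baseline window
  expect_equal(length(unique(e$lignans$analyte)), 8L)
  expect_equal(length(unique(e$neurotransmitters$analyte)), 4L)
  expect_equal(sort(unique(e$lignans$group)), c("ADM", "BLA", "SCH"))
})

test_that("interval samples equal the analytic window average", {
  p <- pk1c_params(0.045, 0.009, 0.02)
  got <- simulate_pk_sample(p, 1, c(40, 60), recovery = 0.25)
  quad <- stats::integrate(function(t) predict_conc(p, t), 40, 60,
                           rel.tol = 1e-12)$value / 20
  expect_equal(got, 0.25 * quad, tolerance = 1e-8)

  # window straddling the dose: only the post-dose part contributes
  strad <- simulate_pk_sample(p, 1, c(-10, 10))
  quad2 <- stats::integrate(function(t) predict_conc(p, t), 0, 10,
                            rel.tol = 1e-12)$value / 20
  expect_equal(strad, quad2, tolerance = 1e-8)
})

test_that("effect samples are baseline pre-dose and shifted post-dose", {
  pd <- pd_params("stimulation", e0 = 100, emax = 60, c50 = 20, hill_n = 1.5)
  pk <- pk1c_params(0.045, 0.009, 0.02)
  expect_equal(simulate_effect_sample(pd, 0.02, pk, 1, c(-20, 0)), 100)
  post <- vapply(seq(0, 460, 20), function(t0)
    simulate_effect_sample(pd, 0.02, pk, 1, c(t0, t0 + 20)), numeric(1))
  expect_gt(max(post), 100)

  inhib <- pd_params("inhibition", e0 = 100, imax = 0.5, c50 = 30,
                     hill_n = 1.5)
  post_i <- vapply(seq(0, 460, 20), function(t0)
    simulate_effect_sample(inhib, 0.02, pk, 1, c(t0, t0 + 20)), numeric(1))
  # minimum effect matches the closed form at the effect-site peak, up to
  # the 20-min sampling resolution around the peak
  ce <- effect_compartment_conc(pk, 0.02, seq(0, 480, 0.1))
  expect_equal(min(post_i), pd_predict(inhib, max(ce)), tolerance = 0.01)
})

test_that("noise-free simulation reproduces closed-form NCA truth", {
  cfg <- simulation_config(seed = 5, n_subjects = 1, noise_cv = 0,
                           noise_floor = 0,
                           recovery = setNames(rep(1, 8),
                                               names(mdpkpd:::default_recovery_truth())))
  e <- generate_experiment(cfg)
  one <- subset(e$lignans, analyte == "schisandrol A" & group == "BLA")
  s <- sample_series(one$t_min[one$t_min > 0], one$conc_ng_ml[one$t_min > 0],
                     interval = 20)
  res <- nca_full(s)
  truth <- e$truth$pk[["schisandrol A|BLA"]]
  expect_equal(res$auc_0_t + res$cmax / res$lambda_z * 0, res$auc_0_t)
  expect_equal(res$auc_0_inf, truth$auc_0_inf, tolerance = 0.01)
  expect_equal(res$cmax, truth$cmax, tolerance = 0.02)  # window averaging
  expect_lte(abs(res$tmax - truth$tmax), 20)
  expect_equal(res$lambda_z, truth$ke, tolerance = 0.02)
})

test_that("group exposure ordering is ADM > SCH > BLA", {
  cfg <- simulation_config(seed = 6, n_subjects = 1, noise_cv = 0,
                           noise_floor = 0)
  e <- generate_experiment(cfg)
  auc_of <- function(g) {
    d <- subset(e$lignans, analyte == "schisandrol A" & group == g &
                  t_min > 0)
    auc_trapezoid(sample_series(d$t_min, d$conc_ng_ml, interval = 20))
  }
  expect_gt(auc_of("ADM"), auc_of("SCH"))
  expect_gt(auc_of("SCH"), auc_of("BLA"))
})

test_that("simulated calibration and recovery tables carry their truth", {
  cfg <- simulation_config(seed = 7, n_subjects = 1, noise_cv = 0,
                           noise_floor = 0)
  e <- generate_experiment(cfg)
  # calibration: slope recovered exactly at zero noise
  one <- subset(e$calibration, analyte == "schisandrol A")
  cc <- fit_calibration(
    data.frame(nominal_conc = one$nominal_conc, peak_area = one$peak_area),
    ranges = list(c(1, 100), c(10, 1000)))
  expect_equal(cc$ranges$slope, c(50, 50), tolerance = 1e-9)
  # recovery: best flow rate is 2 and the truth value is recovered
  tab <- compute_recovery(e$recovery)
  expect_equal(select_flow_rate(tab), 2)
  bf <- tab$by_flow
  got <- bf$mean_recovery[bf$analyte == "schisandrol A" & bf$flow_rate == 2]
  expect_equal(got, cfg$recovery[["schisandrol A"]], tolerance = 1e-9)
})

test_that("invalid configurations are rejected with a clear class", {
  expect_error(simulation_config(interval = 23), class = "sim_invalid_config")
  expect_error(simulation_config(recovery = setNames(rep(1.5, 8),
                  names(mdpkpd:::default_recovery_truth()))),
               class = "sim_invalid_config")
  expect_error(simulation_config(index_analyte = "nonexistent"),
               class = "sim_invalid_config")
})
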