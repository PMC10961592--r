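test_that("effect-site concentration matches the ODE oracle", {
  skip_if_not_installed("deSolve")
  ka <- 0.05; ke <- 0.01; ke0 <- 0.02; vf <- 1
  p <- pk1c_params(ka, ke, vf)
  tt <- seq(0, 480, by = 20)
  oracle <- ode_1c_oracle(tt, ka, ke, vf, ke0 = ke0)$ce
  expect_equal(effect_compartment_conc(p, ke0, tt), oracle, tolerance = 1e-6)
})

test_that("a fast effect compartment equilibrates instantly", {
  p <- pk1c_params(0.05, 0.01, 1)
  tt <- seq(20, 480, by = 20)
  ce <- effect_compartment_conc(p, 1e6 * 0.05, tt)
  cp <- predict_conc(p, tt)
  expect_equal(ce, cp, tolerance = 1e-3)
})

test_that("the effect-site peak lags the plasma peak", {
  p <- pk1c_params(0.05, 0.01, 1)
  grid <- seq(0, 480, by = 0.1)
  cp <- predict_conc(p, grid)
  ce <- effect_compartment_conc(p, 0.02, grid)
  expect_gt(grid[which.max(ce)], grid[which.max(cp)])
})

test_that("the lambda = ke0 coincidence uses the analytic limit", {
  p <- pk1c_params(0.05, 0.01, 1)
  at <- effect_compartment_conc(p, 0.01, c(50, 100, 200))
  near <- effect_compartment_conc(p, 0.01 * (1 + 1e-7), c(50, 100, 200))
  expect_equal(at, near, tolerance = 1e-5)
})

test_that("noise-free link-model data are recovered within 5%", {
  pk <- pk1c_params(0.05, 0.01, 0.02)
  truth_pd <- pd_params("stimulation", e0 = 100, emax = 60, c50 = 15,
                        hill_n = 1.5)
  ke0 <- 0.02
  tt <- seq(10, 470, by = 20)
  eff <- pd_predict(truth_pd, effect_compartment_conc(pk, ke0, tt))
  fit <- fit_link(eff, pk, mode = "stimulation", times = tt)
  expect_equal(fit$ke0, ke0, tolerance = 0.05)
  expect_equal(fit$pd$e0, 100, tolerance = 0.05)
  expect_equal(fit$pd$emax, 60, tolerance = 0.05)
  expect_equal(fit$pd$c50, 15, tolerance = 0.05)
  expect_equal(fit$pd$hill_n, 1.5, tolerance = 0.05)
})

test_that("an effectively direct response yields a collapsed loop", {
  pk <- pk1c_params(0.05, 0.01, 0.02)
  truth_pd <- pd_params("stimulation", e0 = 100, emax = 60, c50 = 15,
                        hill_n = 1.5)
  tt <- seq(10, 470, by = 20)
  eff <- pd_predict(truth_pd, effect_compartment_conc(pk, 10, tt))
  loop <- hysteresis_loop(predict_conc(pk, tt), eff, times = tt)
  # the residual area is the sliver between the closing chord and the
  # single-valued curve, far below any real loop (~0.5 here)
  expect_lt(abs(loop$normalized_area), 0.05)
})

test_that("flat effect series are unidentifiable", {
  pk <- pk1c_params(0.05, 0.01, 0.02)
  expect_error(fit_link(rep(100, 24), pk, times = seq(10, 470, 20)),
               class = "link_unidentifiable")
})

test_that("shoelace area is +/-1 on the unit square", {
  x <- c(0, 1, 1, 0); y <- c(0, 0, 1, 1)
  ccw <- hysteresis_loop(x, y)
  expect_equal(ccw$signed_area, 1)
  expect_equal(ccw$direction, "counterclockwise")
  cw <- hysteresis_loop(rev(x), rev(y))
  expect_equal(cw$signed_area, -1)
  expect_equal(cw$direction, "clockwise")
})

test_that("a single-valued concentration-effect relation has no loop", {
  conc <- seq(1, 10, length.out = 12)
  eff <- 100 + 5 * conc^2
  # traverse up and back down the same curve
  loop <- hysteresis_loop(c(conc, rev(conc)), c(eff, rev(eff)))
  expect_lt(abs(loop$normalized_area), 1e-12)
  expect_equal(loop$direction, "none")
})

test_that("time reversal flips the loop sign exactly", {
  set.seed(21)
  for (i in 1:5) {
    x <- runif(8, 0, 50); y <- runif(8, 50, 150)
    fwd <- hysteresis_loop(x, y)
    rev_ <- hysteresis_loop(rev(x), rev(y))
    expect_equal(rev_$signed_area, -fwd$signed_area)
    expect_gte(fwd$normalized_area, -1)
    expect_lte(fwd$normalized_area, 1)
  }
})

test_that("degenerate loops and short inputs are flagged", {
  flat <- hysteresis_loop(rep(2, 5), c(1, 2, 3, 2, 1))
  expect_equal(flat$direction, "none")
  expect_true("degenerate_range" %in% flat$flags)
  expect_error(hysteresis_loop(1:3, 1:3), class = "loop_insufficient_points")
})

test_that("direction plus mode maps to the standard interpretation", {
  cw <- hysteresis_loop(c(0, 0, 1, 1), c(0, 1, 1, 0))
  ccw <- hysteresis_loop(c(0, 1, 1, 0), c(0, 0, 1, 1))
  none <- hysteresis_loop(rep(2, 4), c(1, 2, 3, 2))
  expect_equal(classify_relationship(cw, "inhibition"),
               "delayed suppression (Asp/Glu pattern)")
  expect_equal(classify_relationship(ccw, "stimulation"),
               "delayed enhancement (Tau/Ach pattern)")
  expect_equal(classify_relationship(none, "stimulation"), "atypical")
  expect_equal(classify_relationship(ccw, "inhibition"), "atypical")
})

test_that("simulated link loops follow the mode-direction law", {
  pk <- pk1c_params(0.045, 0.009, 0.02)
  tt <- seq(10, 470, by = 20)
  cp <- predict_conc(pk, tt)
  stim <- pd_params("stimulation", e0 = 100, emax = 60, c50 = 20, hill_n = 1.5)
  inhib <- pd_params("inhibition", e0 = 100, imax = 0.5, c50 = 30, hill_n = 1.5)
  for (ke0 in c(0.005, 0.02, 0.1)) {
    ce <- effect_compartment_conc(pk, ke0, tt)
    expect_equal(hysteresis_loop(cp, pd_predict(stim, ce), times = tt)$direction,
                 "counterclockwise")
    expect_equal(hysteresis_loop(cp, pd_predict(inhib, ce), times = tt)$direction,
                 "clockwise")
  }
})
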