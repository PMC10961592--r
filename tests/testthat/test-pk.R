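test_that("closed-form 1C prediction matches the ODE oracle", {
  skip_if_not_installed("deSolve")
  ka <- 0.05; ke <- 0.01; vf <- 1000
  p <- pk1c_params(ka, ke, vf)
  tt <- seq(0, 480, by = 20)
  oracle <- ode_1c_oracle(tt, ka, ke, vf)$cp
  expect_equal(predict_conc(p, tt, dose = 1), oracle, tolerance = 1e-6)
})

test_that("1C profile starts at zero and peaks at the Bateman Tmax", {
  p <- pk1c_params(0.05, 0.01, 1, tlag = 15)
  expect_equal(predict_conc(p, 15), 0)
  expect_equal(predict_conc(p, 0), 0)

  p0 <- pk1c_params(0.05, 0.01, 1)
  grid <- seq(0, 480, by = 0.01)
  cp <- predict_conc(p0, grid)
  expect_equal(grid[which.max(cp)], bateman_tmax(0.05, 0.01), tolerance = 1e-3)
})

test_that("predictions are nonnegative and vanish at late times", {
  p1 <- pk1c_params(0.07, 0.012, 2)
  p2 <- pk2c_params(0.1, 0.2, 0.01, 50, 10)
  tt <- seq(0, 5000, by = 50)
  expect_true(all(predict_conc(p1, tt) >= 0))
  expect_true(all(predict_conc(p2, tt) >= 0))
  expect_lt(predict_conc(p1, 5000), 1e-6 * max(predict_conc(p1, tt)))
  expect_lt(predict_conc(p2, 5000), 1e-6 * max(predict_conc(p2, tt)))
})

test_that("interval-average prediction matches numerical quadrature", {
  p <- pk1c_params(0.045, 0.009, 0.02)
  got <- predict_conc_interval(p, 40, 60)
  quad <- stats::integrate(function(t) predict_conc(p, t), 40, 60,
                           rel.tol = 1e-10)$value / 20
  expect_equal(got, quad, tolerance = 1e-8)
})

test_that("degenerate parameters are rejected", {
  expect_error(pk1c_params(0.05, 0.05, 1), class = "pk_degenerate_rate")
  expect_error(pk2c_params(0.1, 0.01, 0.2, 1, 1), class = "pk_invalid_params")
})

test_that("noise-free 1C data are recovered within 1%", {
  truth <- list(ka = 0.05, ke = 0.01, v_f = 1000)
  tt <- seq(20, 480, by = 20)
  s <- sample_series(tt, bateman_conc(tt, truth$ka, truth$ke, truth$v_f))
  fit <- fit_pk(s, "1C", dose = 1, seed = 1)
  expect_equal(fit$params$ka, truth$ka, tolerance = 0.01)
  expect_equal(fit$params$ke, truth$ke, tolerance = 0.01)
  expect_equal(fit$params$v_f, truth$v_f, tolerance = 0.01)
})

test_that("noise-free interval-averaged data are recovered within 1%", {
  s <- bateman_interval_series(0.045, 0.009, 0.02)
  fit <- fit_pk(s, "1C", dose = 1, seed = 1)
  expect_equal(fit$params$ka, 0.045, tolerance = 0.01)
  expect_equal(fit$params$ke, 0.009, tolerance = 0.01)
})

test_that("the 2C model nests the 1C model on noise-free 1C data", {
  tt <- seq(20, 480, by = 20)
  s <- sample_series(tt, bateman_conc(tt, 0.05, 0.01, 1000))
  f1 <- fit_pk(s, "1C", seed = 1)
  f2 <- fit_pk(s, "2C", seed = 1)
  scale <- max(s$conc)^2
  expect_lte(f2$scores$ssr, f1$scores$ssr + 1e-10 * scale)
})

test_that("fitting all-zero data fails loudly", {
  s <- sample_series(seq(20, 200, 20), rep(0, 10))
  expect_error(fit_pk(s, "1C"), class = "pk_fit_failed")
})

test_that("AIC and BIC rank identically at equal parameter count", {
  tt <- seq(10, 470, 20)
  set.seed(5)
  fits <- lapply(c(0.3, 0.05), function(noise) {
    conc <- bateman_conc(tt, 0.05, 0.01, 100) * (1 + noise * rnorm(24))
    fit_pk(sample_series(tt, pmax(conc, 0)), "1C", seed = 2)
  })
  aic_order <- order(vapply(fits, function(f) f$scores$aic, 0))
  bic_order <- order(vapply(fits, function(f) f$scores$bic, 0))
  expect_equal(aic_order, bic_order)
})

test_that("model selection follows minimal AIC with a parsimony band", {
  fake <- function(aic, p, id) {
    structure(list(model_id = id, observed = NULL,
                   scores = list(aic = aic, bic = aic, ssr = 1,
                                 n_obs = 20L, n_params = p)),
              class = "pk_fit")
  }
  expect_equal(select_model(list(fake(100, 3, "A"), fake(110, 5, "B")))$model_id,
               "A")
  # within 2 AIC units the smaller model wins even if slightly worse
  expect_equal(select_model(list(fake(101, 4, "small"),
                                 fake(100, 6, "big")))$model_id, "small")
  expect_error(select_model(list()), class = "pk_no_fits")
})

test_that("flip-flop fits are canonicalized to ka > ke", {
  tt <- seq(10, 470, 20)
  s <- sample_series(tt, bateman_conc(tt, 0.03, 0.006, 50))
  fit <- fit_pk(s, "1C", seed = 3)
  expect_gt(fit$params$ka, fit$params$ke)
  # the canonical and original parameterizations describe the same curve
  expect_equal(fit$predicted$conc,
               bateman_conc(tt, 0.03, 0.006, 50), tolerance = 1e-4)
})

test_that("CV percent is finite and small on well-conditioned noisy fits", {
  tt <- seq(10, 470, 20)
  set.seed(11)
  conc <- pmax(bateman_conc(tt, 0.05, 0.01, 100) * (1 + 0.05 * rnorm(24)), 0)
  fit <- fit_pk(sample_series(tt, conc), "1C", seed = 4)
  expect_false(fit$scores$cov_singular)
  expect_true(all(fit$scores$cv_percent > 0))
  expect_true(all(fit$scores$cv_percent < 50))
})
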