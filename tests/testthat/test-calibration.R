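test_that("calibration fit reproduces exact and OLS-oracle lines", {
  # exactly collinear points
  pts <- data.frame(nominal_conc = c(1, 2, 4), peak_area = c(10, 20, 40))
  cc <- fit_calibration(pts)
  expect_equal(cc$ranges$slope, 10)
  expect_equal(cc$ranges$intercept, 0)
  expect_equal(cc$ranges$r_squared, 1)

  # hand-computed normal-equations oracle
  x <- c(1, 2, 3, 4); y <- c(11, 19, 31, 39)
  oracle <- ols_normal_equations(x, y)
  cc2 <- fit_calibration(data.frame(nominal_conc = x, peak_area = y))
  expect_equal(cc2$ranges$slope, unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(cc2$ranges$intercept, unname(oracle["intercept"]),
               tolerance = 1e-12)
})

test_that("dual-range curves keep both ranges, sorted ascending", {
  # dual-range layout used for schisandrol A: 1-100 and 10-1000 ng/mL
  lo <- c(1, 2, 5, 10, 50, 100)
  hi <- c(10, 50, 100, 250, 500, 1000)
  pts <- data.frame(nominal_conc = c(lo, hi),
                    peak_area = 63 * c(lo, hi) + 10)
  cc <- fit_calibration(pts, ranges = list(c(1, 100), c(10, 1000)))
  expect_equal(nrow(cc$ranges), 2L)
  expect_equal(cc$ranges$conc_low, c(1, 10))
  expect_equal(cc$ranges$conc_high, c(100, 1000))
  expect_equal(cc$ranges$slope, c(63, 63), tolerance = 1e-9)
})

test_that("underdetermined ranges are rejected", {
  pts <- data.frame(nominal_conc = c(1, 1, 2), peak_area = c(10, 11, 20))
  expect_error(fit_calibration(pts), class = "calibration_underdetermined")
})

test_that("OLS residuals are orthogonal to the design per range", {
  set.seed(42)
  for (rep in 1:5) {
    x <- sort(runif(8, 1, 100))
    y <- 5 * x + 3 + rnorm(8)
    cc <- fit_calibration(data.frame(nominal_conc = x, peak_area = y))
    r <- y - (cc$ranges$slope * x + cc$ranges$intercept)
    expect_lt(abs(sum(r)) / sum(abs(y)), 1e-9)
    expect_lt(abs(sum(x * r)) / sum(abs(x * y)), 1e-9)
  }
})

test_that("back-calculation inverts the line and flags edge cases", {
  pts <- data.frame(nominal_conc = c(1, 5, 10, 50, 100),
                    peak_area = 10 * c(1, 5, 10, 50, 100))
  cc <- fit_calibration(pts, ranges = list(c(1, 100)), loq = 1)
  expect_equal(invert_calibration(cc, 50)$value, 5)

  at_intercept <- invert_calibration(cc, cc$ranges$intercept)
  expect_equal(at_intercept$value, 0)
  expect_true("below_loq" %in% at_intercept$flags)

  neg <- invert_calibration(cc, cc$ranges$intercept - 5)
  expect_equal(neg$value, 0)
  expect_true("clamped_negative" %in% neg$flags)
})

test_that("overlapping dual ranges resolve to the lower range", {
  lo <- c(1, 2, 5, 10, 50, 100)
  hi <- c(10, 50, 100, 250, 500, 1000)
  # slightly different slopes so the two ranges disagree measurably
  pts <- data.frame(
    nominal_conc = c(lo, hi),
    peak_area = c(60 * lo, 63 * hi + 100))
  cc <- fit_calibration(pts, ranges = list(c(1, 100), c(10, 1000)))
  # a response mapping into the overlap [10, 100] of both ranges
  area <- 60 * 50
  out <- invert_calibration(cc, area)
  expect_equal(out$range_index, 1L)
  expect_true("overlap" %in% out$flags)
  low_value <- (area - cc$ranges$intercept[1]) / cc$ranges$slope[1]
  expect_equal(out$value, low_value)
})

test_that("invert is the identity on predicted in-range areas", {
  pts <- data.frame(nominal_conc = c(2, 5, 20, 60, 90),
                    peak_area = c(25, 61, 239, 723, 1081))
  cc <- fit_calibration(pts)
  for (conc in c(2.5, 10, 44.4, 89)) {
    area <- cc$ranges$slope * conc + cc$ranges$intercept
    expect_equal(invert_calibration(cc, area)$value, conc, tolerance = 1e-9)
  }
})

test_that("detection limits follow S/N = 3 and 10 and scale linearly", {
  dl <- detection_limits(10, 1)
  expect_equal(unname(dl), c(0.3, 1.0))
  expect_equal(unname(detection_limits(10, 0)), c(0, 0))
  # homogeneity: degree 1 in noise, degree -1 in slope
  expect_equal(unname(detection_limits(10, 2)), 2 * unname(detection_limits(10, 1)))
  expect_equal(unname(detection_limits(20, 1)), unname(detection_limits(10, 1)) / 2)
  expect_error(detection_limits(0, 1), class = "calibration_invalid_slope")
})

test_that("QC levels sit at 3x LLOQ, 40% and 80% ULOQ", {
  expect_equal(as.numeric(qc_levels(1, 100)), c(3, 40, 80))
  expect_equal(as.numeric(qc_levels(0.1, 50)), c(0.3, 20, 40))
  expect_warning(lv <- qc_levels(10, 40), class = "qc_overlap")
  expect_equal(as.numeric(lv), c(30, 16, 32))
  expect_true(attr(lv, "overlap"))
})

test_that("precision and accuracy match replicate statistics", {
  pa <- precision_accuracy(c(9, 10, 11), 10)
  expect_equal(unname(pa), c(10, 0))
  expect_equal(unname(precision_accuracy(c(10, 10, 10), 8)), c(0, 25))
  expect_equal(unname(precision_accuracy(c(8, 8, 8), 10))[2], -20)
  # RSD is scale invariant
  x <- c(4.1, 5.2, 4.8, 5.5)
  expect_equal(precision_accuracy(x, 5)[["rsd_percent"]],
               precision_accuracy(7 * x, 35)[["rsd_percent"]])
})

test_that("matrix effect is the mean response ratio in percent", {
  expect_equal(matrix_effect(c(95, 95, 95), c(100, 100, 100))[["me_percent"]], 95)
  same <- c(88, 93, 101)
  expect_equal(matrix_effect(same, same)[["me_percent"]], 100)
  # a mean ratio of 98.6% sits inside the typical acceptance envelope
  me <- matrix_effect(c(98.0, 98.6, 99.2), c(99.4, 100, 100.6))
  expect_gt(me[["me_percent"]], 92.24)
  expect_lt(me[["me_percent"]], 106.85)
})

test_that("qc_report aggregates per analyte, level and day", {
  qc <- data.frame(analyte = "a", level = rep(c("low", "high"), each = 6),
                   day = rep(rep(1:2, each = 3), 2),
                   nominal_conc = rep(c(3, 80), each = 6),
                   measured_conc = c(2.9, 3.0, 3.1, 3.2, 3.0, 2.8,
                                     81, 79, 80, 78, 82, 80))
  rep_ <- qc_report(qc)
  expect_equal(nrow(rep_), 4L)
  expect_true(all(rep_$n_replicates == 3))
  row1 <- rep_[rep_$level == "low" & rep_$day == 1, ]
  expect_equal(row1$re_percent, 0, tolerance = 1e-9)
})
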