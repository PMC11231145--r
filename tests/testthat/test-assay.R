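test_that("exponential calibration recovers known parameters", {
  x <- seq(0, 50, by = 5)
  y <- 2 * exp(0.1 * x) + 1
  m <- fit_exponential(x, y)
  expect_equal(m$coefficients$a, 2, tolerance = 1e-6)
  expect_equal(m$coefficients$b, 0.1, tolerance = 1e-6)
  expect_equal(m$coefficients$c, 1, tolerance = 1e-5)
  expect_lt(m$residual_scale, 1e-6 * max(y))
})

test_that("degenerate calibration data fall back gracefully", {
  x <- c(0, 5, 10, 20, 40)
  expect_warning(m <- fit_exponential(x, rep(3, 5)), "constant")
  expect_equal(m$coefficients$a, 0)
  expect_equal(predict(m, c(0, 40)), c(3, 3), tolerance = 1e-9)
  expect_error(fit_exponential(c(0, 1, 2), c(1, 2, 3)), ">= 4")
})

test_that("independent calibration sets sharing a dose-0 generator agree at 0", {
  # two synthetic exposure series with different growth rates but a common
  # control state, plus measurement noise
  set.seed(61)
  x <- rep(c(0, 5, 10, 15, 25, 35, 50), each = 3)
  base <- 1.5
  y2 <- base + 0.5 * (exp(0.02 * x) - 1) + rnorm(length(x), 0, 0.01)
  y3 <- base + 0.5 * (exp(0.04 * x) - 1) + rnorm(length(x), 0, 0.01)
  m2 <- fit_exponential(x, y2, exposure = "T2")
  m3 <- fit_exponential(x, y3, exposure = "T3")
  gap <- abs(predict(m2, 0) - predict(m3, 0))
  pooled <- sqrt((m2$residual_scale^2 + m3$residual_scale^2) / 2)
  expect_lt(gap, 2 * pooled)
})

test_that("cubic calibration interpolates and flags non-monotone fits", {
  x <- c(0, 3, 6, 9, 12, 15)
  y <- 1 + 0.2 * x + 0.01 * x^2 + 0.001 * x^3
  m <- fit_cubic(x, y)
  expect_equal(unname(unlist(m$coefficients)), c(1, 0.2, 0.01, 0.001),
               tolerance = 1e-8)

  # linear data: quadratic and cubic terms collapse to zero
  ml <- fit_cubic(x, 2 + 0.5 * x)
  expect_equal(ml$coefficients$p2, 0, tolerance = 1e-10)
  expect_equal(ml$coefficients$p3, 0, tolerance = 1e-10)

  xs <- c(0, 2, 4, 6, 8, 12, 16)
  expect_warning(fit_cubic(xs, xs * (xs - 8) * (xs - 16) / 100),
                 "not monotone")
  expect_error(fit_cubic(c(0, 1, 2, 3), c(1, 2, 3, 4)), ">= 5")
})

test_that("cubic recovery under noise is nearly unbiased", {
  true <- c(1, 0.25, 0.012, 0.0015)
  x <- c(0, 2.5, 5, 7.5, 10, 12.5, 15)
  y0 <- true[1] + true[2] * x + true[3] * x^2 + true[4] * x^3
  sigma <- 0.02 * diff(range(y0))
  set.seed(62)
  coefs <- t(sapply(1:100, function(k) {
    # occasional non-monotone draws legitimately warn; the study only
    # cares about the coefficient distribution
    suppressWarnings(
      unlist(fit_cubic(x, y0 + rnorm(length(x), 0, sigma))$coefficients))
  }))
  bias <- abs(colMeans(coefs) - true)
  # intercept and slope dominate the curve; bias well under 10% of truth
  expect_lt(bias[1] / abs(true[1]), 0.1)
  expect_lt(bias[2] / abs(true[2]), 0.1)
})

test_that("calibration inversion round-trips and clamps out-of-range values", {
  x <- seq(0, 50, by = 5)
  m <- fit_exponential(x, 2 * exp(0.08 * x) + 0.5)
  for (x0 in c(0.5, 7, 23, 49)) {
    inv <- invert_calibration(m, predict(m, x0))
    expect_false(inv$out_of_range)
    expect_equal(inv$dose_uM, x0, tolerance = 1e-9)
  }
  low <- invert_calibration(m, 0.1)  # below the dose-0 value
  expect_true(low$out_of_range)
  expect_equal(low$dose_uM, 0)
  high <- invert_calibration(m, predict(m, 50) * 10)
  expect_true(high$out_of_range)
  expect_equal(high$dose_uM, 50)
})

test_that("cubic inversion matches a dense grid-search oracle", {
  x <- c(0, 3, 6, 9, 12, 15)
  m <- fit_cubic(x, 1 + 0.3 * x + 0.005 * x^2 + 0.0008 * x^3)
  grid <- seq(0, 15, length.out = 200001)
  yy <- predict(m, grid)
  for (target_x in c(1.3, 7.7, 14.2)) {
    y <- predict(m, target_x)
    oracle <- grid[which.min(abs(yy - y))]
    inv <- invert_calibration(m, y)
    expect_equal(inv$dose_uM, oracle, tolerance = 1e-4)
    expect_equal(inv$dose_uM, target_x, tolerance = 1e-6)
  }
})

test_that("decision tables reproduce the published interval structure", {
  tab <- build_decision_table()
  expect_length(tab$labels, 7)
  expect_length(tab$step1_labels, 4)
  expect_length(tab$step2_labels, 4)

  t2 <- build_decision_table(step1_bounds = c(30, 42.5), step2_bounds = NULL)
  expect_length(t2$labels, 3)

  expect_error(build_decision_table(step1_bounds = c(30, 20)), "increasing")
  expect_error(build_decision_table(step2_bounds = c(2.5, 20)), "partition")
})

test_that("two-step classification follows the trigger logic", {
  # calibration models with exactly known inverses
  doses <- seq(0, 50, by = 5)
  m_msl <- fit_exponential(doses, 1 * exp(0.05 * doses) + 0.2)
  m_ent <- fit_cubic(c(0, 2.5, 5, 7.5, 10, 12.5, 15, 17.5),
                     0.5 + 0.1 * c(0, 2.5, 5, 7.5, 10, 12.5, 15, 17.5))
  models <- list(msl = m_msl, entropy = m_ent)
  tab <- build_decision_table()

  # step-1 estimate of 25 uM: label [22.5, 30), step 2 not run
  call1 <- classify_dose(predict(m_msl, 25), NA, models, tab)
  expect_equal(call1$label, "[22.5, 30) uM")
  expect_false(call1$step2_ran)

  # step-1 estimate 8 uM triggers step 2; entropy pointing at 10 uM
  call2 <- classify_dose(predict(m_msl, 8), predict(m_ent, 10), models, tab)
  expect_true(call2$step2_ran)
  expect_equal(call2$label, "[7.5, 12.5) uM")

  # trigger without an entropy measurement is an explicit error
  expect_error(classify_dose(predict(m_msl, 5), NA_real_, models, tab),
               "entropy measurement")
})

test_that("the dose sweep produces exactly the labelled partition", {
  doses <- seq(0, 50, by = 5)
  m_msl <- fit_exponential(doses, 1 * exp(0.05 * doses) + 0.2)
  ent_x <- c(0, 2.5, 5, 7.5, 10, 12.5, 15, 17.5)
  m_ent <- fit_cubic(ent_x, 0.5 + 0.1 * ent_x)
  models <- list(msl = m_msl, entropy = m_ent)
  tab <- build_decision_table()

  sweep <- seq(0, 49.9, by = 0.1)
  labels <- vapply(sweep, function(d) {
    classify_dose(predict(m_msl, d), predict(m_ent, min(d, 17.4)),
                  models, tab)$label
  }, character(1))
  expect_setequal(unique(labels), tab$labels)
  # the mapping is a total function: one label per dose, ordered
  expect_length(labels, length(sweep))
  expect_identical(labels, labels[order(sweep)])
})

test_that("severity bridge is monotone, shared at dose 0, steeper for T3", {
  d <- c(0, 5, 10, 15, 25, 35, 50)
  s3 <- severity_from_dose(d, "T3")
  s2 <- severity_from_dose(d, "T2")
  expect_equal(s3[1], 0)
  expect_equal(s2[1], 0)
  expect_true(all(diff(s3) > 0))
  expect_true(all(s3[-1] > s2[-1]))
  expect_true(all(s3 <= 1 & s2 <= 1))
})
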