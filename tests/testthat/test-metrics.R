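# Evaluation metrics: closed forms, ranges, and independent oracles.

test_that("F-measure closed forms", {
  expect_equal(f_measure(1, 1, 0.3), 1)
  expect_equal(f_measure(0.8, 0.6, 0.3), 0.624 / 0.84, tolerance = 1e-12)
  # beta^2 = 1 reduces to the harmonic mean
  p <- 0.37; r <- 0.81
  expect_equal(f_measure(p, r, 1), 2 * p * r / (p + r), tolerance = 1e-12)
  # symmetry under P <-> R holds exactly when beta^2 = 1
  expect_equal(f_measure(p, r, 1), f_measure(r, p, 1))
  expect_false(isTRUE(all.equal(f_measure(p, r, 0.3), f_measure(r, p, 0.3))))
  expect_warning(z <- f_measure(0, 0, 0.3), "defined as 0")
  expect_equal(z, 0)
})

test_that("weighted F-measure matches a brute-force reference and its anchors", {
  set.seed(5)
  truth <- matrix(0, 24, 24)
  truth[6:18, 9:15] <- 255
  expect_equal(weighted_f_measure(truth, truth), 1, tolerance = 1e-9)
  expect_lt(weighted_f_measure(255 - truth, truth), 0.05)

  for (rep in 1:4) {
    pred <- matrix(runif(24 * 24), 24, 24)
    expect_equal(weighted_f_measure(pred, truth),
                 wfm_reference(pred, truth), tolerance = 0.02)
  }
  expect_error(weighted_f_measure(truth, matrix(0, 24, 24)),
               class = "stemspot_metric_error")
})

test_that("S-measure: identity, range, and degradation under salt noise", {
  truth <- matrix(0, 40, 40)
  truth[10:30, 15:25] <- 255
  expect_equal(s_measure(truth / 255, truth), 1, tolerance = 1e-6)

  set.seed(6)
  for (rep in 1:20) {
    pred <- matrix(runif(1600), 40, 40)
    v <- s_measure(pred, truth)
    expect_gte(v, 0); expect_lte(v, 1)
  }

  salted <- function(frac, seed) {
    set.seed(seed)
    p <- truth / 255
    flip <- sample(length(p), round(frac * length(p)))
    p[flip] <- 1 - p[flip]
    p
  }
  vals <- vapply(c(0.05, 0.15, 0.3), function(f) s_measure(salted(f, 7), truth),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(s_measure(truth, matrix(0, 40, 40)),
               class = "stemspot_metric_error")
})

test_that("E-measure: identity, inequality, and range", {
  truth <- matrix(0, 30, 30)
  truth[1:15, ] <- 255
  expect_equal(e_measure(truth, truth), 1, tolerance = 1e-9)
  expect_lt(e_measure(matrix(1, 30, 30), truth), 1)
  set.seed(7)
  for (rep in 1:20) {
    v <- e_measure(matrix(runif(900), 30, 30), truth)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("error metrics: hand cases, RMSE^2 = MSE, loop oracle", {
  em <- error_metrics(c(3, 7, 11), c(3, 7, 11))
  expect_equal(em$mae, 0); expect_equal(em$mse, 0); expect_equal(em$rmse, 0)
  expect_equal(em$r_squared, 1)
  expect_true(all(em$relative_errors_pct == 0))

  em1 <- error_metrics(10, 9)
  expect_equal(em1$mae, 1); expect_equal(em1$mse, 1); expect_equal(em1$rmse, 1)
  expect_equal(em1$relative_errors_pct, 10)

  set.seed(8)
  for (rep in 1:5) {
    m <- runif(100, 1, 90); r <- m + rnorm(100, 0, 0.5)
    em2 <- error_metrics(m, r)
    expect_equal(em2$rmse^2, em2$mse, tolerance = 1e-12)
    ref <- error_metrics_loops(m, r)
    expect_equal(em2$mae, ref$mae, tolerance = 1e-12)
    expect_equal(em2$mse, ref$mse, tolerance = 1e-12)
    expect_equal(em2$rmse, ref$rmse, tolerance = 1e-12)
  }

  # zero measured values are flagged and excluded from RE
  em3 <- error_metrics(c(0, 5), c(1, 5))
  expect_true(is.na(em3$relative_errors_pct[1]))
  expect_equal(em3$re_excluded, 1L)

  # the reference-denominator and conventional-R2 variants differ knowingly
  em4 <- error_metrics(c(10, 20), c(9, 22), re_denominator = "reference")
  expect_equal(em4$relative_errors_pct, c(100 / 9, 200 / 22))
  expect_error(error_metrics(1:3, 1:2), class = "stemspot_parameter_error")
})

test_that("mask evaluation wrapper scores a perfect pair as perfect", {
  truth <- matrix(0, 32, 32)
  truth[8:24, 12:20] <- 255
  ev <- evaluate_masks(list(truth), list(truth))
  expect_equal(ev$means$f_measure, 1)
  expect_equal(ev$means$weighted_f_measure, 1, tolerance = 1e-9)
  expect_equal(ev$means$s_measure, 1, tolerance = 1e-6)
  expect_equal(ev$means$e_measure, 1, tolerance = 1e-9)
  expect_equal(ev$means$mae, 0)
})
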