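test_that("wood_eval matches closed forms and validates its domain", {
  expect_equal(wood_eval(wood_params(1, 0, 0), 200), 1)
  expect_equal(wood_eval(wood_params(2, 0, 0.1), 10), 2 * exp(-1),
               tolerance = 1e-12)
  # full-lactation herd curve at its peak day
  expect_equal(wood_eval(t1_params, 105.3793), 42.14896, tolerance = 1e-6)
  # day 0 limits
  expect_equal(wood_eval(wood_params(3, 0.5, 0.01), 0), 0)
  expect_equal(wood_eval(wood_params(3, 0, 0.01), 0), 3)
  expect_error(wood_eval(wood_params(3, -0.2, 0.01), 0), "domain")
  expect_error(wood_eval(t1_params, -1), "non-negative")
  expect_error(wood_params(-1, 0.3, 0.003), "positive")
})

test_that("peak exists iff b > 0 and c > 0, at b/c with the analytic value", {
  pk <- wood_peak(t1_params)
  expect_true(pk$exists)
  expect_equal(pk$peak_day, 0.3056 / 0.0029, tolerance = 1e-12)
  expect_equal(pk$peak_day_int, 105L)
  expect_equal(pk$peak_value, 42.14896, tolerance = 1e-6)

  # negative c: curve still rising at the window's end, no interior peak
  expect_false(wood_peak(wood_params(15.0170, 0.2425, -0.0013))$exists)
  expect_false(wood_peak(wood_params(5, -0.1, 0.01))$exists)

  pk2 <- wood_peak(wood_params(5, 1, 1))
  expect_equal(pk2$peak_day, 1)
  expect_equal(pk2$peak_value, 5 * exp(-1), tolerance = 1e-12)
})

test_that("peak value matches a fine grid search for random rising curves", {
  set.seed(11)
  grid <- seq(0.01, 400, by = 0.01)
  for (i in 1:25) {
    # keep the peak day b/c inside the grid's [0, 400] window
    p <- wood_params(runif(1, 1, 50), runif(1, 0.05, 1),
                     runif(1, 0.005, 0.02))
    pk <- wood_peak(p)
    vals <- wood_eval(p, grid)
    # the analytic peak dominates the grid, and the grid gets within its
    # resolution of it (flat curves make the argmax location meaningless,
    # so the comparison is on the value)
    expect_gte(pk$peak_value, max(vals))
    expect_lt((pk$peak_value - max(vals)) / pk$peak_value, 1e-7)
  }
})

test_that("cumulative yield matches closed forms and is additive", {
  expect_equal(wood_cumulative(wood_params(1, 0, 0.01), 0, 100),
               100 * (1 - exp(-1)), tolerance = 1e-10)
  expect_equal(wood_cumulative(t1_params, 50, 50), 0)
  expect_error(wood_cumulative(t1_params, 100, 50), "t1")
  expect_error(wood_cumulative(wood_params(1, -1.2, 0.01), 0, 100),
               "diverges")

  # additivity over a split point
  set.seed(21)
  for (i in 1:20) {
    p <- wood_params(runif(1, 1, 50), runif(1, -0.5, 1),
                     runif(1, -0.003, 0.02))
    ts <- sort(runif(3, 0, 400))
    i12 <- wood_cumulative(p, ts[1], ts[2]) + wood_cumulative(p, ts[2], ts[3])
    i02 <- wood_cumulative(p, ts[1], ts[3])
    expect_equal(i12, i02, tolerance = 1e-10)
  }
})

test_that("incomplete-gamma and quadrature integrals agree where both apply", {
  set.seed(31)
  for (i in 1:200) {
    p <- wood_params(runif(1, 1, 50), runif(1, 0, 1), runif(1, 5e-4, 0.02))
    t0 <- runif(1, 0, 200); t1 <- t0 + runif(1, 0, 200)
    g <- wood_cumulative(p, t0, t1, method = "gamma")
    q <- wood_cumulative(p, t0, t1, method = "quadrature")
    expect_equal(g, q, tolerance = 1e-8)
  }
})

test_that("negative-c curves integrate by quadrature and keep rising", {
  p <- wood_params(15.0170, 0.2425, -0.0013)
  # monotone increasing on day > 0
  d <- wood_eval(p, 2:305) - wood_eval(p, 1:304)
  expect_true(all(d > 0))
  expect_gt(wood_cumulative(p, 0, 305), 0)
  expect_error(wood_cumulative(p, 0, 305, method = "gamma"), "c > 0")
})

test_that("wood_eval is positive over day > 0 for random parameter draws", {
  set.seed(41)
  for (i in 1:20) {
    p <- wood_params(runif(1, 0.1, 50), runif(1, -0.9, 1),
                     runif(1, -0.01, 0.02))
    expect_true(all(wood_eval(p, c(0.5, 1, 10, 100, 305)) > 0))
  }
})

test_that("phase shares normalise and reproduce the uniform-density case", {
  flat <- wood_params(7, 0, 0)
  expect_equal(unname(phase_shares(flat, c(100, 200), 305)),
               c(100, 100, 105) / 305, tolerance = 1e-10)
  expect_equal(unname(phase_shares(t1_params, numeric(0), 305)), 1)
  s <- phase_shares(t1_params, c(100, 200), 305)
  expect_equal(sum(s), 1, tolerance = 1e-10)
  # mid-lactation (100-200 d) share of the full-lactation herd curve
  expect_equal(unname(s[2]), 0.3554074, tolerance = 1e-6)
  expect_error(phase_shares(t1_params, c(200, 100), 305), "increasing")
})
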