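test_that("log-linear fit interpolates exactly through three clean points", {
  p <- wood_params(10, 0.3, 0.003)
  f <- fit_loglinear(exact_records(p, c(10, 100, 250)))
  expect_equal(unname(coef(f)), c(10, 0.3, 0.003), tolerance = 1e-9)
  expect_equal(f$rss, 0, tolerance = 1e-12)
})

test_that("log-linear fit recovers generating parameters from clean records", {
  f <- fit_loglinear(exact_records(t1_params, seq(15, 285, by = 30)))
  expect_equal(unname(coef(f)), c(13.7833, 0.3056, 0.0029), tolerance = 1e-9)
})

test_that("log-linear fit rejects or omits non-positive values as asked", {
  rec <- exact_records(t1_params, seq(15, 285, by = 30))
  rec$milk[2] <- 0
  expect_error(fit_loglinear(rec), "non-positive")
  f <- fit_loglinear(rec, on_nonpositive = "omit")
  expect_equal(f$n_excluded, 1L)
  expect_equal(f$n_obs, nrow(rec) - 1L)
  expect_error(fit_loglinear(exact_records(t1_params, c(10, 10, 10))),
               "distinct")
})

test_that("log-linear recovery stays accurate under multiplicative noise", {
  days <- rep(seq(15, 285, by = 30), each = 30)
  truth <- c(13.7833, 0.3056, 0.0029)
  errs <- vapply(1:200, function(s) {
    set.seed(s)
    rec <- data.frame(cow_id = "c", herd_id = "h", day = days,
                      milk = wood_eval(t1_params, days) *
                        exp(rnorm(length(days), 0, 0.08)))
    abs(unname(coef(fit_loglinear(rec))) / truth - 1)
  }, numeric(3))
  expect_lt(max(apply(errs, 1, median)), 0.05)
})

test_that("nonlinear fit reproduces clean curves with zero residual", {
  f <- fit_wood(exact_records(t1_params, seq(5, 305, by = 20)))
  expect_equal(unname(coef(f)), c(13.7833, 0.3056, 0.0029), tolerance = 1e-6)
  expect_lt(f$rss, 1e-10)
  expect_true(f$converged)
})

test_that("nonlinear fit recovers a negative post-peak slope unconstrained", {
  p <- wood_params(15, 0.24, -0.0013)
  set.seed(5)
  days <- rep(c(5, 12, 19, 26, 33), each = 10)
  rec <- data.frame(cow_id = "c", herd_id = "h", day = days,
                    milk = wood_eval(p, days) * exp(rnorm(length(days), 0, 0.02)))
  f <- fit_wood(rec)
  expect_lt(f$params$c, 0)
  expect_equal(f$params$a, 15, tolerance = 0.2)
})

test_that("nonlinear refinement never exceeds its initialiser's rss", {
  for (s in 1:5) {
    h <- small_herd(n_cows = 40, seed = s)
    init <- fit_wood(h$records, method = "loglinear")
    ref <- fit_wood(h$records, method = "nls")
    expect_lte(ref$rss, init$rss + 1e-8)
  }
})

test_that("fits are invariant to the order of the records", {
  h <- small_herd(n_cows = 50, seed = 6)
  f1 <- fit_wood(h$records)
  set.seed(1)
  f2 <- fit_wood(h$records[sample(nrow(h$records)), ])
  expect_identical(coef(f1), coef(f2))
})

test_that("herd-level fit recovers generator parameters within 5% median", {
  truth <- c(13.7833, 0.3056, 0.0029)
  errs <- vapply(1:8, function(s) {
    h <- simulate_herd(herd_sim_config(n_cows = 200,
                                       cull_check_tests = integer(0),
                                       seed = 100 + s))
    abs(unname(coef(fit_wood(h$records))) / truth - 1)
  }, numeric(3))
  expect_lt(max(apply(errs, 1, median)), 0.05)
})

test_that("per-trait fitting works on composition and urea series", {
  h <- small_herd(n_cows = 60, seed = 3)
  for (tr in c("fat", "protein", "lactose", "urea")) {
    f <- fit_wood(h$records, trait = tr)
    gen <- h$config$trait_params[[tr]]
    expect_equal(f$params$a, gen$a, tolerance = 0.15)
    # fitted curve tracks the generating curve's level mid-lactation
    expect_equal(wood_eval(f$params, 150), wood_eval(gen, 150),
                 tolerance = 0.1)
  }
})

test_that("truncated fits extrapolate clean curves exactly", {
  rec <- exact_records(t1_params, seq(5, 60, by = 5))
  f <- fit_truncated(rec, max_day = 60)
  expect_equal(f$predicted_305, wood_cumulative(t1_params, 0, 305),
               tolerance = 1e-6)
  expect_equal(f$area_window, wood_cumulative(t1_params, 0, 60),
               tolerance = 1e-6)
  expect_equal(f$n_obs, sum(rec$day <= 60))
})

test_that("a full-window truncated fit is self-consistent at the horizon", {
  h <- small_herd(n_cows = 60, seed = 4)
  f <- fit_truncated(h$records, max_day = 305)
  expect_equal(f$predicted_305, f$area_window, tolerance = 1e-10)
})

test_that("projection error shrinks from the shortest to the longest window", {
  h <- simulate_herd(herd_sim_config(seed = 1))
  truth <- mean(h$truth$true_305)
  ts <- truncation_series(h$records, truncation_days = c(30, 270))
  err <- abs(ts$predicted_305 - truth)
  expect_lt(err[ts$max_day == 270], err[ts$max_day == 30])
})
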