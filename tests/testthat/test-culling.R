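test_that("cohort membership follows the count of attended monthly tests", {
  rec <- data.frame(cow_id = c("a", rep("b", 10), rep("d", 2)),
                    day = c(25, seq(15, 285, by = 30), c(20, 50)))
  coh <- assign_cohorts(rec)
  expect_s3_class(coh, "culling_cohorts")
  asg <- attr(coh, "assignment")
  expect_equal(asg$final_day[asg$cow_id == "a"], 30)   # one test
  expect_equal(asg$final_day[asg$cow_id == "b"], 305)  # ten tests: completer
  expect_equal(asg$final_day[asg$cow_id == "d"], 60)
  expect_equal(sum(coh$n_cows), 3)
  expect_equal(sum(coh$n_milkings), nrow(rec))
})

test_that("all-completer herds collapse to a single cohort", {
  days <- seq(15, 285, by = 30)
  rec <- do.call(rbind, lapply(1:7, function(i)
    data.frame(cow_id = paste0("c", i), day = days)))
  coh <- assign_cohorts(rec)
  expect_equal(nrow(coh), 1L)
  expect_equal(coh$final_day, 305)
  expect_equal(coh$n_milkings, 10L * coh$n_cows)
})

test_that("counterfactual is the cow-weighted mean of projected yields", {
  coh <- culling_cohorts(c(150, 305), c(5, 10), c(3, 3),
                         c(5000, 11000), c(10000, 12000))
  expect_equal(herd_counterfactual(coh), 11000)
  one <- culling_cohorts(305, 10, 42, 11000, 11000)
  expect_equal(herd_counterfactual(one), 11000)
  expect_error(herd_counterfactual(coh[0, ]), "non-empty")
  expect_error(culling_cohorts(30, 3, 0, 1, 1), "n_cows > 0")
})

test_that("counterfactual is invariant to reordering and cohort splitting", {
  coh <- culling_cohorts(c(30, 150, 305), c(4, 20, 40), c(4, 4, 4),
                         c(700, 5500, 11400), c(8000, 10900, 11400))
  expect_equal(herd_counterfactual(coh), herd_counterfactual(coh[3:1, ]))
  split <- culling_cohorts(c(30, 60, 150, 305), c(2, 2, 20, 40),
                           c(2, 2, 4, 4), c(700, 700, 5500, 11400),
                           c(8000, 8000, 10900, 11400))
  expect_equal(herd_counterfactual(split), herd_counterfactual(coh))
})

test_that("culling gain preserves sign and propagates the counterfactual", {
  coh <- culling_cohorts(305, 10, 5, 11000, 11000)
  expect_equal(culling_gain(11000, coh), 0)
  expect_equal(culling_gain(12000, coh), 1000)
  expect_equal(culling_gain(10000, coh), -1000)  # culling hurt
  expect_error(culling_gain(-1, coh), "positive")
})

test_that("the culling rule is a strict below-threshold comparison", {
  expect_equal(cull_decision(23.9), "cull")
  expect_equal(cull_decision(24.0), "keep")
  expect_equal(cull_decision(42.1), "keep")
  expect_equal(cull_decision(c(0, 23.999, 24, 30)),
               c("cull", "cull", "keep", "keep"))
  expect_error(cull_decision(-1), ">= 0")
})

test_that("reports from records: no culling means zero gain, one cohort", {
  h <- small_herd(n_cows = 60, seed = 2, cull_check_tests = integer(0))
  rep <- build_culling_report(h$records)
  expect_equal(nrow(rep$cohorts), 1L)
  expect_equal(rep$gain_per_cow, 0, tolerance = 1e-9)
})

test_that("report counterfactual matches the per-cow ground-truth oracle", {
  # noise-free, heterogeneous herd: the counterfactual must reproduce the
  # brute-force average of the cows' true 0-305 integrals
  h <- simulate_herd(herd_sim_config(n_cows = 150, noise_cv = 0, seed = 8))
  expect_gt(sum(h$truth$culled), 0)
  rep <- build_culling_report(h$records)
  oracle <- mean(h$truth$true_305)
  expect_equal(rep$herd_counterfactual_305, oracle, tolerance = 0.03)
})

test_that("round trip at default noise stays within 3% of the truth mean", {
  h <- simulate_herd(herd_sim_config(seed = 1))
  rep <- build_culling_report(h$records)
  truth <- mean(h$truth$true_305)
  expect_lt(abs(rep$herd_counterfactual_305 - truth) / truth, 0.03)
  expect_gt(rep$gain_per_cow, 0)
})

test_that("culling low producers raises the realised herd average", {
  gains <- vapply(1:20, function(s) {
    h <- simulate_herd(herd_sim_config(n_cows = 120, seed = 300 + s))
    build_culling_report(h$records)$gain_per_cow
  }, numeric(1))
  expect_gte(mean(gains > 0), 0.95)
})

test_that("precomputed cohort tables reproduce the reference accounting", {
  coh <- herd_t1_cohorts()
  rep <- culling_report_from_cohorts(coh, herd_t1_actual_yield)
  expect_equal(round(rep$herd_counterfactual_305, 2), 9798.13)
  expect_equal(round(rep$gain_per_cow, 2), 1586.87)
  expect_equal(sum(coh$n_cows), 628)
  # milkings/cows ratio equals the cohort's monthly test count
  expect_equal(coh$n_milkings / coh$n_cows, coh$final_day %/% 30,
               ignore_attr = TRUE)
})
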