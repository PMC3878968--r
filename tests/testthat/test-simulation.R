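test_that("log-F draws are seeded, symmetric for equal df, and validated", {
  a <- sample_log_f(50, 2, 4.5, seed = 5)
  b <- sample_log_f(50, 2, 4.5, seed = 5)
  expect_identical(a, b)
  expect_error(sample_log_f(10, -1, 2), "positive")
  # X ~ F(d, d) implies 1/X ~ F(d, d), so log X is symmetric about 0
  x <- sample_log_f(200000, 4.5, 4.5, seed = 1)
  expect_lt(abs(median(x)), 0.02)
  expect_lt(abs(mean((x - mean(x))^3) / sd(x)^3), 0.05)
})

test_that("scenario datasets are reproducible per replicate and well-formed", {
  sc <- power_scenario(c(4, 5, 4), c(0, 0.25, 0.5), df = c(2, 4.5), seed = 9)
  d1 <- generate_dataset(sc, 3)
  d2 <- generate_dataset(sc, 3)
  expect_identical(d1$samples, d2$samples)
  expect_false(identical(generate_dataset(sc, 4)$samples, d1$samples))
  expect_equal(d1$sizes, c(4L, 5L, 4L))
  expect_error(power_scenario(c(4, 4), c(0, 1, 2)), "one entry per group")
  expect_error(power_scenario(c(4, 4, 4), c(0, 1, 2), df = c(2, -1)), "positive")
})

test_that("extreme location separation drives KTMB to its maximum", {
  sc <- power_scenario(c(4, 4, 4), c(0, 1e6, 2e6), seed = 2, reps = 5)
  for (r in 1:5) {
    d <- generate_dataset(sc, r)
    expect_equal(tuple_statistic(d, "KTMB"), 3 * prod(d$sizes))
  }
})

test_that("the calibrated rule holds type-I error near alpha under the null", {
  sc <- power_scenario(c(4, 4, 4), c(0, 0, 0), df = c(2, 4.5), reps = 4000,
                       seed = 101)
  row <- estimate_power(sc, tests = c("KTMB", "JT"))
  se <- sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(row$KTMB - 0.05), 4 * se)
  expect_lt(abs(row$JT - 0.05), 4 * se)
  expect_equal(row$KTMB_se, sqrt(row$KTMB * (1 - row$KTMB) / 4000))
})

test_that("KTMB power increases with the scale of an ascending trend", {
  pw <- vapply(c(0.5, 1, 2), function(s) {
    sc <- power_scenario(c(4, 4, 4), s * c(0, 0.5, 1), df = c(2, 4.5),
                         reps = 2000, seed = 300 + round(10 * s))
    estimate_power(sc, tests = "KTMB")$KTMB
  }, numeric(1))
  se <- sqrt(0.25 / 2000)
  expect_gt(pw[2], pw[1] - 3 * se)
  expect_gt(pw[3], pw[2] - 3 * se)
  expect_gt(pw[3], pw[1] + 3 * se)  # the overall rise must be real
})

test_that("DP summaries follow the printed conventions", {
  row <- list(KTMB = 0.1176, TM = 0.1255, KTP = 0.2, JT = 0.15, MJT = 0.18)
  expect_equal(dp_metrics(row, "gain_vs_tm"), 100 * (0.1176 - 0.1255) / 0.1255)
  expect_equal(round(dp_metrics(row, "gain_vs_tm"), 2), -6.29)
  expect_equal(dp_metrics(list(KTMB = 0.2, TM = 0.2), "gain_vs_tm"), 0)
  expect_equal(dp_metrics(list(KTMB = 0.1, KTP = 0.2, JT = 0.3, MJT = 0.2,
                               TM = 0.1), "loss_vs_best"), 0)
  expect_error(dp_metrics(list(KTMB = 0.1, TM = 0), "gain_vs_tm"), "undefined")
  expect_error(dp_metrics(list(KTMB = 0.1), "gain_vs_tm"), "lacks a value")
})

test_that("run_study assembles reproducible tables and survives bad scenarios", {
  scs <- list(power_scenario(c(3, 3, 3), c(0, 0, 0), reps = 300, seed = 5),
              power_scenario(c(3, 3, 3), c(0, 1, 2), reps = 300, seed = 5))
  t1 <- run_study(scs, tests = c("KTMB", "TM"))
  t2 <- run_study(scs, tests = c("KTMB", "TM"))
  expect_equal(t1$KTMB, t2$KTMB)
  expect_equal(nrow(t1), 2)
  expect_gt(t1$KTMB[2], t1$KTMB[1])  # trend scenario rejects more often
  expect_equal(nrow(run_study(list())), 0)
})
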