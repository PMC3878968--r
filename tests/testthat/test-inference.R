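test_that("standardization follows z = (T - E0)/sqrt(V0) with upper-tail p", {
  tt <- ordered_trend_test(sample_set(list(c(1, 2), 3, 4)), "KTMB",
                           moments = "enumeration")
  expect_equal(tt$observed, 6)
  expect_equal(tt$null_mean, 2)
  expect_equal(tt$null_variance, 8 / 3)
  expect_equal(tt$z, 4 / sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(tt$p.value, pnorm(tt$z, lower.tail = FALSE))
  expect_true(tt$reject)
})

test_that("observed at the null mean gives z = 0 and p = 0.5", {
  # the single tuple (2, 1, 3) has one fixed point, exactly E0[T] = 1
  tt <- ordered_trend_test(list(2, 1, 3), "KTMB")
  expect_equal(tt$observed, 1)
  expect_equal(tt$z, 0)
  expect_equal(tt$p.value, 0.5)
})

test_that("p-values decrease as the observed statistic increases", {
  nm <- null_moments(c(2, 2, 2), "KTMB")
  z <- function(t) (t - nm$mean) / sqrt(nm$variance)
  p <- pnorm(z(0:24), lower.tail = FALSE)
  expect_true(all(diff(p) < 0))
})

test_that("the battery reports all five tests in fixed order and shares alpha", {
  b <- ordered_trend_battery(list(c(1, 2), c(3, 4), c(5, 6)), alpha = 0.05)
  expect_named(b, c("KTMB", "KTP", "JT", "MJT", "TM"))
  expect_true(all(vapply(b, `[[`, logical(1), "reject")))   # separated ascending
  r <- ordered_trend_battery(list(c(5, 6), c(3, 4), c(1, 2)))
  expect_false(any(vapply(r, `[[`, logical(1), "reject")))  # reversed
  # descending k=3 tuples still fix the middle position, so the KTMB
  # statistic sits exactly at its null mean (z = 0); all others fall below
  expect_true(all(vapply(r, `[[`, numeric(1), "z") <= 0))
  expect_lt(r$TM$z, 0)
  expect_lt(r$KTP$z, 0)
})

test_that("battery results depend on group membership, not within-group order", {
  x <- random_sample_set(c(4, 3, 4), 7)
  y <- sample_set(lapply(x$samples, rev))
  bx <- as.data.frame(ordered_trend_battery(x))
  by <- as.data.frame(ordered_trend_battery(y))
  expect_equal(bx$observed, by$observed)
  expect_equal(bx$p.value, by$p.value)
})

test_that("ties are surfaced as recorded warnings, invalid alpha rejected", {
  tt <- ordered_trend_test(sample_set(list(c(1, 1), 2, 3)), "KTMB")
  expect_true(any(grepl("tie", tt$warnings)))
  expect_error(ordered_trend_test(list(1:2, 3:4, 5:6), alpha = 0.9), "alpha")
})

test_that("normal-rule rejection is documented against the exact benchmark", {
  # for sizes (2,1,1) the exact-PMF rejection probability at alpha = 0.05 is
  # P(T = 6) = 1/12; the normal rule rejects T >= E0 + 1.645 sd = 4.69, i.e.
  # also only T = 6 here, so the two rules coincide for this design
  nd <- enumerate_null_pmf(c(2, 1, 1), "KTMB")
  thr <- nd$mean + qnorm(0.95) * sqrt(nd$variance)
  exact_rej <- sum(nd$probabilities[nd$support >= thr])
  expect_equal(exact_rej, 1 / 12)
  # ... but at larger designs the normal rule is anticonservative: its exact
  # size at (4,4,4) exceeds the nominal 0.05 (documented discrepancy)
  nd3 <- enumerate_null_pmf(c(3, 3, 3), "KTMB")
  thr3 <- nd3$mean + qnorm(0.95) * sqrt(nd3$variance)
  expect_gt(sum(nd3$probabilities[nd3$support >= thr3]), 0.05)
})

test_that("write_report emits the delimited table plus metadata block", {
  b <- ordered_trend_battery(list(c(1, 2), c(3, 4), c(5, 6)))
  tmp <- tempfile()
  write_report(b, tmp)
  lines <- readLines(tmp)
  expect_equal(sum(startsWith(lines, "#")), 4)
  expect_match(lines[1], "statistic")
  expect_equal(length(lines), 1 + 5 + 4)
})
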