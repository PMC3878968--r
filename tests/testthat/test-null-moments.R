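test_that("partition counting is the exact multinomial coefficient", {
  expect_equal(count_rank_partitions(c(2, 1, 1)), 12)
  expect_equal(count_rank_partitions(c(1, 1, 3)), 20)
  expect_equal(count_rank_partitions(c(2, 1, 2)), 30)
  expect_equal(count_rank_partitions(c(5, 5, 5, 5)), 11732745024)
  expect_error(count_rank_partitions(c(2, 0, 1)), ">= 1")
})

test_that("enumerated KTMB null PMFs reproduce the tabulated small designs", {
  nd <- enumerate_null_pmf(c(2, 1, 1), "KTMB")
  expect_equal(nd$support, c(0, 1, 2, 3, 4, 6))
  expect_equal(nd$counts, c(2, 3, 4, 1, 1, 1))
  expect_equal(nd$denominator, 12)
  expect_equal(nd$mean, 2)
  expect_equal(nd$variance, 8 / 3)
  expect_equal(sum(nd$counts), nd$denominator)  # probabilities sum to 1 exactly

  nd2 <- enumerate_null_pmf(c(2, 1, 2), "KTMB")
  expect_equal(nd2$mean, 4)
  expect_equal(round(nd2$variance, 3), 6.867)

  nd3 <- enumerate_null_pmf(c(1, 1, 3), "KTMB")
  expect_equal(nd3$mean, 3)
  expect_equal(nd3$variance, 5)

  # single-tuple design: the fixed-point distribution of a uniform permutation
  nd1 <- enumerate_null_pmf(c(1, 1, 1), "KTMB")
  expect_equal(nd1$support, c(0, 1, 3))
  expect_equal(nd1$counts, c(2, 3, 1))
  expect_equal(nd1$mean, 1)
  expect_equal(nd1$variance, 1)

  expect_error(enumerate_null_pmf(c(5, 5, 5, 5), "KTMB"), "budget")
})

test_that("KTMB null mean equals prod(sizes) across designs", {
  for (sz in list(c(2, 2, 1), c(3, 1, 2), c(2, 1, 1, 2), c(1, 4, 2))) {
    expect_equal(enumerate_null_pmf(sz, "KTMB")$mean, prod(sz))
    expect_equal(exact_null_moments(sz, "KTMB")$mean, prod(sz))
  }
})

test_that("tie-pattern exact moments equal enumeration and permutation oracles", {
  sizes_list <- list(c(2, 1, 1), c(2, 1, 2), c(1, 1, 3), c(2, 2, 2),
                     c(1, 2, 1, 2), c(2, 1, 1, 2))
  for (sz in sizes_list) for (s in c("KTMB", "TM", "KTP")) {
    en <- enumerate_null_pmf(sz, s)
    ex <- exact_null_moments(sz, s)
    expect_equal(ex$mean, en$mean, tolerance = 1e-10)
    expect_equal(ex$variance, en$variance, tolerance = 1e-10)
  }
  # fully independent oracle: average over all N! orderings of pooled ranks
  om <- oracle_null_moments(c(2, 1, 2), function(g)
    oracle_tuple_stat(g, oracle_ktmb_kernel))
  expect_equal(om[["mean"]], 4)
  expect_equal(om[["var"]], exact_null_moments(c(2, 1, 2), "KTMB")$variance,
               tolerance = 1e-10)
})

test_that("single-tuple variance equals the k! kernel variance", {
  for (s in c("KTMB", "TM", "KTP")) {
    kern <- switch(s, KTMB = oracle_ktmb_kernel, TM = oracle_tm_kernel,
                   KTP = oracle_ktp_kernel)
    vals <- apply(oracle_perms(3), 1, kern)
    expect_equal(exact_null_moments(c(1, 1, 1), s)$variance,
                 mean(vals^2) - mean(vals)^2, tolerance = 1e-10)
  }
})

test_that("JT and MJT closed forms match enumeration for all shapes with N <= 7", {
  shapes <- list(c(1, 1, 1), c(2, 1, 1), c(2, 2, 1), c(2, 2, 2), c(3, 2, 2),
                 c(1, 2, 3), c(5, 1, 1), c(2, 1, 1, 2), c(2, 2, 2, 1), c(1, 1, 1, 4))
  for (sz in shapes) {
    en_jt <- enumerate_null_pmf(sz, "JT")
    cf_jt <- jt_null_moments(sz)
    expect_equal(cf_jt$mean, en_jt$mean)
    expect_equal(cf_jt$variance, en_jt$variance, tolerance = 1e-10)
    en_mjt <- enumerate_null_pmf(sz, "MJT")
    cf_mjt <- mjt_null_moments(sz)
    expect_equal(cf_mjt$mean, en_mjt$mean)
    expect_equal(cf_mjt$variance, en_mjt$variance, tolerance = 1e-10)
    # MJT mean closed form: sum over pairs of (m - l) n_l n_m / 2
    k <- length(sz)
    mm <- 0
    for (l in 1:(k - 1)) for (m in (l + 1):k) mm <- mm + (m - l) * sz[l] * sz[m] / 2
    expect_equal(cf_mjt$mean, mm)
  }
})

test_that("Monte Carlo moments converge to the exact values and are seeded", {
  nm <- mc_null_moments(c(2, 1, 1), "KTMB", reps = 100000, seed = 11)
  se_mean <- sqrt(8 / 3 / 100000)
  expect_lt(abs(nm$mean - 2), 3 * se_mean)
  nm2 <- mc_null_moments(c(2, 1, 2), "KTMB", reps = 100000, seed = 12)
  expect_lt(abs(nm2$mean - 4), 4 * sqrt(6.867 / 100000))
  expect_lt(abs(nm2$variance - 6.867) / 6.867, 0.05)
  rerun <- mc_null_moments(c(2, 1, 2), "KTMB", reps = 5000, seed = 3)
  rerun2 <- mc_null_moments(c(2, 1, 2), "KTMB", reps = 5000, seed = 3)
  expect_identical(rerun$mean, rerun2$mean)
  expect_identical(rerun$variance, rerun2$variance)
  expect_error(mc_null_moments(c(2, 1, 1), reps = 10), "1000")
})

test_that("the auto moment policy picks exact methods and caching is transparent", {
  nm <- null_moments(c(2, 1, 1), "KTMB")
  expect_equal(nm$method, "enumeration")
  expect_equal(nm$variance, 8 / 3)
  nm_big <- null_moments(c(6, 6, 6), "KTMB")
  expect_equal(nm_big$method, "tie_pattern_exact")
  expect_equal(nm_big$mean, 216)
  expect_equal(null_moments(c(3, 3, 3), "JT")$method, "closed_form")
  # advisory file cache round-trip
  tmp <- tempfile(fileext = ".tsv")
  withr::with_options(list(ktmb.cache_file = tmp), {
    a <- null_moments(c(2, 2, 1), "KTMB", cache = TRUE)
    expect_true(file.exists(tmp))
    b <- null_moments(c(2, 2, 1), "KTMB", cache = TRUE)
    expect_equal(a$variance, b$variance)
  })
})

test_that("randomized exact critical regions attain size alpha on the null PMF", {
  for (s in c("KTMB", "TM", "JT")) {
    nd <- enumerate_null_pmf(c(2, 2, 2), s)
    cr <- null_critical_region(c(2, 2, 2), s, alpha = 0.05)
    size <- sum(nd$probabilities[nd$support > cr$c]) +
      cr$gamma * nd$probabilities[match(cr$c, nd$support)]
    expect_equal(size, 0.05, tolerance = 1e-12)
    expect_gte(cr$gamma, 0)
    expect_lt(cr$gamma, 1)
  }
})
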