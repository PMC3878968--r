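# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: scalar kernels via base rank(), tuple sums via
# recursive index loops, and null moments by averaging over ALL N!
# permutations of the pooled ranks (each rank partition is counted the same
# number of times, so moments agree with the partition distribution).

oracle_ktmb_kernel <- function(v) {
  r <- rank(v, ties.method = "min")
  sum(r == seq_along(v))
}

oracle_tm_kernel <- function(v) {
  as.integer(!is.unsorted(v) && v[1] < v[length(v)])
}

oracle_ktp_kernel <- function(v) {
  r <- rank(v)
  if (stats::sd(r) == 0) return(0)
  stats::cor(r, seq_along(v))
}

# sum a scalar kernel over all k-tuples by explicit recursion
oracle_tuple_stat <- function(samples, kernel) {
  k <- length(samples)
  total <- 0
  rec <- function(i, tuple) {
    if (i > k) {
      total <<- total + kernel(tuple)
      return(invisible(NULL))
    }
    for (v in samples[[i]]) rec(i + 1L, c(tuple, v))
  }
  rec(1L, numeric(0))
  total
}

oracle_jt <- function(samples, weighted = FALSE) {
  k <- length(samples)
  s <- 0
  for (l in 1:(k - 1)) for (m in (l + 1):k)
    for (a in samples[[l]]) for (b in samples[[m]])
      s <- s + (if (weighted) (m - l) else 1) * (a < b)
  s
}

# all permutations of 1..n (n <= 7 here)
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(pos)
    cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
          sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])))
}

# exact null mean/variance by averaging the statistic over all N! orderings
oracle_null_moments <- function(sizes, statfun) {
  N <- sum(sizes)
  P <- oracle_perms(N)
  grp <- rep(seq_along(sizes), sizes)
  vals <- apply(P, 1, function(p) statfun(split(p, grp)))
  c(mean = mean(vals), var = mean(vals^2) - mean(vals)^2)
}

random_sample_set <- function(sizes, seed) {
  set.seed(seed)
  sample_set(lapply(sizes, stats::rnorm))
}
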