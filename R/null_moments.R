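# ---------------------------------------------------------------------------
# Exact null distributions and null moments
#
# Under H0 every assignment of the pooled ranks 1..N to the groups (respecting
# the sample sizes) is equally likely; there are N!/(n1! ... nk!) such rank
# partitions. Small designs are enumerated in full; arbitrary designs get
# exact moments from a tie-pattern covariance decomposition of the tuple
# statistic; Monte Carlo is the fallback.
# ---------------------------------------------------------------------------

#' Number of equally likely rank partitions
#'
#' Multinomial coefficient `N!/(n1! ... nk!)` counting the distinct ways to
#' assign the pooled ranks `1..N` to groups of the given sizes.
#'
#' @param sizes integer vector of group sizes, all >= 1.
#' @return the exact count as a double (exact up to 2^53).
#' @examples
#' count_rank_partitions(c(2, 1, 1)) # 12
#' @export
count_rank_partitions <- function(sizes) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) stop("all group sizes must be >= 1", call. = FALSE)
  total <- 1
  placed <- 0L
  for (n in sizes) {
    total <- total * choose(placed + n, n)
    placed <- placed + n
  }
  total
}

# All permutations of 1..n as an n! x n matrix (n <= 9 in practice).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, m * n, n)
  for (pos in seq_len(n)) {
    rows <- (pos - 1L) * m + seq_len(m)
    out[rows, pos] <- n
    out[rows, -pos] <- sub
  }
  out
}

# Visit every distinct rank partition, calling fn(groups) with the list of
# rank vectors; recursion over combinations keeps memory flat.
.visit_partitions <- function(sizes, fn) {
  k <- length(sizes)
  groups <- vector("list", k)
  recurse <- function(i, remaining) {
    if (i == k) {
      groups[[k]] <<- remaining
      fn(groups)
      return(invisible(NULL))
    }
    for (pick in utils::combn(length(remaining), sizes[i], simplify = FALSE)) {
      groups[[i]] <<- remaining[pick]
      recurse(i + 1L, remaining[-pick])
    }
  }
  recurse(1L, seq_len(sum(sizes)))
  invisible(NULL)
}

#' Exact null distribution by full enumeration
#'
#' Enumerates every distinct assignment of the pooled ranks `1..N` to the
#' groups, computes the statistic on each, and tallies the exact probability
#' mass function. Probabilities are exact rationals `count / partition_count`
#' (stored as integer counts plus the common denominator).
#'
#' @param sizes integer vector of group sizes (k >= 3 for the test statistics).
#' @param statistic one of `"KTMB"`, `"TM"`, `"KTP"`, `"JT"`, `"MJT"`.
#' @param budget refuse designs with more rank partitions than this.
#' @return An object of class `"null_distribution"`: list with `support`,
#'   `counts`, `probabilities`, `denominator` (= `partition_count`), `mean`,
#'   `variance`, `sizes`, `statistic`.
#' @examples
#' nd <- enumerate_null_pmf(c(2, 1, 1), "KTMB")
#' nd$mean      # 2
#' nd$variance  # 8/3
#' @export
enumerate_null_pmf <- function(sizes, statistic = "KTMB",
                               budget = getOption("ktmb.enum_budget", 1e6)) {
  statistic <- match.arg(statistic, .STATISTICS)
  sizes <- as.integer(sizes)
  npart <- count_rank_partitions(sizes)
  if (npart > budget)
    stop("design has ", format(npart, big.mark = ","), " rank partitions, over the ",
         "enumeration budget; use exact_null_moments() or mc_null_moments()",
         call. = FALSE)
  idx <- if (statistic %in% c("KTMB", "TM", "KTP")) .tuple_index(sizes) else NULL
  tally <- new.env(parent = emptyenv())
  .visit_partitions(sizes, function(groups) {
    v <- if (is.null(idx)) {
      if (statistic == "JT") .pairwise_sum(groups, weighted = FALSE)
      else .pairwise_sum(groups, weighted = TRUE)
    } else sum(.rows_kernel(.tuple_values(groups, idx), statistic))
    key <- format(v, digits = 15)
    tally[[key]] <- (if (is.null(tally[[key]])) 0 else tally[[key]]) + 1
  })
  support <- as.numeric(ls(tally))
  o <- order(support)
  support <- support[o]
  counts <- vapply(ls(tally), function(k) tally[[k]], numeric(1))[o]
  p <- counts / npart
  mu <- sum(support * counts) / npart
  v2 <- sum(support^2 * counts) / npart - mu^2
  structure(list(support = support, counts = unname(counts), probabilities = unname(p),
                 denominator = npart, partition_count = npart,
                 mean = mu, variance = v2, sizes = sizes, statistic = statistic),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Exact null distribution of", x$statistic, "for sizes (",
      paste(x$sizes, collapse = ", "), ")\n")
  cat("  partitions:", format(x$denominator, big.mark = ","), "\n")
  tab <- data.frame(value = x$support,
                    probability = sprintf("%d/%d", as.integer(x$counts),
                                          as.integer(x$denominator)))
  print(tab, row.names = FALSE)
  cat(sprintf("  mean %.4g  variance %.4g\n", x$mean, x$variance))
  invisible(x)
}

.pairwise_sum <- function(groups, weighted) {
  k <- length(groups)
  s <- 0
  for (l in seq_len(k - 1L))
    for (m in (l + 1L):k) {
      u <- sum(outer(groups[[l]], groups[[m]], "<"))
      s <- s + if (weighted) (m - l) * u else u
    }
  s
}

# ---- null-moments container ------------------------------------------------

.null_moments <- function(mean, variance, method, statistic, sizes,
                          mc_reps = NULL, seed = NULL) {
  structure(list(mean = mean, variance = variance, method = method,
                 statistic = statistic, sizes = as.integer(sizes),
                 mc_reps = mc_reps, seed = seed),
            class = "null_moments")
}

#' @export
print.null_moments <- function(x, ...) {
  cat(sprintf("Null moments of %s for sizes (%s): mean %.6g, variance %.6g [%s%s]\n",
              x$statistic, paste(x$sizes, collapse = ", "), x$mean, x$variance,
              x$method,
              if (!is.null(x$mc_reps)) sprintf(", %d reps, seed %d", x$mc_reps, x$seed) else ""))
  invisible(x)
}

# ---- exact moments via the tie-pattern covariance decomposition -------------

# The variance of a tuple statistic T = sum over tuples of h(tuple) is the sum
# of Cov(h_a, h_b) over all ordered tuple pairs. That covariance depends only
# on the set S of coordinates where the two tuples share the same observation:
# the 2k - |S| distinct observations are exchangeable under H0, so Cov_S is an
# exact average over the (2k - |S|)! relative orderings. Pairs sharing no
# coordinate are independent (disjoint observation sets). The number of
# ordered pairs with sharing pattern S is
#   prod_{i in S} n_i * prod_{i notin S} n_i (n_i - 1).

.ktmb_cov_cache <- new.env(parent = emptyenv())

# mean and variance of the kernel over one tuple (all k! orderings)
.kernel_moments <- function(k, statistic) {
  key <- paste0("k", k, statistic)
  hit <- .ktmb_cov_cache[[key]]
  if (!is.null(hit)) return(hit)
  h <- .rows_kernel(.permutations(k), statistic)
  out <- c(mean = mean(h), var = mean(h^2) - mean(h)^2)
  .ktmb_cov_cache[[key]] <- out
  out
}

# Cov_S for two tuples sharing exactly the coordinates in S (integer vector).
.pattern_cov <- function(k, S, statistic) {
  key <- paste0("k", k, statistic, "S", paste(S, collapse = "."))
  hit <- .ktmb_cov_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- 2L * k - length(S)
  P <- .permutations(m)
  colB <- integer(k)
  nxt <- k
  for (i in seq_len(k)) {
    if (i %in% S) colB[i] <- i else { nxt <- nxt + 1L; colB[i] <- nxt }
  }
  hA <- .rows_kernel(P[, seq_len(k), drop = FALSE], statistic)
  hB <- .rows_kernel(P[, colB, drop = FALSE], statistic)
  mu <- .kernel_moments(k, statistic)[["mean"]]
  out <- mean(hA * hB) - mu^2
  .ktmb_cov_cache[[key]] <- out
  out
}

#' Exact null moments of a tuple statistic for arbitrary designs
#'
#' Computes the exact null mean and variance of the KTMB, TM or KTP statistic
#' without enumerating rank partitions. The mean is `prod(sizes)` times the
#' kernel's null mean (1 for KTMB, `1/k!` for TM, 0 for KTP). The variance is
#' assembled from exact pairwise tuple covariances grouped by sharing pattern;
#' each pattern covariance is an exhaustive average over the orderings of the
#' pair's distinct observations, so the result is exact for any sample sizes.
#'
#' @inheritParams enumerate_null_pmf
#' @param kmax largest k handled exactly (the heaviest pattern enumerates
#'   `(2k - 1)!` orderings); larger designs fall back to [mc_null_moments]
#'   with a warning.
#' @param mc_reps,seed forwarded to the Monte Carlo fallback.
#' @return a `"null_moments"` object with `method = "tie_pattern_exact"`.
#' @examples
#' exact_null_moments(c(2, 1, 1), "KTMB") # mean 2, variance 2.667
#' @export
exact_null_moments <- function(sizes, statistic = c("KTMB", "TM", "KTP"),
                               kmax = getOption("ktmb.tie_pattern_kmax", 5L),
                               mc_reps = 200000L, seed = 20130101L) {
  statistic <- match.arg(statistic)
  sizes <- as.integer(sizes)
  k <- length(sizes)
  if (k > kmax) {
    warning("tie-pattern enumeration capped at k = ", kmax,
            "; falling back to Monte Carlo moments", call. = FALSE)
    return(mc_null_moments(sizes, statistic, reps = mc_reps, seed = seed))
  }
  km <- .kernel_moments(k, statistic)
  mu <- prod(sizes) * km[["mean"]]
  v <- 0
  for (code in seq_len(2^k - 1L)) {
    S <- which(bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    pairs <- prod(sizes[S]) * prod(sizes[-S] * (sizes[-S] - 1L))
    if (pairs == 0) next
    v <- v + pairs * .pattern_cov(k, S, statistic)
  }
  .null_moments(mu, v, "tie_pattern_exact", statistic, sizes)
}

#' Monte Carlo null moments
#'
#' Draws `reps` uniform random assignments of the pooled ranks `1..N` to the
#' group multiset and returns the sample mean and variance of the statistic.
#' Reproducible for a fixed seed (the RNG state of the session is preserved).
#'
#' @inheritParams enumerate_null_pmf
#' @param reps number of random rank partitions (>= 1000).
#' @param seed integer seed recorded in the result.
#' @return a `"null_moments"` object with `method = "monte_carlo"`.
#' @export
mc_null_moments <- function(sizes, statistic = "KTMB", reps = 10000L,
                            seed = 20130101L) {
  statistic <- match.arg(statistic, .STATISTICS)
  sizes <- as.integer(sizes)
  if (reps < 1000L) stop("use at least 1000 Monte Carlo replicates", call. = FALSE)
  N <- sum(sizes)
  grp <- rep(seq_along(sizes), sizes)
  idx <- if (statistic %in% c("KTMB", "TM", "KTP")) .tuple_index(sizes) else NULL
  vals <- numeric(reps)
  old <- .preserve_rng(seed)
  on.exit(.restore_rng(old))
  for (r in seq_len(reps)) {
    ranks <- sample.int(N)
    groups <- split(ranks, grp)
    vals[r] <- if (is.null(idx)) .pairwise_sum(groups, weighted = statistic == "MJT")
               else sum(.rows_kernel(.tuple_values(groups, idx), statistic))
  }
  .null_moments(mean(vals), stats::var(vals), "monte_carlo", statistic, sizes,
                mc_reps = as.integer(reps), seed = as.integer(seed))
}

.preserve_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# ---- closed forms for the pairwise statistics -------------------------------

#' Closed-form null moments of the Jonckheere-Terpstra statistic
#'
#' Standard tie-free null moments: mean `(N^2 - sum(n_i^2))/4`, variance
#' `[N^2 (2N + 3) - sum(n_i^2 (2 n_i + 3))]/72`.
#'
#' @inheritParams enumerate_null_pmf
#' @return a `"null_moments"` object with `method = "closed_form"`.
#' @export
jt_null_moments <- function(sizes) {
  sizes <- as.integer(sizes)
  N <- sum(sizes)
  mu <- (N^2 - sum(sizes^2)) / 4
  v <- (N^2 * (2 * N + 3) - sum(sizes^2 * (2 * sizes + 3))) / 72
  .null_moments(mu, v, "closed_form", "JT", sizes)
}

#' Closed-form null moments of the modified Jonckheere-Terpstra statistic
#'
#' For `MJT = sum_{l<m} (m - l) U_lm` the tie-free null mean is
#' `sum_{l<m} (m - l) n_l n_m / 2`. The variance combines the Mann-Whitney
#' variances `n_l n_m (n_l + n_m + 1)/12` with the exact cross-covariances of
#' counts sharing one group (`+ n_a n_b n_c / 12` when the shared group sits on
#' the same side of both comparisons, `- n_a n_b n_c / 12` when it switches
#' sides); counts on disjoint group pairs are independent.
#'
#' @inheritParams enumerate_null_pmf
#' @return a `"null_moments"` object with `method = "closed_form"`.
#' @export
mjt_null_moments <- function(sizes) {
  sizes <- as.integer(sizes)
  k <- length(sizes)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE) # (l, m), l < m
  w <- pairs[, 2] - pairs[, 1]
  mu <- sum(w * sizes[pairs[, 1]] * sizes[pairs[, 2]]) / 2
  v <- sum(w^2 * sizes[pairs[, 1]] * sizes[pairs[, 2]] *
             (sizes[pairs[, 1]] + sizes[pairs[, 2]] + 1) / 12)
  np <- nrow(pairs)
  for (p in seq_len(np)) for (q in seq_len(np)) {
    if (p == q) next
    l1 <- pairs[p, 1]; m1 <- pairs[p, 2]
    l2 <- pairs[q, 1]; m2 <- pairs[q, 2]
    shared <- intersect(c(l1, m1), c(l2, m2))
    if (length(shared) != 1L) next
    g <- shared
    others <- c(setdiff(c(l1, m1), g), setdiff(c(l2, m2), g))
    sgn <- if ((g == l1) == (g == l2)) 1 else -1   # same side vs switched side
    v <- v + sgn * w[p] * w[q] * sizes[g] * prod(sizes[others]) / 12
  }
  .null_moments(mu, v, "closed_form", "MJT", sizes)
}

# ---- calibrated critical regions --------------------------------------------

#' Exact level-alpha critical region of a trend statistic
#'
#' For a discrete null distribution the threshold test `T >= c` cannot in
#' general attain size `alpha` exactly. The canonical randomized level-alpha
#' test rejects when `T > c`, and with probability `gamma` when `T = c`, where
#' `c` and `gamma in [0, 1)` solve `P0(T > c) + gamma P0(T = c) = alpha`. The
#' null distribution is taken from full enumeration when the partition count
#' permits, else from a seeded Monte Carlo sample of rank partitions.
#'
#' @inheritParams enumerate_null_pmf
#' @param alpha target one-sided size.
#' @param method `"auto"`, `"enumeration"` or `"monte_carlo"`.
#' @param enum_limit partition-count bound for `"auto"` enumeration.
#' @param reps,seed Monte Carlo controls for the null sample.
#' @return list with `c` (threshold), `gamma` (rejection probability at the
#'   threshold), `alpha`, `method`, `sizes`, `statistic`.
#' @export
null_critical_region <- function(sizes, statistic = "KTMB", alpha = 0.05,
                                 method = c("auto", "enumeration", "monte_carlo"),
                                 enum_limit = getOption("ktmb.crit_enum_limit", 5e4),
                                 reps = 100000L, seed = 20130101L) {
  statistic <- match.arg(statistic, .STATISTICS)
  method <- match.arg(method)
  sizes <- as.integer(sizes)
  if (method == "auto")
    method <- if (count_rank_partitions(sizes) <= enum_limit) "enumeration"
              else "monte_carlo"
  key <- paste0("crit|", .moment_key(sizes, statistic, method), "|", alpha,
                if (method == "monte_carlo") paste0("|", reps, "|", seed) else "")
  hit <- .ktmb_cov_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (method == "enumeration") {
    nd <- enumerate_null_pmf(sizes, statistic, budget = enum_limit)
    support <- nd$support
    probs <- nd$probabilities
  } else {
    N <- sum(sizes)
    grp <- rep(seq_along(sizes), sizes)
    idx <- if (statistic %in% c("KTMB", "TM", "KTP")) .tuple_index(sizes) else NULL
    vals <- numeric(reps)
    old <- .preserve_rng(seed)
    for (r in seq_len(reps)) {
      g <- split(sample.int(N), grp)
      vals[r] <- if (is.null(idx)) .pairwise_sum(g, weighted = statistic == "MJT")
                 else sum(.rows_kernel(.tuple_values(g, idx), statistic))
    }
    .restore_rng(old)
    tb <- table(vals)
    support <- as.numeric(names(tb))
    probs <- as.numeric(tb) / reps
  }
  tail <- rev(cumsum(rev(probs)))
  j <- which(tail > alpha)
  if (length(j) == 0L) j <- 1L else j <- j[length(j)]  # tail crosses alpha at c
  pgt <- if (j < length(support)) tail[j + 1L] else 0
  out <- list(c = support[j], gamma = max(0, (alpha - pgt) / probs[j]),
              alpha = alpha, method = method, sizes = sizes,
              statistic = statistic)
  .ktmb_cov_cache[[key]] <- out
  out
}

# ---- policy front-end -------------------------------------------------------

#' Null moments under a moment policy
#'
#' Returns the null mean and variance of a statistic for a design, choosing
#' the most exact feasible method: closed forms for JT/MJT; for the tuple
#' statistics full enumeration when the partition count is small (at most
#' `enum_limit`), the tie-pattern exact decomposition otherwise, and Monte
#' Carlo when `k` exceeds the tie-pattern cap.
#'
#' @inheritParams enumerate_null_pmf
#' @param method `"auto"` or one of `"enumeration"`, `"tie_pattern_exact"`,
#'   `"closed_form"`, `"monte_carlo"`.
#' @param enum_limit partition-count threshold below which `"auto"` uses full
#'   enumeration for tuple statistics.
#' @param mc_reps,seed Monte Carlo controls.
#' @param cache use the advisory moment cache (see [moment_cache_file]).
#' @return a `"null_moments"` object.
#' @export
null_moments <- function(sizes, statistic = "KTMB",
                         method = c("auto", "enumeration", "tie_pattern_exact",
                                    "closed_form", "monte_carlo"),
                         enum_limit = getOption("ktmb.auto_enum_limit", 1e4),
                         mc_reps = 200000L, seed = 20130101L, cache = TRUE) {
  statistic <- match.arg(statistic, .STATISTICS)
  method <- match.arg(method)
  sizes <- as.integer(sizes)
  if (method == "auto") {
    method <- if (statistic %in% c("JT", "MJT")) "closed_form"
      else if (count_rank_partitions(sizes) <= enum_limit) "enumeration"
      else if (length(sizes) <= getOption("ktmb.tie_pattern_kmax", 5L)) "tie_pattern_exact"
      else "monte_carlo"
  }
  if (cache) {
    hit <- .moment_cache_get(sizes, statistic, method)
    if (!is.null(hit)) return(hit)
  }
  out <- switch(method,
    closed_form = {
      if (!statistic %in% c("JT", "MJT"))
        stop("closed-form moments are available for JT and MJT only", call. = FALSE)
      if (statistic == "JT") jt_null_moments(sizes) else mjt_null_moments(sizes)
    },
    enumeration = {
      nd <- enumerate_null_pmf(sizes, statistic)
      .null_moments(nd$mean, nd$variance, "enumeration", statistic, sizes)
    },
    tie_pattern_exact = exact_null_moments(sizes, statistic, mc_reps = mc_reps,
                                           seed = seed),
    monte_carlo = mc_null_moments(sizes, statistic, reps = mc_reps, seed = seed))
  if (cache) .moment_cache_put(out)
  out
}
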