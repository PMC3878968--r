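# Tuple enumeration index: all combinations of one observation per group, in
# lexicographic order over the index vectors (j1, ..., jk); row-major matrix
# with one tuple per row.
.tuple_index <- function(sizes) {
  idx <- do.call(expand.grid, rev(lapply(sizes, seq_len)))
  as.matrix(idx[, rev(seq_along(sizes)), drop = FALSE])
}

# Build the M x k value matrix for a list of group vectors.
.tuple_values <- function(samples, idx) {
  k <- length(samples)
  V <- matrix(0, nrow(idx), k)
  for (i in seq_len(k)) V[, i] <- samples[[i]][idx[, i]]
  V
}

#' Tuple statistics: KTMB, TM and KTP
#'
#' Sum of a k-tuple kernel over all `prod(sizes)` k-tuplets (one observation
#' per group). The KTMB statistic sums the fixed-point-count kernel, TM the
#' ascending-order indicator, KTP the Spearman rank-correlation kernel.
#'
#' @param x a [sample_set] (or a plain list of numeric vectors).
#' @param kernel one of `"KTMB"`, `"TM"`, `"KTP"`.
#' @param budget maximum number of tuples to enumerate; designs with
#'   `prod(sizes)` above this raise an error rather than silently grinding.
#' @param warn_ties warn when the pooled data contain ties.
#' @return the statistic value (integer-valued for KTMB/TM).
#' @examples
#' tuple_statistic(sample_set(list(c(1, 2), 3, 4)), "KTMB") # 6
#' @export
tuple_statistic <- function(x, kernel = c("KTMB", "TM", "KTP"),
                            budget = getOption("ktmb.tuple_budget", 1e7),
                            warn_ties = TRUE) {
  kernel <- match.arg(kernel)
  x <- sample_set(x)
  .check_kmin3(x)
  n_star <- prod(x$sizes)
  if (n_star > budget)
    stop("tuple enumeration over ", format(n_star, big.mark = ","),
         " tuples exceeds the budget (", format(budget, big.mark = ","),
         "); raise options(ktmb.tuple_budget=) deliberately", call. = FALSE)
  if (warn_ties && x$has_ties)
    warning("ties present; continuous-model kernels use documented tie conventions",
            call. = FALSE)
  idx <- .tuple_index(x$sizes)
  sum(.rows_kernel(.tuple_values(x$samples, idx), kernel))
}

#' Jonckheere-Terpstra statistic
#'
#' Sum over all group pairs `l < m` of the Mann-Whitney count
#' `U_lm = #\{(a, b): x_la < x_mb\}`. Ties contribute nothing (strict
#' comparison only).
#'
#' @inheritParams tuple_statistic
#' @return integer statistic value.
#' @examples
#' jt_statistic(sample_set(list(c(1, 2), 3, 4))) # 5
#' @export
jt_statistic <- function(x) {
  x <- sample_set(x)
  .check_kmin3(x)
  s <- 0
  for (l in seq_len(x$k - 1L))
    for (m in (l + 1L):x$k)
      s <- s + sum(outer(x$samples[[l]], x$samples[[m]], "<"))
  s
}

#' Modified Jonckheere-Terpstra statistic
#'
#' As [jt_statistic] but each pairwise Mann-Whitney count `U_lm` is weighted
#' by the group-index distance `m - l`.
#'
#' @inheritParams tuple_statistic
#' @return statistic value.
#' @examples
#' mjt_statistic(sample_set(list(c(1, 2), 3, 4))) # 7
#' @export
mjt_statistic <- function(x) {
  x <- sample_set(x)
  .check_kmin3(x)
  s <- 0
  for (l in seq_len(x$k - 1L))
    for (m in (l + 1L):x$k)
      s <- s + (m - l) * sum(outer(x$samples[[l]], x$samples[[m]], "<"))
  s
}

.STATISTICS <- c("KTMB", "KTP", "JT", "MJT", "TM")

# Single dispatch point used by inference and simulation.
.stat_value <- function(x, statistic, warn_ties = TRUE) {
  switch(statistic,
    KTMB = ,
    TM = ,
    KTP = tuple_statistic(x, statistic, warn_ties = warn_ties),
    JT = jt_statistic(x),
    MJT = mjt_statistic(x),
    stop("unknown statistic: ", statistic, call. = FALSE))
}

# Fast path for the simulation engine: all requested statistics on one
# dataset given a precomputed tuple index (no validation, no warnings).
.stat_values_fast <- function(samples, statistics, idx) {
  out <- numeric(length(statistics))
  names(out) <- statistics
  tup <- intersect(statistics, c("KTMB", "TM", "KTP"))
  if (length(tup)) {
    V <- .tuple_values(samples, idx)
    for (s in tup) out[s] <- sum(.rows_kernel(V, s))
  }
  if (any(c("JT", "MJT") %in% statistics)) {
    k <- length(samples)
    jt <- 0; mjt <- 0
    for (l in seq_len(k - 1L))
      for (m in (l + 1L):k) {
        u <- sum(outer(samples[[l]], samples[[m]], "<"))
        jt <- jt + u
        mjt <- mjt + (m - l) * u
      }
    if ("JT" %in% statistics) out["JT"] <- jt
    if ("MJT" %in% statistics) out["MJT"] <- mjt
  }
  out
}
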