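#' Within-tuple ranks
#'
#' Rank of each element of a k-tuple with respect to the whole tuple, using
#' the min-rank convention under ties: the rank of `x[i]` is one plus the
#' number of elements strictly smaller than `x[i]`. Tie-free input yields a
#' permutation of `1..k`.
#'
#' @param values numeric vector of length k >= 1 (one observation per group,
#'   in group order).
#' @return integer vector of ranks.
#' @examples
#' rank_within_tuple(c(0.10, 0.05, 0.20, 0.40)) # 2 1 3 4
#' @export
rank_within_tuple <- function(values) {
  if (length(values) == 0L) stop("empty tuple", call. = FALSE)
  values <- as.numeric(values)
  vapply(values, function(v) 1L + sum(values < v), integer(1))
}

#' Fixed-point-count kernel (KTMB)
#'
#' Number of positions `i` in a k-tuple whose within-tuple rank equals `i`,
#' i.e. the number of fixed points of the tuple's rank permutation. For a
#' tie-free tuple the value lies in `{0, 1, ..., k}` excluding `k - 1` (a
#' permutation cannot have exactly `k - 1` fixed points).
#'
#' @inheritParams rank_within_tuple
#' @param warn_ties warn when the tuple contains tied values (the sampling
#'   model assumes continuous responses; ties are handled with min-ranks).
#' @return integer kernel score.
#' @examples
#' ktmb_kernel(c(0.10, 0.05, 0.20, 0.40)) # 2
#' @export
ktmb_kernel <- function(values, warn_ties = TRUE) {
  if (length(values) < 2L) stop("kernel needs a tuple of length >= 2", call. = FALSE)
  if (warn_ties && anyDuplicated(values) > 0L)
    warning("tied values in tuple; min-rank convention applied", call. = FALSE)
  r <- rank_within_tuple(values)
  sum(r == seq_along(r))
}

#' Ascending-order indicator kernel (TM)
#'
#' Indicator that the tuple is non-decreasing with at least one strict
#' inequality; a fully tied tuple scores 0.
#'
#' @inheritParams rank_within_tuple
#' @return 0 or 1.
#' @export
tm_kernel <- function(values) {
  if (length(values) < 2L) stop("kernel needs a tuple of length >= 2", call. = FALSE)
  values <- as.numeric(values)
  k <- length(values)
  as.integer(all(values[-k] <= values[-1]) && values[1] < values[k])
}

#' Spearman rank-correlation kernel (KTP)
#'
#' Spearman correlation between the tuple's within-tuple ranks (average ranks
#' under ties) and the group index vector `1..k`. A fully tied tuple has zero
#' rank variance and scores 0 by convention (no evidence of trend).
#'
#' @inheritParams rank_within_tuple
#' @return real value in `[-1, 1]`.
#' @examples
#' ktp_kernel(c(0.10, 0.05, 0.20, 0.40)) # 0.8
#' @export
ktp_kernel <- function(values) {
  if (length(values) < 2L) stop("kernel needs a tuple of length >= 2", call. = FALSE)
  values <- as.numeric(values)
  k <- length(values)
  r <- rank(values)                      # average ranks under ties
  g <- seq_len(k)
  m <- (k + 1) / 2
  den2 <- sum((r - m)^2) * sum((g - m)^2)
  if (den2 <= 0) return(0)
  sum((r - m) * (g - m)) / sqrt(den2)
}

# ---- vectorized row-wise kernels over a tuple matrix (M x k) ----------------
# These are the workhorses for tuple statistics, exact moment enumeration and
# the simulation engine; V holds one tuple per row, columns in group order.

.rows_ktmb <- function(V) {
  k <- ncol(V)
  fp <- numeric(nrow(V))
  for (i in seq_len(k)) {
    r <- 1
    vi <- V[, i]
    for (j in seq_len(k)) if (j != i) r <- r + (V[, j] < vi)
    fp <- fp + (r == i)
  }
  fp
}

.rows_tm <- function(V) {
  k <- ncol(V)
  ok <- rep(TRUE, nrow(V))
  for (i in seq_len(k - 1L)) ok <- ok & (V[, i] <= V[, i + 1L])
  as.numeric(ok & (V[, 1L] < V[, k]))
}

.rows_ktp <- function(V) {
  k <- ncol(V)
  m <- (k + 1) / 2
  M <- nrow(V)
  num <- numeric(M)
  ss <- numeric(M)                       # sum of squared centred midranks
  for (i in seq_len(k)) {
    vi <- V[, i]
    s <- 0.5                             # self term of the midrank sum
    for (j in seq_len(k)) if (j != i) s <- s + (V[, j] < vi) + 0.5 * (V[, j] == vi)
    ri <- s + 0.5                        # midrank of column i within the row
    num <- num + (ri - m) * (i - m)
    ss <- ss + (ri - m)^2
  }
  den2 <- ss * sum((seq_len(k) - m)^2)
  out <- numeric(M)
  pos <- den2 > 0
  out[pos] <- num[pos] / sqrt(den2[pos])
  out
}

.rows_kernel <- function(V, statistic) {
  switch(statistic,
    KTMB = .rows_ktmb(V),
    TM   = .rows_tm(V),
    KTP  = .rows_ktp(V),
    stop("unknown tuple kernel: ", statistic, call. = FALSE))
}
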