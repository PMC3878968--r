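#' Ordered collection of k independent samples
#'
#' Container for a completely randomized design with `k` groups whose order
#' encodes the alternative hypothesis: group 1 is hypothesized stochastically
#' smallest, group `k` largest (`F1 >= F2 >= ... >= Fk`). The group order is
#' part of the hypothesis and is never rearranged by the package.
#'
#' @param samples list of numeric vectors, one per group, in hypothesis order.
#' @param labels optional character vector of group labels (defaults to
#'   `"G1"..."Gk"`).
#' @return An object of class `"sample_set"`: a list with elements `samples`,
#'   `sizes`, `k`, `labels`, `n` (total observations) and `has_ties` (`TRUE`
#'   when exact duplicates occur anywhere in the pooled data).
#' @examples
#' x <- sample_set(list(c(1, 2), 3, 4))
#' x$sizes
#' @export
sample_set <- function(samples, labels = NULL) {
  if (inherits(samples, "sample_set")) return(samples)
  if (!is.list(samples) || length(samples) < 2L)
    stop("`samples` must be a list of at least two numeric vectors", call. = FALSE)
  samples <- lapply(samples, function(s) {
    s <- as.numeric(s)
    if (length(s) < 1L) stop("every group must contain at least one observation", call. = FALSE)
    if (anyNA(s)) stop("missing values are not allowed", call. = FALSE)
    s
  })
  k <- length(samples)
  if (is.null(labels)) labels <- paste0("G", seq_len(k))
  if (length(labels) != k) stop("`labels` must have one entry per group", call. = FALSE)
  pooled <- unlist(samples, use.names = FALSE)
  structure(
    list(samples = samples, sizes = vapply(samples, length, integer(1)),
         k = k, labels = as.character(labels), n = length(pooled),
         has_ties = anyDuplicated(pooled) > 0L),
    class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("Ordered sample set: k =", x$k, "groups, N =", x$n, "observations\n")
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  if (x$has_ties) cat("  note: pooled data contain ties\n")
  invisible(x)
}

#' @export
as.data.frame.sample_set <- function(x, ...) {
  data.frame(
    group = factor(rep(x$labels, x$sizes), levels = x$labels),
    value = unlist(x$samples, use.names = FALSE))
}

# shared validation for the test statistics (all require k >= 3)
.check_kmin3 <- function(x) {
  if (x$k < 3L)
    stop("ordered-alternative tests require at least 3 groups", call. = FALSE)
  invisible(x)
}
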