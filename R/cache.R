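# Advisory plain-text moment cache: one tab-separated line per
# (sizes, statistic, method) triple. Purely an accelerator -- results are
# identical with the cache disabled. In-memory memoisation is always on;
# the file layer is opt-in via options(ktmb.cache_file=).

.moment_file_cache <- new.env(parent = emptyenv())

#' Advisory moment cache file
#'
#' Null moments can be cached in a plain-text key-value file so repeated runs
#' skip recomputation (mainly useful for Monte Carlo moments). Set
#' `options(ktmb.cache_file = path)` to enable, `NULL` (default) to disable.
#'
#' @return the active cache path, or `NULL` when disabled.
#' @export
moment_cache_file <- function() getOption("ktmb.cache_file", NULL)

.moment_key <- function(sizes, statistic, method)
  paste(statistic, method, paste(sizes, collapse = ","), sep = "|")

.moment_cache_get <- function(sizes, statistic, method) {
  key <- .moment_key(sizes, statistic, method)
  hit <- .moment_file_cache[[key]]
  if (!is.null(hit)) return(hit)
  path <- moment_cache_file()
  if (is.null(path) || !file.exists(path)) return(NULL)
  lines <- readLines(path, warn = FALSE)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) >= 3 && f[1] == key) {
      out <- .null_moments(as.numeric(f[2]), as.numeric(f[3]), method,
                           statistic, sizes,
                           mc_reps = if (length(f) >= 4 && nzchar(f[4])) as.integer(f[4]) else NULL,
                           seed = if (length(f) >= 5 && nzchar(f[5])) as.integer(f[5]) else NULL)
      .moment_file_cache[[key]] <- out
      return(out)
    }
  }
  NULL
}

.moment_cache_put <- function(nm) {
  key <- .moment_key(nm$sizes, nm$statistic, nm$method)
  .moment_file_cache[[key]] <- nm
  path <- moment_cache_file()
  if (is.null(path)) return(invisible(nm))
  line <- paste(key, format(nm$mean, digits = 17), format(nm$variance, digits = 17),
                if (is.null(nm$mc_reps)) "" else nm$mc_reps,
                if (is.null(nm$seed)) "" else nm$seed, sep = "\t")
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(nm)
}
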