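#' One-sided test for a non-decreasing ordered alternative
#'
#' Computes a trend statistic on the ordered samples, standardizes it by its
#' null mean and variance, and reports the upper-tail standard-normal p-value.
#' `H0`: all group distributions equal; `H1`: distributions stochastically
#' non-decreasing in group order with at least one strict inequality. Large
#' statistics support `H1`, so `H0` is rejected when
#' `z = (T - E0[T]) / sqrt(V0[T]) >= qnorm(1 - alpha)`.
#'
#' @param x a [sample_set] (or list of numeric vectors, in hypothesis order).
#' @param statistic one of `"KTMB"`, `"KTP"`, `"JT"`, `"MJT"`, `"TM"`.
#' @param alpha one-sided significance level in `(0, 0.5]`.
#' @param moments moment policy passed to [null_moments] (`"auto"` picks the
#'   most exact feasible method).
#' @param mc_reps,seed Monte Carlo moment controls (used only when the policy
#'   resolves to `"monte_carlo"`).
#' @return An object of class `"trend_test"`: statistic name, observed value,
#'   null mean/variance (and the method that produced them), `z`, one-sided
#'   `p.value`, `alpha`, `reject`, and any tie warnings.
#' @examples
#' ordered_trend_test(sample_set(list(c(1, 2), 3, 4)), "KTMB")
#' @export
ordered_trend_test <- function(x, statistic = c("KTMB", "KTP", "JT", "MJT", "TM"),
                               alpha = 0.05,
                               moments = c("auto", "enumeration", "tie_pattern_exact",
                                           "closed_form", "monte_carlo"),
                               mc_reps = 200000L, seed = 20130101L) {
  statistic <- match.arg(statistic)
  moments <- match.arg(moments)
  x <- sample_set(x)
  .check_kmin3(x)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 0.5)
    stop("`alpha` must lie in (0, 0.5]", call. = FALSE)
  warnings <- character(0)
  obs <- withCallingHandlers(
    .stat_value(x, statistic),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (moments == "auto" && statistic %in% c("JT", "MJT")) moments <- "closed_form"
  nm <- null_moments(x$sizes, statistic, method = moments,
                     mc_reps = mc_reps, seed = seed)
  if (!is.finite(nm$variance) || nm$variance <= 0)
    stop("degenerate null variance for sizes (",
         paste(x$sizes, collapse = ", "), ")", call. = FALSE)
  z <- (obs - nm$mean) / sqrt(nm$variance)
  p <- stats::pnorm(z, lower.tail = FALSE)
  structure(list(statistic_name = statistic, observed = obs,
                 null_mean = nm$mean, null_variance = nm$variance,
                 z = z, p.value = p, alpha = alpha,
                 reject = z >= stats::qnorm(1 - alpha),
                 moments_method = nm$method, sizes = x$sizes,
                 warnings = warnings),
            class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("%s test for a non-decreasing ordered alternative\n", x$statistic_name))
  cat(sprintf("  sizes: (%s)   T = %.6g   E0[T] = %.6g   V0[T] = %.6g [%s]\n",
              paste(x$sizes, collapse = ", "), x$observed, x$null_mean,
              x$null_variance, x$moments_method))
  cat(sprintf("  z = %.4f   one-sided p = %.5g   %s H0 at alpha = %g\n",
              x$z, x$p.value, if (x$reject) "reject" else "do not reject", x$alpha))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Run the full five-test battery
#'
#' Applies the KTMB, KTP, JT, MJT and TM tests to the same ordered samples at
#' a shared significance level, in that fixed report order.
#'
#' @inheritParams ordered_trend_test
#' @param tests subset of statistics to run (default all five).
#' @return An object of class `"trend_battery"`: a named list of
#'   [ordered_trend_test] results.
#' @export
ordered_trend_battery <- function(x, alpha = 0.05, tests = .BATTERY_ORDER,
                                  moments = "auto", mc_reps = 200000L,
                                  seed = 20130101L) {
  tests <- match.arg(tests, .BATTERY_ORDER, several.ok = TRUE)
  tests <- .BATTERY_ORDER[.BATTERY_ORDER %in% tests]
  out <- lapply(tests, function(s)
    ordered_trend_test(x, s, alpha = alpha, moments = moments,
                       mc_reps = mc_reps, seed = seed))
  names(out) <- tests
  structure(out, class = "trend_battery")
}

.BATTERY_ORDER <- c("KTMB", "KTP", "JT", "MJT", "TM")

#' @export
print.trend_battery <- function(x, ...) {
  cat("Ordered-alternative test battery (one-sided, alpha =",
      x[[1]]$alpha, ")\n")
  print(as.data.frame(x), row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
as.data.frame.trend_battery <- function(x, ...) {
  data.frame(
    statistic = vapply(x, `[[`, character(1), "statistic_name"),
    observed = vapply(x, `[[`, numeric(1), "observed"),
    null_mean = vapply(x, `[[`, numeric(1), "null_mean"),
    null_variance = vapply(x, `[[`, numeric(1), "null_variance"),
    z = vapply(x, `[[`, numeric(1), "z"),
    p.value = vapply(x, `[[`, numeric(1), "p.value"),
    reject = vapply(x, `[[`, logical(1), "reject"),
    method = vapply(x, `[[`, character(1), "moments_method"),
    row.names = NULL)
}

#' Write a battery report
#'
#' Serializes battery results as a delimited table followed by a
#' machine-readable key-value metadata block (sizes, moment methods, alpha,
#' tie warnings).
#'
#' @param battery a `"trend_battery"` object.
#' @param path output file path (or `""` for stdout).
#' @param delimiter field delimiter for the table.
#' @export
write_report <- function(battery, path = "", delimiter = "\t") {
  df <- as.data.frame(battery)
  con <- if (nzchar(path)) file(path, "w") else stdout()
  if (nzchar(path)) on.exit(close(con))
  utils::write.table(format(df, digits = 8), con, sep = delimiter,
                     quote = FALSE, row.names = FALSE)
  meta <- c(
    paste0("# sizes=", paste(battery[[1]]$sizes, collapse = ",")),
    paste0("# alpha=", battery[[1]]$alpha),
    paste0("# moments=", paste(df$statistic, df$method, sep = ":", collapse = ";")),
    paste0("# tie_warnings=", length(unlist(lapply(battery, `[[`, "warnings")))))
  writeLines(meta, con)
  invisible(df)
}
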