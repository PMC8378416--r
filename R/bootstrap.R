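#' Bootstrap percentile confidence interval
#'
#' Resamples rows of `data` with replacement `B` times, recomputes the
#' statistic on each resample, and returns the percentile interval whose
#' endpoints are the `ceiling(0.025 B)`-th and `floor(0.975 B)`-th order
#' statistics — for `B = 2000` exactly the 50th and 1950th sorted
#' estimates, for `B = 200` the 5th and 195th.  Resamples on which the
#' statistic is undefined (error or non-finite) are redrawn and counted; if
#' more than `max_fail` of `B` would be needed the interval is refused
#' rather than silently reported.
#'
#' @param data data frame (or vector) to resample by row/element.
#' @param statistic function of a resampled `data` returning a numeric
#'   scalar or fixed-length named vector.
#' @param B number of bootstrap replications (>= 40).
#' @param seed RNG seed; identical seeds give identical intervals.
#' @param max_fail maximum tolerated fraction of undefined resamples.
#' @param keep_estimates retain the B-row matrix of resample estimates.
#' @return object of class `boot_ci`: list with `point`, `lower`, `upper`
#'   (each aligned to the statistic's components), `B`, `seed`,
#'   `n_undefined`, and optionally `estimates`.
#' @export
bootstrap_ci <- function(data, statistic, B = 2000, seed = 1,
                         max_fail = 0.05, keep_estimates = FALSE) {
  if (B < 40) stop("B must be at least 40")
  n <- if (is.data.frame(data) || is.matrix(data)) nrow(data) else length(data)
  take <- function(idx) {
    if (is.data.frame(data) || is.matrix(data)) data[idx, , drop = FALSE]
    else data[idx]
  }
  point <- statistic(data)
  k <- length(point)
  est <- matrix(NA_real_, B, k)
  n_undef <- 0L
  max_undef <- ceiling(max_fail * B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        v <- tryCatch(statistic(take(idx)), error = function(e) NULL)
        if (!is.null(v) && all(is.finite(v))) break
        n_undef <- n_undef + 1L
        if (n_undef > max_undef)
          stop("statistic undefined on more than ", 100 * max_fail,
               "% of bootstrap resamples (", n_undef, " failures)")
      }
      est[b, ] <- v
    }
  })
  lo_i <- ceiling(0.025 * B)
  hi_i <- floor(0.975 * B)
  lower <- apply(est, 2, function(col) sort(col)[lo_i])
  upper <- apply(est, 2, function(col) sort(col)[hi_i])
  names(lower) <- names(upper) <- names(point)
  out <- list(point = point, lower = lower, upper = upper, B = B, seed = seed,
              n_undefined = n_undef)
  if (keep_estimates) out$estimates <- est
  structure(out, class = "boot_ci")
}

#' @export
print.boot_ci <- function(x, digits = 4, ...) {
  tab <- cbind(point = x$point, lower = x$lower, upper = x$upper)
  cat("Bootstrap percentile 95% CI (B = ", x$B, ", seed = ", x$seed, ")\n", sep = "")
  print(round(tab, digits))
  if (x$n_undefined > 0)
    cat("  (", x$n_undefined, " undefined resamples redrawn)\n", sep = "")
  invisible(x)
}
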