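#' External validation of a fitted mRS model
#'
#' Computes, on an external cohort with observed outcomes, the four standard
#' performance measures: Harrell's C for the prediction of functional
#' independence (mRS 0--2), the C-statistic for the full ordinal outcome
#' (patients ranked by the linear predictor), and the calibration intercept
#' and slope of the functional-independence prediction.  Bootstrap
#' percentile 95% CIs resample patients with the model held fixed
#' (external-validation bootstrap, no refitting).
#'
#' @param object an `mrs_fit`.
#' @param data external cohort with predictors and `mrs_90d`.
#' @param B bootstrap replications (default 2000); `B = 0` skips CIs.
#' @param seed bootstrap seed.
#' @return object of class `mrs_validation`: a metric table (`name`,
#'   `point`, `lower`, `upper`) plus `n`, `B`, `seed`.
#' @export
validate_model <- function(object, data, B = 2000, seed = 1) {
  stopifnot(inherits(object, "mrs_fit"))
  if (is.null(data$mrs_90d) || anyNA(data$mrs_90d))
    stop("validation cohort must have complete mrs_90d")
  p_good <- predict(object, data, type = "good")
  lp <- predict(object, data, type = "lp")
  df <- data.frame(p_good = p_good, lp = lp,
                   good = as.numeric(data$mrs_90d <= 2),
                   mrs = as.integer(data$mrs_90d))
  stat <- function(d) {
    cal <- calibration_intercept_slope(d$p_good, d$good)
    c(c_binary = c_binary(d$p_good, d$good),
      c_ordinal = c_ordinal(d$lp, d$mrs),
      cal_intercept = cal$intercept,
      cal_slope = cal$slope)
  }
  point <- stat(df)
  if (B > 0) {
    ci <- bootstrap_ci(df, stat, B = B, seed = seed)
    lower <- ci$lower; upper <- ci$upper
  } else {
    lower <- upper <- rep(NA_real_, length(point))
  }
  tab <- data.frame(metric = names(point), point = unname(point),
                    lower = unname(lower), upper = unname(upper))
  structure(list(metrics = tab, n = nrow(df), B = B, seed = seed),
            class = "mrs_validation")
}

#' @export
print.mrs_validation <- function(x, digits = 3, ...) {
  cat("External validation (n = ", x$n, ")\n", sep = "")
  lab <- c(c_binary = "C (mRS 0-2)", c_ordinal = "C (ordinal mRS)",
           cal_intercept = "Calibration intercept", cal_slope = "Calibration slope")
  tab <- x$metrics
  for (i in seq_len(nrow(tab))) {
    ci <- if (is.na(tab$lower[i])) "" else
      sprintf(" (%s-%s)", format(round(tab$lower[i], digits)),
              format(round(tab$upper[i], digits)))
    cat(sprintf("  %-22s %s%s\n", lab[tab$metric[i]],
                format(round(tab$point[i], digits)), ci))
  }
  if (x$B > 0) cat("  95% bootstrap percentile CIs, B = ", x$B, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.mrs_validation <- function(x, ...) {
  out <- x$metrics
  out$n <- x$n; out$B <- x$B; out$seed <- x$seed
  out
}
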