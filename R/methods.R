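#' @export
print.mrs_fit <- function(x, digits = 4, ...) {
  cat("Proportional-odds model of 90-day mRS",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  cat("  n =", x$n, " logLik =", format(x$logLik, digits = 8), "\n")
  cat("  cutpoints:\n")
  print(round(x$cutpoints, digits))
  cat("  coefficients (positive = better outcome):\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.mrs_fit <- function(object, ...) object$coefficients

#' @export
vcov.mrs_fit <- function(object, ...) object$vcov

#' @export
logLik.mrs_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$cutpoints) + length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
summary.mrs_fit <- function(object, ...) {
  est <- c(object$cutpoints, object$coefficients)
  se <- sqrt(diag(object$vcov))
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  or <- exp(object$coefficients)
  structure(list(coefficients = tab, odds_ratios = or, n = object$n,
                 logLik = object$logLik, converged = object$converged,
                 spec = object$spec),
            class = "summary.mrs_fit")
}

#' @export
print.summary.mrs_fit <- function(x, digits = 4, ...) {
  cat("Proportional-odds model of 90-day mRS (n = ", x$n, ", logLik = ",
      format(x$logLik, digits = 8), ")\n", sep = "")
  if (!x$converged) cat("  ** fit did not converge **\n")
  printCoefmat(x$coefficients, digits = digits, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nCommon odds ratios (per unit, for a shift toward better mRS):\n")
  print(round(x$odds_ratios, digits))
  invisible(x)
}

# linear predictor eta for new data (without cutpoints)
mrs_lp <- function(object, newdata, evt_override = NULL) {
  X <- build_design(newdata, object$spec, cohort_levels = object$cohort_levels,
                    evt_override = evt_override)
  drop(X %*% object$coefficients)
}

# cumulative P(mRS <= j), j = 0..5, given eta; rows = patients
mrs_cumprob <- function(cutpoints, eta) {
  if (any(diff(cutpoints) <= 0))
    stop("invalid model: cutpoints are not strictly increasing")
  outer(eta, cutpoints, function(e, a) plogis(a + e))
}

#' Predict from a fitted mRS model
#'
#' @param object an `mrs_fit`.
#' @param newdata patient table with the spec's predictor columns.
#' @param type `"probs"` (7 per-category probabilities over mRS 0--6),
#'   `"cumulative"` (P(mRS <= j), j = 0..5), `"class"` (modal mRS),
#'   `"lp"` (linear predictor), `"good"` (P(mRS 0--2), functional
#'   independence), or `"benefit"` (difference in P(mRS 0--2) with
#'   `evt` forced to 1 vs 0; see [predicted_benefit()]).
#' @param evt_override force the treatment indicator to 0 or 1 (interactions
#'   are recomputed); ignored for `type = "benefit"`.
#' @param ... unused.
#' @return matrix (`"probs"`, `"cumulative"`) or numeric vector.
#' @export
predict.mrs_fit <- function(object, newdata,
                            type = c("probs", "cumulative", "class", "lp",
                                     "good", "benefit"),
                            evt_override = NULL, ...) {
  type <- match.arg(type)
  if (type == "benefit")
    return(predicted_benefit(object, newdata)$benefit)
  eta <- mrs_lp(object, newdata, evt_override = evt_override)
  if (type == "lp") return(eta)
  cum <- mrs_cumprob(object$cutpoints, eta)
  colnames(cum) <- paste0("mrs<=", 0:5)
  if (type == "cumulative") return(cum)
  if (type == "good") return(cum[, 3])
  pr <- cbind(cum, 1)
  pr <- pr - cbind(0, cum)
  pr <- pmax(pr, 0)
  colnames(pr) <- paste0("mrs", 0:6)
  if (type == "probs") return(pr)
  as.integer(max.col(pr, ties.method = "first") - 1L)
}

#' Individualized predicted treatment benefit
#'
#' Evaluates the model twice per patient with the treatment indicator forced
#' to 1 and to 0 (treatment interactions recomputed from the forced value),
#' sums the probabilities of mRS 0--2 each time, and returns the difference.
#' The patient's recorded `evt` value is ignored.
#'
#' @param object an `mrs_fit` whose spec includes the treatment term.
#' @param newdata patient table.
#' @return data frame with `p_good_treated`, `p_good_control`, `benefit`.
#' @export
predicted_benefit <- function(object, newdata) {
  stopifnot(inherits(object, "mrs_fit"))
  if (!"evt" %in% names(object$coefficients))
    stop("model spec has no treatment (evt) term; benefit is undefined")
  p1 <- predict(object, newdata, type = "good", evt_override = 1)
  p0 <- predict(object, newdata, type = "good", evt_override = 0)
  data.frame(p_good_treated = p1, p_good_control = p0, benefit = p1 - p0)
}

#' Simulate mRS outcomes from a fitted model
#'
#' Draws `nsim` independent outcome vectors from the per-patient category
#' probabilities at the patients' recorded covariates and treatment.
#'
#' @param object an `mrs_fit`.
#' @param nsim number of replicate outcome vectors.
#' @param seed optional RNG seed (restored afterwards).
#' @param newdata patient table.
#' @param ... unused.
#' @return data frame, one column per replicate.
#' @export
simulate.mrs_fit <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  cum <- predict(object, newdata, type = "cumulative")
  n <- nrow(cum)
  with_seed(seed, {
    out <- replicate(nsim, {
      u <- runif(n)
      as.integer(rowSums(u > cum))
    })
  })
  as.data.frame(matrix(out, nrow = n,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

#' Response residuals on the functional-independence scale
#'
#' Observed indicator of mRS 0--2 minus predicted P(mRS 0--2); the natural
#' residual for the model's primary (binary) prediction target.
#'
#' @param object an `mrs_fit`.
#' @param newdata patient table including `mrs_90d`.
#' @param ... unused.
#' @return numeric vector.
#' @export
residuals.mrs_fit <- function(object, newdata, ...) {
  if (is.null(newdata$mrs_90d)) stop("newdata must contain 'mrs_90d'")
  as.numeric(newdata$mrs_90d <= 2) - predict(object, newdata, type = "good")
}

#' Likelihood-ratio test of nested mRS models
#'
#' @param full,reduced `mrs_fit` objects fitted to the identical observation
#'   set; the reduced spec's design columns must be a subset of the full's.
#' @return An object of class `htest` with the chi-square statistic, df and
#'   p-value.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "mrs_fit"), inherits(reduced, "mrs_fit"))
  if (full$n != reduced$n)
    stop("models fitted on different observation counts; not comparable")
  if (!all(names(reduced$coefficients) %in% names(full$coefficients)))
    stop("specs are not nested: reduced model has terms absent from the full model")
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df < 0) stop("specs are not nested: reduced model has more parameters")
  stat <- 2 * (full$logLik - reduced$logLik)
  if (stat < -1e-6)
    warning("full-model log-likelihood below reduced model; check convergence")
  stat <- max(stat, 0)
  structure(list(
    statistic = c(`X-squared` = stat),
    parameter = c(df = df),
    p.value = if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE),
    method = "Likelihood-ratio test of nested proportional-odds models",
    data.name = paste0("full (", length(full$coefficients), " terms) vs reduced (",
                       length(reduced$coefficients), " terms), n = ", full$n)
  ), class = "htest")
}
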