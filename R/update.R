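#' Recalibrate the model intercept on an external cohort
#'
#' Shifts all six cutpoints by a single offset `delta` chosen to maximize
#' the external cohort's likelihood with the regression coefficients held
#' fixed.  This is intercept updating ("calibration-in-the-large" repair):
#' it adapts the baseline outcome level to a new setting without touching
#' predictor effects.
#'
#' @param object a converged `mrs_fit`.
#' @param data external cohort with predictors and `mrs_90d`.
#' @return An `mrs_fit` with shifted cutpoints, identical coefficients, and
#'   a `recalibration` element recording `delta`, the external n and the
#'   external log-likelihood at the optimum.
#' @export
recalibrate_intercepts <- function(object, data) {
  stopifnot(inherits(object, "mrs_fit"))
  if (is.null(data) || nrow(data) == 0L) stop("external cohort is empty")
  if (is.null(data$mrs_90d) || anyNA(data$mrs_90d))
    stop("external cohort must have complete mrs_90d")
  y <- as.integer(data$mrs_90d)
  eta <- mrs_lp(object, data)
  a <- object$cutpoints
  nll <- function(delta) {
    cum <- mrs_cumprob(a + delta, eta)
    pr <- cbind(cum, 1) - cbind(0, cum)
    -sum(log(pmax(pr[cbind(seq_along(y), y + 1L)], 1e-300)))
  }
  opt <- optimize(nll, interval = c(-10, 10), tol = 1e-9)
  out <- object
  out$cutpoints <- a + opt$minimum
  out$recalibration <- list(delta = opt$minimum, n_external = length(y),
                            loglik_external = -opt$objective)
  out
}

#' Refit with a derivation-vs-validation cohort adjustment
#'
#' Fits the spec on a combined cohort with the cohort-adjustment flag on, so
#' the model carries shared predictor coefficients plus main-effect
#' offset(s) for cohort membership (reference = first cohort level).
#'
#' @param data combined patient table with a `cohort` label column holding
#'   at least two distinct labels.
#' @param spec an `mrs_spec`; its `cohort_adjustment` flag is switched on.
#' @param ... passed to [fit_mrs_model()].
#' @return An `mrs_fit`; the cohort offsets appear among the coefficients as
#'   `cohort<label>`.
#' @export
refit_with_cohort_adjustment <- function(data, spec, ...) {
  stopifnot(inherits(spec, "mrs_spec"))
  if (is.null(data$cohort)) stop("data must contain a 'cohort' label column")
  labs <- unique(as.character(data$cohort))
  if (length(labs) < 2L)
    stop("only one cohort label present; use fit_mrs_model() directly")
  spec$cohort_adjustment <- TRUE
  fit_mrs_model(data, spec, cohort_levels = labs, ...)
}
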