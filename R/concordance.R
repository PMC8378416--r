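# Shared concordance kernel.  Convention: a usable pair is two observations
# with different outcome values; it is concordant when the observation with
# the HIGHER outcome has the HIGHER score, ties in score count 1/2, pairs
# tied on outcome are excluded.  Computed per outcome-level pair with a
# sort + findInterval sweep, O(L^2 n log n) for L outcome levels.
concordance_kernel <- function(score, outcome) {
  stopifnot(length(score) == length(outcome))
  if (anyNA(score) || anyNA(outcome)) stop("scores/outcomes must be complete")
  lev <- sort(unique(outcome))
  if (length(lev) < 2L)
    stop("undefined concordance: fewer than 2 distinct outcome values")
  by_lev <- split(score, factor(outcome, levels = lev))
  sorted <- lapply(by_lev, sort)
  nconc <- 0; nties <- 0; npairs <- 0
  L <- length(lev)
  for (i in seq_len(L - 1L)) {
    lo <- sorted[[i]]
    for (j in (i + 1L):L) {
      hi <- by_lev[[j]]
      # pairs where higher-outcome member has strictly higher score
      le <- findInterval(hi, lo)                    # lo <= hi
      lt <- findInterval(hi, lo, left.open = TRUE)  # lo <  hi
      nconc <- nconc + sum(lt)
      nties <- nties + sum(le - lt)
      npairs <- npairs + length(lo) * length(hi)
    }
  }
  (nconc + 0.5 * nties) / npairs
}

#' Concordance for a binary outcome (Harrell's C / AUC)
#'
#' Probability, over all pairs of one patient with and one without the
#' outcome, that the patient with the outcome received the higher predicted
#' probability; tied predictions count 1/2.
#'
#' @param predictions predicted probabilities (or any risk score).
#' @param outcomes binary 0/1 vector (1 = functional independence when
#'   scoring the model's primary prediction).
#' @return concordance in `[0, 1]`.
#' @export
c_binary <- function(predictions, outcomes) {
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be binary 0/1")
  if (length(unique(outcomes)) < 2L)
    stop("undefined concordance: outcomes contain a single class")
  concordance_kernel(predictions, outcomes)
}

#' Ordinal concordance over the full mRS
#'
#' Over all patient pairs with different mRS, the proportion in which the
#' patient with the better (lower) mRS has the higher score; score ties
#' count 1/2; outcome-tied pairs are excluded.  Patients are ranked by a
#' single score, by convention the model's linear predictor (oriented so
#' that higher means better outcome).
#'
#' @param scores numeric scores, higher = predicted better outcome.
#' @param outcomes integer mRS 0--6.
#' @return concordance in `[0, 1]`.
#' @export
c_ordinal <- function(scores, outcomes) {
  if (length(unique(outcomes)) < 2L)
    stop("undefined concordance: all outcomes identical")
  # lower mRS is the better outcome; flip so kernel's "higher outcome" = better
  concordance_kernel(scores, -as.numeric(outcomes))
}

#' Calibration intercept and slope
#'
#' The calibration slope is the coefficient of a logistic regression of the
#' observed binary outcome on the logit of the predicted probability (ideal
#' 1); the calibration intercept ("calibration-in-the-large") is the
#' intercept of a logistic regression with that logit entered as a fixed
#' offset (ideal 0).
#'
#' @param predictions predicted probabilities; values outside
#'   `(eps, 1 - eps)` are clipped with a warning.
#' @param outcomes binary 0/1.
#' @param eps clipping bound for degenerate predictions.
#' @return list with `intercept` and `slope`.
#' @export
calibration_intercept_slope <- function(predictions, outcomes, eps = 1e-8) {
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be binary 0/1")
  if (length(unique(outcomes)) < 2L)
    stop("calibration undefined: outcomes contain a single class")
  if (any(predictions <= eps | predictions >= 1 - eps)) {
    warning("predictions at or beyond (0, 1) clipped at eps = ", eps)
    predictions <- pmin(pmax(predictions, eps), 1 - eps)
  }
  lp <- qlogis(predictions)
  slope <- unname(coef(glm(outcomes ~ lp, family = binomial()))[2])
  intercept <- unname(coef(glm(outcomes ~ 1, offset = lp, family = binomial()))[1])
  list(intercept = intercept, slope = slope)
}

#' Grouped calibration curve
#'
#' Groups patients by predicted probability (deciles by default) and
#' reports, per group, the mean predicted probability, the observed outcome
#' proportion and the count — the standard graphical check of calibration
#' for the functional-independence prediction.
#'
#' @param predictions predicted probabilities.
#' @param outcomes binary 0/1.
#' @param groups number of quantile groups.
#' @return data frame of class `calibration_curve` with columns `group`,
#'   `mean_predicted`, `observed`, `n`.
#' @export
calibration_curve <- function(predictions, outcomes, groups = 10) {
  br <- unique(quantile(predictions, probs = seq(0, 1, length.out = groups + 1)))
  g <- cut(predictions, breaks = br, include.lowest = TRUE)
  out <- data.frame(
    group = levels(g),
    mean_predicted = as.numeric(tapply(predictions, g, mean)),
    observed = as.numeric(tapply(outcomes, g, mean)),
    n = as.integer(table(g))
  )
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' @export
plot.calibration_curve <- function(x, ...) {
  plot(x$mean_predicted, x$observed, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "Predicted probability", ylab = "Observed proportion",
       pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
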