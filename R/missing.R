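# Missing data: MCAR injection and the simple imputation policy
# (mean/mode for sparsely missing fields, single deterministic regression
# imputation when more than the threshold is missing).

#' Inject MCAR missingness
#'
#' Independently blanks each value of each named field with that field's
#' rate.  The outcome column is never blanked unless explicitly listed
#' (cohorts with missing outcomes are excluded upstream, not imputed).
#'
#' @param data patient table.
#' @param rates named per-field rates in `[0, 1]`.
#' @param seed RNG seed for the mask.
#' @return `data` with `NA`s inserted.
#' @export
inject_missingness <- function(data, rates, seed = 1) {
  if (is.null(rates) || length(rates) == 0L) return(data)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  bad <- setdiff(names(rates), names(data))
  if (length(bad)) stop("rates name columns absent from data: ",
                        paste(bad, collapse = ", "))
  with_seed(seed, {
    for (f in names(rates)) {
      if (rates[[f]] <= 0) next
      mask <- runif(nrow(data)) < rates[[f]]
      data[[f]][mask] <- NA
    }
  })
  data
}

.continuous_fields <- c("age", "sbp", "glucose", "onset_to_groin")
.integer_mean_fields <- c("nihss", "aspects")  # mean-imputed, rounded

impute_mode <- function(v) {
  tb <- table(v[!is.na(v)])
  names(tb)[which.max(tb)]
}

#' Impute missing predictor values
#'
#' Applies the study's simple imputation rule: fields with at most
#' `threshold` missing get mean (continuous; integer scores are rounded) or
#' mode (binary/categorical) imputation from the observed values.  Under
#' the `"single_regression"` policy, fields missing above the threshold are
#' instead filled by a deterministic single regression imputation — linear
#' regression for continuous fields, multinomial logistic regression for
#' categorical/binary/ordinal-score fields — on the covariates that are
#' themselves complete; no noise is added.  Under `"mean_mode"` every field
#' gets mean/mode regardless of its missing fraction.  The outcome column
#' must already be complete.
#'
#' @param data patient table with `NA`s in predictor columns.
#' @param policy `"single_regression"` (default) or `"mean_mode"`.
#' @param threshold missing-fraction above which regression imputation is
#'   used (default 0.05).
#' @return completed table (no missing predictor cells).
#' @export
impute_cohort <- function(data, policy = c("single_regression", "mean_mode"),
                          threshold = 0.05) {
  policy <- match.arg(policy)
  if (!is.null(data$mrs_90d) && anyNA(data$mrs_90d))
    stop("outcome column contains missing values; exclude those patients first")
  fields <- intersect(names(.profile_fields()), names(data))
  frac <- vapply(fields, function(f) mean(is.na(data[[f]])), numeric(1))
  if (any(frac == 1))
    stop("field(s) with no observed values cannot be imputed: ",
         paste(fields[frac == 1], collapse = ", "))
  complete_covs <- fields[frac == 0]
  for (f in fields[frac > 0]) {
    idx <- is.na(data[[f]])
    use_reg <- policy == "single_regression" && frac[[f]] > threshold &&
      length(complete_covs) > 0
    if (use_reg) {
      covs <- setdiff(complete_covs, f)
      rhs <- paste(covs, collapse = " + ")
      train <- data[!idx, c(f, covs)]
      newd <- data[idx, covs, drop = FALSE]
      if (f %in% c(.continuous_fields, .integer_mean_fields)) {
        fit <- lm(as.formula(paste(f, "~", rhs)), data = train)
        pred <- predict(fit, newdata = newd)
        if (f %in% .integer_mean_fields) pred <- round(pred)
      } else {
        yy <- factor(train[[f]])
        if (nlevels(yy) < 2L) {
          pred <- rep(levels(yy), sum(idx))
        } else {
          fit <- nnet::multinom(as.formula(paste("yy ~", rhs)),
                                data = cbind(yy = yy, train[covs]),
                                trace = FALSE)
          pred <- as.character(predict(fit, newdata = newd))
        }
        if (!f %in% "occlusion_location") pred <- as.numeric(pred)
      }
      data[[f]][idx] <- pred
    } else {
      if (f %in% .continuous_fields) {
        data[[f]][idx] <- mean(data[[f]], na.rm = TRUE)
      } else if (f %in% .integer_mean_fields) {
        data[[f]][idx] <- round(mean(data[[f]], na.rm = TRUE))
      } else {
        m <- impute_mode(data[[f]])
        if (!f %in% "occlusion_location") m <- as.numeric(m)
        data[[f]][idx] <- m
      }
    }
  }
  data
}
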