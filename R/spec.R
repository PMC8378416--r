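#' Model specification for the outcome/benefit model
#'
#' Defines which baseline predictors enter the cumulative-logit model of the
#' 90-day modified Rankin Scale, how glucose is coded, which
#' treatment-interaction terms are included, and whether a cohort-membership
#' adjustment (derivation vs validation indicator) is added.
#'
#' Fixed codings: occlusion location enters as two indicators (ICA/ICA-T and
#' M2) against an M1 reference; collateral grade and prestroke mRS enter as
#' single linear scores; onset-to-groin time enters linearly in minutes.
#' The treatment indicator `evt` is always a main term, and every requested
#' interaction is `evt` times the named main term.
#'
#' @param main character vector of main-effect predictors (any of
#'   `age`, `nihss`, `sbp`, `iv_alteplase`, `diabetes`, `prestroke_mrs`,
#'   `aspects`, `occlusion_location`, `collateral_grade`, `onset_to_groin`,
#'   `prior_stroke`).
#' @param glucose `NULL` for no glucose term, or a [glucose_term()].
#' @param interactions subset of `c("onset_to_groin", "collateral_grade",
#'   "prior_stroke")`; each is crossed with `evt` and must appear in `main`.
#' @param cohort_adjustment logical; add indicator columns for cohort
#'   membership (reference = first cohort level seen when fitting).
#' @param outcome_levels ordinal outcome levels; fixed at mRS 0--6.
#' @return An object of class `mrs_spec`.
#' @seealso [spec_original()], [spec_updated()] for the shipped presets.
#' @export
model_spec <- function(main,
                       glucose = NULL,
                       interactions = character(),
                       cohort_adjustment = FALSE,
                       outcome_levels = 0:6) {
  allowed <- setdiff(names(.profile_fields()), c("glucose", "evt", "etici_success"))
  bad <- setdiff(main, allowed)
  if (length(bad))
    stop("unknown main terms: ", paste(bad, collapse = ", "))
  if (!is.null(glucose) && !inherits(glucose, "glucose_term"))
    stop("glucose must be NULL or a glucose_term()")
  interactions <- as.character(interactions)
  bad <- setdiff(interactions, c("onset_to_groin", "collateral_grade", "prior_stroke"))
  if (length(bad))
    stop("unsupported interactions: ", paste(bad, collapse = ", "))
  miss <- setdiff(interactions, main)
  if (length(miss))
    stop("interaction terms must reference declared main terms: ",
         paste(miss, collapse = ", "))
  if (!identical(as.integer(outcome_levels), 0:6))
    stop("outcome_levels is fixed at mRS 0..6")
  structure(list(main = main, glucose = glucose,
                 interactions = interactions,
                 cohort_adjustment = isTRUE(cohort_adjustment),
                 outcome_levels = 0:6),
            class = "mrs_spec")
}

#' @export
print.mrs_spec <- function(x, ...) {
  cat("Cumulative-logit model specification (mRS 0-6)\n")
  cat("  main terms:  ", paste(x$main, collapse = ", "), "\n")
  if (is.null(x$glucose)) cat("  glucose:      (none)\n")
  else if (x$glucose$form == "piecewise_linear")
    cat("  glucose:      piecewise linear, knot", x$glucose$knot, "mg/dL\n")
  else
    cat("  glucose:      restricted cubic, knots",
        paste(x$glucose$rcs_knots, collapse = ", "), "mg/dL\n")
  cat("  treatment:    evt",
      if (length(x$interactions))
        paste0(" + interactions with ", paste(x$interactions, collapse = ", "))
      else "", "\n", sep = "")
  if (x$cohort_adjustment) cat("  cohort adjustment: yes\n")
  invisible(x)
}

.preset_main <- c("age", "nihss", "sbp", "iv_alteplase", "diabetes",
                  "prestroke_mrs", "aspects", "occlusion_location",
                  "collateral_grade", "onset_to_groin")

#' Shipped model presets
#'
#' `spec_original()` is the derivation-cohort configuration: ten baseline
#' predictors plus prior stroke, no glucose term, and three treatment
#' interactions (time to treatment, collateral grade, prior stroke).
#' `spec_updated()` is the updated configuration after model revision:
#' glucose added as a (by default piecewise-linear) term, prior stroke
#' removed, and the treatment interactions with time and collateral grade
#' retained.  Coefficient values are never part of a spec; they come from
#' fitting or are supplied explicitly (e.g. to the cohort generator).
#'
#' @param glucose glucose coding for the updated preset.
#' @param cohort_adjustment add a cohort-membership indicator.
#' @return An `mrs_spec`.
#' @export
spec_original <- function(cohort_adjustment = FALSE) {
  model_spec(main = c(.preset_main, "prior_stroke"),
             glucose = NULL,
             interactions = c("onset_to_groin", "collateral_grade", "prior_stroke"),
             cohort_adjustment = cohort_adjustment)
}

#' @rdname spec_original
#' @export
spec_updated <- function(glucose = glucose_term(), cohort_adjustment = FALSE) {
  model_spec(main = .preset_main,
             glucose = glucose,
             interactions = c("onset_to_groin", "collateral_grade"),
             cohort_adjustment = cohort_adjustment)
}
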