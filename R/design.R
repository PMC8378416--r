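# Design-matrix construction.  Column order is fully determined by the spec:
# main terms in the order declared (occlusion expanding to its two indicators,
# glucose to its basis columns), then evt, then evt interactions in the
# declared order, then cohort indicators.

design_colnames <- function(spec, cohort_levels = NULL) {
  cols <- character()
  for (term in spec$main) {
    if (term == "occlusion_location")
      cols <- c(cols, "occlusion_ICA", "occlusion_M2")
    else cols <- c(cols, term)
  }
  if (!is.null(spec$glucose))
    cols <- c(cols, colnames(spline_basis(0, spec$glucose)))
  cols <- c(cols, "evt")
  if (length(spec$interactions))
    cols <- c(cols, paste0("evt:", spec$interactions))
  if (spec$cohort_adjustment) {
    if (is.null(cohort_levels) || length(cohort_levels) < 2L)
      stop("cohort_adjustment requires >= 2 cohort levels")
    cols <- c(cols, paste0("cohort", cohort_levels[-1]))
  }
  cols
}

required_fields <- function(spec) {
  f <- unique(c(spec$main, if (!is.null(spec$glucose)) "glucose", "evt",
                if (spec$cohort_adjustment) "cohort"))
  f
}

check_profile_values <- function(data, fields) {
  defs <- .profile_fields()
  for (f in intersect(fields, names(defs))) {
    v <- data[[f]]
    d <- defs[[f]]
    ok <- switch(d$type,
      binary = all(v %in% c(0, 1)),
      integer = all(v == round(v)) && all(v >= d$range[1] & v <= d$range[2]),
      categorical = all(as.character(v) %in% d$levels),
      continuous = all(is.finite(v)) && (!isTRUE(d$positive) || all(v > 0)))
    if (!ok) stop("invalid values in field '", f, "'")
  }
  invisible(TRUE)
}

#' Build the model design matrix
#'
#' Expands a patient table into the numeric design matrix implied by a
#' model specification.  Occlusion location is coded as two indicators
#' (ICA/ICA-T and M2) against the M1 reference; interaction columns are the
#' product of `evt` with their parent main term; glucose expands per its
#' [glucose_term()].
#'
#' @param data data frame with the fields the spec requires (see
#'   [model_spec()]); one row per patient.
#' @param spec an `mrs_spec`.
#' @param cohort_levels cohort labels defining the indicator coding when
#'   `spec$cohort_adjustment` is on (first level = reference); defaults to
#'   the levels present in `data$cohort`.
#' @param evt_override optional value (0 or 1) overriding the `evt` column,
#'   used for counterfactual benefit predictions.
#' @param validate check field domains (mRS-scale ranges etc.).
#' @return numeric matrix, one row per patient, deterministic column order.
#' @export
build_design <- function(data, spec, cohort_levels = NULL,
                         evt_override = NULL, validate = TRUE) {
  stopifnot(inherits(spec, "mrs_spec"))
  req <- required_fields(spec)
  missing_fields <- setdiff(req, names(data))
  if (length(missing_fields))
    stop("missing required predictor column(s): ",
         paste(missing_fields, collapse = ", "))
  for (f in req) {
    if (anyNA(data[[f]]))
      stop("missing values in required predictor '", f,
           "' - impute before fitting or predicting")
  }
  if (!is.null(evt_override)) {
    stopifnot(evt_override %in% c(0, 1))
    data$evt <- rep(evt_override, nrow(data))
  }
  if (validate) check_profile_values(data, setdiff(req, "cohort"))

  n <- nrow(data)
  out <- vector("list", 0L)
  for (term in spec$main) {
    if (term == "occlusion_location") {
      occ <- as.character(data$occlusion_location)
      out$occlusion_ICA <- as.numeric(occ == "ICA/ICA-T")
      out$occlusion_M2  <- as.numeric(occ == "M2")
    } else {
      out[[term]] <- as.numeric(data[[term]])
    }
  }
  if (!is.null(spec$glucose)) {
    gb <- spline_basis(as.numeric(data$glucose), spec$glucose)
    for (j in colnames(gb)) out[[j]] <- gb[, j]
  }
  out$evt <- as.numeric(data$evt)
  for (term in spec$interactions)
    out[[paste0("evt:", term)]] <- out$evt * as.numeric(data[[term]])
  if (spec$cohort_adjustment) {
    if (is.null(cohort_levels)) {
      cl <- data$cohort
      cohort_levels <- if (is.factor(cl)) levels(cl) else unique(as.character(cl))
    }
    if (length(cohort_levels) < 2L)
      stop("cohort_adjustment requires >= 2 cohort levels")
    lab <- as.character(data$cohort)
    unknown <- setdiff(unique(lab), cohort_levels)
    if (length(unknown))
      stop("cohort label(s) not in cohort_levels: ", paste(unknown, collapse = ", "))
    for (lv in cohort_levels[-1])
      out[[paste0("cohort", lv)]] <- as.numeric(lab == lv)
  }
  X <- do.call(cbind, out)
  rownames(X) <- NULL
  expected <- design_colnames(spec, cohort_levels)
  stopifnot(identical(colnames(X), expected))
  X
}
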