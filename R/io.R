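# Serialization: cohort CSV schema, fitted-model JSON round trip,
# cohort-spec YAML, validation-report JSON/CSV.

#' Read and write cohorts in the documented CSV schema
#'
#' One row per patient; columns named after the predictor fields plus
#' `evt`, optionally `etici_success`, `mrs_90d` (integer 0--6, may be
#' empty) and `cohort` (string label).  Missing values are empty cells.
#' Latent potential-outcome columns of simulated cohorts are dropped on
#' write unless `keep_latent = TRUE`.
#'
#' @param data patient table.
#' @param path CSV file path.
#' @param keep_latent keep `po_mrs_control` / `po_mrs_treated` columns.
#' @return `read_cohort` returns a data frame; `write_cohort` its path,
#'   invisibly.
#' @export
write_cohort <- function(data, path, keep_latent = FALSE) {
  if (!keep_latent)
    data <- data[setdiff(names(data), c("po_mrs_control", "po_mrs_treated"))]
  write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  for (f in c("mrs_90d", "nihss", "aspects", "prestroke_mrs",
              "collateral_grade", "evt", "etici_success",
              "iv_alteplase", "diabetes", "prior_stroke"))
    if (f %in% names(df)) df[[f]] <- as.integer(df[[f]])
  df
}

spec_to_list <- function(spec) {
  list(main = spec$main,
       glucose = if (is.null(spec$glucose)) NULL else unclass(spec$glucose),
       interactions = spec$interactions,
       cohort_adjustment = spec$cohort_adjustment)
}

spec_from_list <- function(x) {
  gl <- if (is.null(x$glucose)) NULL else {
    if (x$glucose$form == "piecewise_linear")
      glucose_term("piecewise_linear", knot = x$glucose$knot)
    else glucose_term("restricted_cubic", rcs_knots = unlist(x$glucose$rcs_knots))
  }
  model_spec(main = unlist(x$main), glucose = gl,
             interactions = if (length(x$interactions)) unlist(x$interactions) else character(),
             cohort_adjustment = isTRUE(x$cohort_adjustment))
}

#' Serialize a fitted model to JSON and back
#'
#' Round-trips cutpoints, coefficients, covariance, log-likelihood, fit
#' metadata and the model spec through a JSON file, at full double
#' precision.
#'
#' @param object an `mrs_fit`.
#' @param path JSON file path.
#' @return `read_model` returns an `mrs_fit`; `write_model` its path,
#'   invisibly.
#' @export
write_model <- function(object, path) {
  stopifnot(inherits(object, "mrs_fit"))
  x <- list(
    cutpoints = as.list(object$cutpoints),
    coefficients = as.list(object$coefficients),
    covariance = unname(apply(object$vcov, 1, as.list)),
    parameter_names = rownames(object$vcov),
    logLik = object$logLik, n = object$n,
    converged = object$converged, grad_norm = object$grad_norm,
    spec = spec_to_list(object$spec),
    cohort_levels = object$cohort_levels,
    recalibration = object$recalibration
  )
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  pn <- unlist(x$parameter_names)
  vc <- do.call(rbind, lapply(x$covariance, function(r) unlist(r)))
  dimnames(vc) <- list(pn, pn)
  out <- list(
    cutpoints = unlist(x$cutpoints),
    coefficients = unlist(x$coefficients),
    vcov = vc,
    logLik = x$logLik, n = x$n,
    converged = isTRUE(x$converged), grad_norm = x$grad_norm,
    iterations = NA_integer_,
    spec = spec_from_list(x$spec),
    cohort_levels = if (length(x$cohort_levels)) unlist(x$cohort_levels) else NULL,
    call = NULL
  )
  if (!is.null(x$recalibration))
    out$recalibration <- lapply(x$recalibration, function(v) v)
  structure(out, class = "mrs_fit")
}

#' Write a cohort scenario to YAML and back
#'
#' Serializes everything in a [cohort_spec()] except function-valued laws
#' (which are refused with an error).
#'
#' @param spec a `cohort_spec`.
#' @param path YAML file path.
#' @return `read_cohort_spec` returns a `cohort_spec`; `write_cohort_spec`
#'   its path, invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(vapply(spec$covariate_laws, is.function, logical(1))))
    stop("function-valued covariate laws cannot be serialized")
  x <- list(
    n = spec$n, design = spec$design,
    covariate_laws = lapply(spec$covariate_laws, unclass),
    truth = list(preset = attr(spec$truth, "preset"),
                 spec = spec_to_list(spec$truth$spec),
                 cutpoints = as.numeric(spec$truth$cutpoints),
                 coefficients = as.list(spec$truth$coefficients)),
    p_reperf = spec$p_reperf,
    reperf_coef = as.list(spec$reperf_coef),
    copula_cor = if (is.null(spec$copula_cor)) NULL else
      list(names = rownames(spec$copula_cor),
           values = as.numeric(spec$copula_cor)),
    missingness = if (is.null(spec$missingness)) NULL else as.list(spec$missingness),
    label = spec$label, seed = spec$seed
  )
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  laws <- lapply(x$covariate_laws, function(l) {
    l$values <- if (!is.null(l$values)) unlist(l$values)
    l$probs <- if (!is.null(l$probs)) unlist(l$probs)
    structure(Filter(Negate(is.null), l), class = "cov_law")
  })
  truth <- list(spec = spec_from_list(x$truth$spec),
                cutpoints = setNames(unlist(x$truth$cutpoints), paste0("mrs<=", 0:5)),
                coefficients = unlist(x$truth$coefficients))
  cop <- if (is.null(x$copula_cor)) NULL else {
    nm <- unlist(x$copula_cor$names)
    matrix(unlist(x$copula_cor$values), length(nm), length(nm),
           dimnames = list(nm, nm))
  }
  cohort_spec(n = x$n, design = x$design, covariate_laws = laws,
              truth = truth, p_reperf = x$p_reperf,
              reperf_coef = unlist(x$reperf_coef), copula_cor = cop,
              missingness = if (is.null(x$missingness)) NULL else unlist(x$missingness),
              label = x$label, seed = x$seed)
}

#' Write a validation report
#'
#' `write_validation_csv` writes one row per metric (`metric`, `point`,
#' `lower`, `upper`, `n`, `B`, `seed`), mirroring a performance table with
#' 95% CIs; `write_validation_json` writes the same content as JSON.
#'
#' @param report an `mrs_validation`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_validation_csv <- function(report, path) {
  stopifnot(inherits(report, "mrs_validation"))
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_validation_csv
#' @export
write_validation_json <- function(report, path) {
  stopifnot(inherits(report, "mrs_validation"))
  jsonlite::write_json(
    list(metrics = report$metrics, n = report$n, B = report$B, seed = report$seed),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
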