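#' Glucose term specification
#'
#' Describes how baseline glucose enters the linear predictor: either a
#' piecewise-linear ("hinge") form with a single knot, or a restricted cubic
#' spline (natural spline in truncated-power form, linear beyond the boundary
#' knots).  The piecewise-linear default uses a knot at 120 mg/dL, so the two
#' coefficients are directly interpretable as the log-odds slope below the
#' knot and the change in slope above it.
#'
#' @param form `"piecewise_linear"` or `"restricted_cubic"`.
#' @param knot knot (mg/dL) for the piecewise-linear form.
#' @param rcs_knots strictly increasing knots (mg/dL) for the restricted
#'   cubic form; at least 3.
#' @return An object of class `glucose_term`.
#' @export
#' @examples
#' glucose_term()                                   # hinge at 120 mg/dL
#' glucose_term("restricted_cubic", rcs_knots = c(80, 120, 180))
glucose_term <- function(form = c("piecewise_linear", "restricted_cubic"),
                         knot = 120, rcs_knots = c(80, 120, 180)) {
  form <- match.arg(form)
  if (form == "piecewise_linear") {
    stopifnot(is.numeric(knot), length(knot) == 1L, is.finite(knot))
    out <- list(form = form, knot = knot)
  } else {
    if (length(rcs_knots) < 3L || any(diff(rcs_knots) <= 0))
      stop("rcs_knots must be >= 3 strictly increasing values")
    out <- list(form = form, rcs_knots = as.numeric(rcs_knots))
  }
  structure(out, class = "glucose_term")
}

#' Spline basis for the glucose term
#'
#' Expands glucose values into the basis columns implied by a
#' [glucose_term()].  The piecewise-linear form returns `(x, max(0, x - knot))`.
#' The restricted cubic form returns the linear term plus `k - 2`
#' truncated-power terms in Harrell's restricted parameterization: each
#' nonlinear term is identically zero at or below the first knot and the
#' whole expansion is linear beyond the last knot.  Nonlinear terms are
#' scaled by the squared boundary-knot span so their coefficients are on a
#' per-unit scale comparable to the linear term.
#'
#' @param x numeric vector of glucose values (mg/dL); must be finite.
#' @param term a [glucose_term()].
#' @return Numeric matrix with `length(x)` rows; column names
#'   `glucose`, `glucose_hinge` or `glucose_rcs1`, ...
#' @export
spline_basis <- function(x, term) {
  stopifnot(inherits(term, "glucose_term"))
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("glucose values must be finite numbers")
  if (term$form == "piecewise_linear") {
    out <- cbind(glucose = x, glucose_hinge = pmax(0, x - term$knot))
  } else {
    k <- term$rcs_knots
    nk <- length(k)
    t1 <- k[1]; tkm <- k[nk - 1]; tk <- k[nk]
    scl <- (tk - t1)^2
    cub <- function(u) pmax(u, 0)^3
    nl <- vapply(seq_len(nk - 2), function(j) {
      (cub(x - k[j]) -
         cub(x - tkm) * (tk - k[j]) / (tk - tkm) +
         cub(x - tk) * (tkm - k[j]) / (tk - tkm)) / scl
    }, numeric(length(x)))
    nl <- matrix(nl, nrow = length(x))
    colnames(nl) <- paste0("glucose_rcs", seq_len(nk - 2))
    out <- cbind(glucose = x, nl)
  }
  rownames(out) <- NULL
  out
}
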