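#' Match treated and control patients on predicted benefit
#'
#' Builds treated/control pairs for the c-for-benefit: the larger arm is
#' randomly down-sampled (seeded) to the size of the smaller, both arms are
#' sorted by predicted benefit, and patients are paired rank by rank
#' (default) or by greedy nearest-neighbour on predicted benefit.  Each
#' retained patient appears in exactly one pair.  The pair's predicted
#' benefit is the arithmetic mean of its two members'; the pair's observed
#' benefit is the treated member's good-outcome indicator minus the
#' control's, in {-1, 0, 1}.
#'
#' @param benefit per-patient predicted benefit.
#' @param treated arm indicator, 1 = treated (or reperfused, in surrogate
#'   mode), 0 = control.
#' @param good binary good-outcome indicator (mRS 0--2).
#' @param seed seed for the down-sampling draw.
#' @param method `"rank"` (default) or `"nearest"` (greedy nearest
#'   neighbour, sensitivity analysis).
#' @param ids optional patient identifiers (default row positions).
#' @return data frame of class `benefit_pairs`: `treated_id`, `control_id`,
#'   `benefit_treated`, `benefit_control`, `pair_predicted`,
#'   `pair_observed`.
#' @export
match_benefit_pairs <- function(benefit, treated, good, seed = 1,
                                method = c("rank", "nearest"), ids = NULL) {
  method <- match.arg(method)
  stopifnot(length(benefit) == length(treated), length(good) == length(treated))
  if (!all(treated %in% c(0, 1))) stop("treated must be 0/1")
  if (is.null(ids)) ids <- seq_along(benefit)
  it <- which(treated == 1)
  ic <- which(treated == 0)
  if (length(it) == 0L || length(ic) == 0L)
    stop("both arms must be nonempty to form matched pairs")
  m <- min(length(it), length(ic))
  with_seed(seed, {
    if (length(it) > m) it <- sort(sample(it, m))
    if (length(ic) > m) ic <- sort(sample(ic, m))
  })
  it <- it[order(benefit[it])]
  ic <- ic[order(benefit[ic])]
  if (method == "nearest") {
    # greedy sweep over the pooled benefit ordering of the two sorted arms
    sel_c <- integer(m)
    used <- rep(FALSE, m)
    for (k in seq_len(m)) {
      d <- abs(benefit[ic] - benefit[it[k]])
      d[used] <- Inf
      j <- which.min(d)
      sel_c[k] <- j
      used[j] <- TRUE
    }
    ic <- ic[sel_c]
  }
  out <- data.frame(
    treated_id = ids[it], control_id = ids[ic],
    benefit_treated = benefit[it], benefit_control = benefit[ic],
    pair_predicted = (benefit[it] + benefit[ic]) / 2,
    pair_observed = good[it] - good[ic]
  )
  class(out) <- c("benefit_pairs", "data.frame")
  out
}

#' c-for-benefit
#'
#' Concordance between predicted and observed treatment benefit across
#' matched treated/control pairs: over all pairs-of-pairs with different
#' observed benefit, the proportion in which the pair with the greater
#' observed benefit also has the greater predicted benefit; ties in
#' predicted benefit count 1/2; pairs-of-pairs tied on observed benefit are
#' excluded.
#'
#' @param pairs a `benefit_pairs` data frame (from
#'   [match_benefit_pairs()]), or a numeric vector of pair predicted
#'   benefits when `observed` is supplied.
#' @param observed pair observed benefits in {-1, 0, 1}, if `pairs` is a
#'   numeric vector.
#' @return concordance in `[0, 1]`.  All observed benefits identical is an
#'   error (the metric is undefined, not 0.5).
#' @export
c_for_benefit <- function(pairs, observed = NULL) {
  if (is.data.frame(pairs)) {
    predicted <- pairs$pair_predicted
    observed <- pairs$pair_observed
  } else predicted <- pairs
  if (length(predicted) < 2L) stop("need at least 2 matched pairs")
  if (length(unique(observed)) < 2L)
    stop("undefined c-for-benefit: all pairs have the same observed benefit")
  concordance_kernel(predicted, observed)
}

benefit_breaks <- function(benefit, grouping, class_breaks) {
  if (grouping == "quintiles") {
    br <- unique(quantile(benefit, probs = seq(0, 1, 0.2), type = 7))
    if (length(br) < 2L) br <- c(br, br + 1e-12)  # all-equal degenerate case
    attr(br, "labels") <- paste0("Q", seq_len(length(br) - 1L))
  } else {
    br <- c(-Inf, class_breaks, Inf)
    attr(br, "labels") <- c("low (<1%)", "moderate (1-10%)", "high (>10%)")
  }
  br
}

#' Calibration of predicted treatment benefit by group
#'
#' Groups patients on predicted benefit (quintiles of the cohort's own
#' predicted-benefit distribution, or the three fixed classes with cut
#' points 1% and 10%) and compares, per group, the mean predicted benefit
#' with the observed benefit: the difference in the proportion of
#' functional independence (mRS 0--2) between the two arms.
#'
#' @param benefit per-patient predicted benefit.
#' @param treated arm indicator (1/0): randomized treatment, or reperfusion
#'   success in surrogate mode.
#' @param good binary good-outcome indicator.
#' @param grouping `"quintiles"` or `"classes"`.
#' @param class_breaks cut points for the classes grouping.
#' @param surrogate label the contrast as a reperfusion-surrogate (not
#'   causal benefit).
#' @return data frame of class `benefit_group_table`: per group `group`,
#'   `lower`, `upper` (bounds on predicted benefit), `n_treated`,
#'   `n_control`, `mean_predicted`, `observed` (NA with `flagged = TRUE`
#'   when a group lacks one arm).
#' @export
benefit_group_table <- function(benefit, treated, good,
                                grouping = c("quintiles", "classes"),
                                class_breaks = c(0.01, 0.10),
                                surrogate = FALSE) {
  grouping <- match.arg(grouping)
  stopifnot(length(benefit) == length(treated), length(good) == length(treated))
  br <- benefit_breaks(benefit, grouping, class_breaks)
  labs <- attr(br, "labels")
  g <- cut(benefit, breaks = br, include.lowest = TRUE, labels = FALSE)
  ng <- length(br) - 1L
  rows <- lapply(seq_len(ng), function(k) {
    sel <- which(g == k)
    n1 <- sum(treated[sel] == 1); n0 <- sum(treated[sel] == 0)
    obs <- if (n1 > 0 && n0 > 0)
      mean(good[sel][treated[sel] == 1]) - mean(good[sel][treated[sel] == 0])
    else NA_real_
    data.frame(group = labs[k], lower = br[k], upper = br[k + 1L],
               n_treated = n1, n_control = n0,
               mean_predicted = if (length(sel)) mean(benefit[sel]) else NA_real_,
               observed = obs, flagged = n1 == 0 || n0 == 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "surrogate") <- isTRUE(surrogate)
  attr(out, "grouping") <- grouping
  class(out) <- c("benefit_group_table", "data.frame")
  out
}

#' @export
print.benefit_group_table <- function(x, digits = 3, ...) {
  cat(if (isTRUE(attr(x, "surrogate")))
        "Reperfusion-surrogate benefit contrast"
      else "Treatment-benefit calibration",
      " by ", attr(x, "grouping"), "\n", sep = "")
  df <- as.data.frame(x)
  df$mean_predicted <- round(df$mean_predicted, digits)
  df$observed <- round(df$observed, digits)
  print(df, row.names = FALSE)
  if (isTRUE(attr(x, "surrogate")))
    cat("(observed column contrasts reperfused vs non-reperfused patients;\n",
        " it is a surrogate, not a causal treatment effect)\n", sep = "")
  invisible(x)
}

#' Benefit-group calibration of a fitted model on a randomized cohort
#'
#' Convenience wrapper: computes each patient's predicted benefit under the
#' model and tabulates [benefit_group_table()] against the randomized arms.
#'
#' @param object an `mrs_fit`.
#' @param data randomized cohort with `evt` and `mrs_90d`.
#' @inheritParams benefit_group_table
#' @return a `benefit_group_table`.
#' @export
benefit_group_calibration <- function(object, data,
                                      grouping = c("quintiles", "classes"),
                                      class_breaks = c(0.01, 0.10)) {
  grouping <- match.arg(grouping)
  b <- predicted_benefit(object, data)$benefit
  benefit_group_table(b, data$evt, as.numeric(data$mrs_90d <= 2),
                      grouping = grouping, class_breaks = class_breaks)
}

#' Registry reperfusion-surrogate benefit contrast
#'
#' For an all-treated registry without a control arm, contrasts outcomes of
#' patients with successful reperfusion (eTICI >= 2b) against
#' non-successfully treated patients within predicted-benefit groups.  The
#' output is labelled a surrogate contrast, never a causal benefit.
#'
#' @param object an `mrs_fit`.
#' @param data registry cohort: all `evt = 1`, with `etici_success` and
#'   `mrs_90d`.
#' @inheritParams benefit_group_table
#' @return a `benefit_group_table` with the surrogate label.
#' @export
registry_surrogate_benefit <- function(object, data,
                                       grouping = c("classes", "quintiles"),
                                       class_breaks = c(0.01, 0.10)) {
  grouping <- match.arg(grouping)
  if (!all(data$evt == 1))
    stop("surrogate contrast requires an all-treated (evt = 1) registry cohort")
  if (is.null(data$etici_success) || anyNA(data$etici_success))
    stop("registry cohort must have a complete etici_success column")
  b <- predicted_benefit(object, data)$benefit
  benefit_group_table(b, data$etici_success, as.numeric(data$mrs_90d <= 2),
                      grouping = grouping, class_breaks = class_breaks,
                      surrogate = TRUE)
}

#' @export
plot.benefit_group_table <- function(x, ...) {
  mids <- seq_len(nrow(x))
  graphics::barplot(rbind(x$mean_predicted, x$observed), beside = TRUE,
                    names.arg = x$group,
                    legend.text = c("predicted", "observed"),
                    ylab = "Benefit (difference in P(mRS 0-2))", ...)
  invisible(x)
}
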