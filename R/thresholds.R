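#' Calibrate a density-decrease cutpoint against the control group
#'
#' The decrease threshold for an automated measure is anchored to an external
#' reference rule (e.g. a visual 10-percentage-point decrease) by choosing
#' the cutpoint under which exactly `reference_count` control-group women
#' qualify as "decrease" (change <= cutpoint). The cutpoint returned is the
#' `reference_count`-th smallest control change.
#'
#' @param control_changes Transformed-scale density changes in the control
#'   group.
#' @param reference_count Number of control women the decrease category must
#'   contain.
#' @return The calibrated cutpoint. `-Inf` when `reference_count` is 0.
#' @export
calibrate_cutpoint <- function(control_changes, reference_count) {
  x <- control_changes[!is.na(control_changes)]
  n <- length(x)
  stopifnot(reference_count >= 0, reference_count <= n)
  if (reference_count == 0) return(-Inf)
  cut <- sort(x)[reference_count]
  achieved <- sum(x <= cut)
  if (achieved != reference_count) {
    achievable <- sort(unique(vapply(sort(unique(x)),
                                     function(c) sum(x <= c), numeric(1))))
    stop("ties at the candidate cutpoint: ", achieved,
         " controls at or below it (requested ", reference_count,
         "); achievable counts: ",
         paste(utils::head(achievable, 10), collapse = ", "), call. = FALSE)
  }
  cut
}

#' Classify a density change into three categories
#'
#' Change greater than or equal to the no-change boundary (0 by default) is
#' "no change"; change less than or equal to the calibrated decrease cutpoint
#' is "decrease"; anything in between is "intermediate". Both boundaries are
#' inclusive of their own category.
#'
#' @param change Transformed-scale density change(s).
#' @param decrease_cut Calibrated decrease cutpoint (negative).
#' @param no_change_cut No-change boundary (default 0).
#' @return Factor with levels `no_change`, `intermediate`, `decrease`.
#' @export
classify_change <- function(change, decrease_cut, no_change_cut = 0) {
  stopifnot(decrease_cut < no_change_cut)
  out <- ifelse(change >= no_change_cut, "no_change",
                ifelse(change <= decrease_cut, "decrease", "intermediate"))
  factor(out, levels = c("no_change", "intermediate", "decrease"))
}

# Wilson score interval for a single proportion
wilson_ci <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = centre - half, high = centre + half)
}

#' Difference in decrease percentage between groups
#'
#' The absolute difference, in percentage points, between the proportion of
#' tamoxifen-group and control-group women classified as "decrease", with a
#' confidence interval by the Newcombe hybrid score method (default) or a
#' Wald interval.
#'
#' @param tam_counts,ctrl_counts Length-3 count vectors in category order
#'   (no change, intermediate, decrease).
#' @param level Confidence level.
#' @param method `"newcombe"` or `"wald"`.
#' @return List with `difference`, `ci_low`, `ci_high` (percentage points)
#'   and `method`.
#' @export
decrease_difference <- function(tam_counts, ctrl_counts, level = 0.95,
                                method = c("newcombe", "wald")) {
  method <- match.arg(method)
  stopifnot(length(tam_counts) == 3, length(ctrl_counts) == 3)
  n1 <- sum(tam_counts); n2 <- sum(ctrl_counts)
  if (n1 == 0 || n2 == 0) stop("zero group size", call. = FALSE)
  x1 <- unname(tam_counts[3]); x2 <- unname(ctrl_counts[3])
  p1 <- x1 / n1; p2 <- x2 / n2
  d <- p1 - p2
  if (method == "newcombe") {
    w1 <- wilson_ci(x1, n1, level)
    w2 <- wilson_ci(x2, n2, level)
    lo <- d - sqrt((p1 - w1["low"])^2 + (w2["high"] - p2)^2)
    hi <- d + sqrt((w1["high"] - p1)^2 + (p2 - w2["low"])^2)
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
    lo <- d - z * se
    hi <- d + z * se
  }
  list(difference = 100 * unname(d), ci_low = 100 * unname(lo),
       ci_high = 100 * unname(hi), method = method)
}

#' Full cutpoint calibration and classification for one measure
#'
#' Calibrates the decrease cutpoint on control-group 1-year changes, applies
#' the three-category classification to both groups at the requested horizon
#' (reusing the year-1 cutpoint at year 2), and computes the decrease
#' difference with its confidence interval.
#'
#' @param changes_tam,changes_ctrl Transformed-scale changes at the horizon
#'   being classified.
#' @param decrease_cut Calibrated cutpoint (from year-1 control changes).
#' @param measure,horizon Labels carried into the result.
#' @param level,method Passed to [decrease_difference()].
#' @return A `cutpoint_result` list: `measure`, `horizon`, `no_change_cut`,
#'   `decrease_cut`, `counts` (3x2 matrix), `decrease_difference`, `ci_low`,
#'   `ci_high`.
#' @export
cutpoint_result <- function(changes_tam, changes_ctrl, decrease_cut,
                            measure = NA_character_, horizon = "T1_T0",
                            level = 0.95, method = "newcombe") {
  ct <- table(classify_change(changes_tam, decrease_cut))
  cc <- table(classify_change(changes_ctrl, decrease_cut))
  counts <- cbind(tamoxifen = as.integer(ct), control = as.integer(cc))
  rownames(counts) <- c("no_change", "intermediate", "decrease")
  dd <- decrease_difference(counts[, "tamoxifen"], counts[, "control"],
                            level = level, method = method)
  structure(
    list(measure = measure, horizon = horizon, no_change_cut = 0,
         decrease_cut = decrease_cut, counts = counts,
         decrease_difference = dd$difference, ci_low = dd$ci_low,
         ci_high = dd$ci_high, ci_method = dd$method),
    class = "cutpoint_result"
  )
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("%s %s: cutpoints 0 / %.3f (x10: %.1f)\n",
              x$measure, x$horizon, x$decrease_cut, 10 * x$decrease_cut))
  print(x$counts)
  cat(sprintf("decrease difference %.0f%% (%.0f-%.0f%%)\n",
              x$decrease_difference, x$ci_low, x$ci_high))
  invisible(x)
}

# round half away from zero, as in printed percentage tables
round_half_up <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
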