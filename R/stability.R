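#' Build 1-year / 2-year change pairs
#'
#' For each woman with visits at baseline, year 1 and year 2 (sample C), the
#' pair of change scores `delta1 = y(1) - y(0)` and `delta2 = y(2) - y(0)` on
#' the standardised (or transformed) scale. The stability test is run in the
#' tamoxifen group by default.
#'
#' @param records_std Tibble with `participant_id`, `time`, `value` for one
#'   measure.
#' @param participants Participant tibble (used to restrict by group).
#' @param group Group to retain (`"tamoxifen"`, `"control"` or `"both"`).
#' @return Tibble with columns `participant_id`, `delta1`, `delta2`.
#' @export
change_pairs <- function(records_std, participants, group = "tamoxifen") {
  if (group != "both") {
    keep_ids <- participants$id[participants$group == group]
    records_std <- records_std[records_std$participant_id %in% keep_ids, ]
  }
  wide <- tidyr::pivot_wider(
    records_std[records_std$time %in% c(0, 1, 2),
                c("participant_id", "time", "value")],
    names_from = "time", values_from = "value", names_prefix = "t"
  )
  for (cn in c("t0", "t1", "t2")) if (!cn %in% names(wide)) wide[[cn]] <- NA_real_
  wide <- wide[stats::complete.cases(wide[, c("t0", "t1", "t2")]), ]
  tibble::tibble(
    participant_id = wide$participant_id,
    delta1 = wide$t1 - wide$t0,
    delta2 = wide$t2 - wide$t0
  )
}

#' Prequential stability test of 1-year density change
#'
#' Compares two predictors of a woman's 2-year change: her own observed
#' 1-year change (individual predictor) against the cohort mean 1-year change
#' (reference predictor, the same value for everyone). Predictive ability is
#' measured by mean squared error; a relative MSE above 1 means individual
#' 1-year change is a worse predictor than the cohort mean, i.e. the change
#' measure is unstable at the individual level.
#'
#' @param pairs Tibble from [change_pairs()] with `delta1`, `delta2`.
#' @return A `stability_result` list: `mse_reference`, `mse_individual`,
#'   `relative`, `n`. MSEs are on the squared standardised scale (multiply by
#'   100 for display). `relative` is `NA` (flagged) if `mse_reference` is 0.
#' @export
prequential_mse <- function(pairs) {
  stopifnot(all(c("delta1", "delta2") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 2) stop("at least 2 women are required", call. = FALSE)
  mse_ref <- mean((pairs$delta2 - mean(pairs$delta1))^2)
  mse_ind <- mean((pairs$delta2 - pairs$delta1)^2)
  structure(
    list(
      mse_reference = mse_ref,
      mse_individual = mse_ind,
      relative = if (mse_ref > 0) mse_ind / mse_ref else NA_real_,
      flag = if (mse_ref > 0) NA_character_ else "reference MSE is zero",
      n = n
    ),
    class = "stability_result"
  )
}

#' Percentile-bootstrap confidence interval for the relative MSE
#'
#' Women are resampled with replacement; the reference predictor (the mean
#' 1-year change) is recomputed within every resample before the relative MSE
#' is evaluated, so its sampling uncertainty is propagated.
#'
#' @param pairs Tibble with `delta1`, `delta2` (n >= 10 for a meaningful CI).
#' @param n_resamples Number of resamples (default 3000).
#' @param seed Integer seed (required).
#' @param level Confidence level.
#' @return A `stability_result` with `ci_low`, `ci_high`, `n_resamples`.
#' @export
bootstrap_relative <- function(pairs, n_resamples = 3000, seed, level = 0.95) {
  stopifnot(!missing(seed))
  res <- prequential_mse(pairs)
  if (res$n < 10) {
    warning("fewer than 10 women; bootstrap CI will be unreliable")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  n <- res$n
  draws <- rep(NA_real_, n_resamples)
  for (b in seq_len(n_resamples)) {
    rows <- sample.int(n, n, replace = TRUE)
    d1 <- pairs$delta1[rows]
    d2 <- pairs$delta2[rows]
    ref <- mean((d2 - mean(d1))^2)
    if (ref > 0) draws[b] <- mean((d2 - d1)^2) / ref
  }
  n_degenerate <- sum(is.na(draws))
  if (n_degenerate > 0.05 * n_resamples) {
    stop("more than 5% of resamples had zero reference MSE", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  qs <- stats::quantile(draws[!is.na(draws)], c(alpha, 1 - alpha),
                        type = 7, names = FALSE)
  res$ci_low <- qs[1]
  res$ci_high <- qs[2]
  res$n_resamples <- n_resamples
  res$level <- level
  res
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Prequential MSE (x100): reference %.1f, individual %.1f\n",
              100 * x$mse_reference, 100 * x$mse_individual))
  if (!is.null(x$ci_low)) {
    cat(sprintf("relative %.2f (%d%% CI %.2f-%.2f; %d resamples)\n",
                x$relative, round(100 * x$level), x$ci_low, x$ci_high,
                x$n_resamples))
  } else {
    cat(sprintf("relative %.2f\n", x$relative))
  }
  invisible(x)
}

#' Classification disagreement between 1-year and 2-year change
#'
#' Classifies each woman's change (no change / intermediate / decrease, per
#' [classify_change()]) using the same cutpoints at both horizons and returns
#' the fraction of women whose category differs — a further indicator of
#' instability of individual 1-year change.
#'
#' @param delta1,delta2 Changes at the two horizons (transformed scale).
#' @param decrease_cut Calibrated decrease cutpoint.
#' @param no_change_cut No-change boundary (default 0).
#' @return Proportion in `[0, 1]`.
#' @export
threshold_agreement <- function(delta1, delta2, decrease_cut,
                                no_change_cut = 0) {
  stopifnot(length(delta1) == length(delta2))
  c1 <- classify_change(delta1, decrease_cut, no_change_cut)
  c2 <- classify_change(delta2, decrease_cut, no_change_cut)
  mean(c1 != c2)
}
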