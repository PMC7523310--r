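#' Published density-change classification counts
#'
#' Three-category classification counts (no change / intermediate / decrease,
#' by treatment group) of density change at 1 and 2 years, as published for
#' the motivating tamoxifen-prevention cohort, together with the printed
#' decrease differences and confidence intervals. The decrease percentages
#' and their group difference are exactly recomputable from these counts (see
#' [reference_decrease_differences()]).
#'
#' @return Tibble with one row per measure-horizon.
#' @export
reference_category_counts <- function() {
  path <- system.file("extdata", "reference_category_counts.csv",
                      package = "mdchange")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Published prequential mean-squared-error table
#'
#' MSE (x100) of the reference predictor (cohort mean 1-year change) and the
#' individual predictor (a woman's own 1-year change) for 2-year density
#' change, as published for the motivating cohort, with the printed relative
#' performance and bootstrap CI.
#'
#' @return Tibble with one row per measure.
#' @export
reference_stability_mse <- function() {
  path <- system.file("extdata", "reference_stability_mse.csv",
                      package = "mdchange")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Recompute decrease differences from the published counts
#'
#' For each measure-horizon, recomputes the tamoxifen-minus-control
#' difference in the percentage of women classified as "decrease" from the
#' raw 3x2 counts, rounded half-up to integer percentage points for
#' comparison with the printed values.
#'
#' @param counts Tibble as returned by [reference_category_counts()].
#' @return The tibble with columns `recomputed_difference` (integer
#'   percentage points) and `recomputed_difference_raw` appended.
#' @export
reference_decrease_differences <- function(counts = reference_category_counts()) {
  raw <- purrr::pmap_dbl(counts, function(tam_no_change, tam_intermediate,
                                          tam_decrease, ctrl_no_change,
                                          ctrl_intermediate, ctrl_decrease,
                                          ...) {
    decrease_difference(
      c(tam_no_change, tam_intermediate, tam_decrease),
      c(ctrl_no_change, ctrl_intermediate, ctrl_decrease)
    )$difference
  })
  counts$recomputed_difference_raw <- raw
  counts$recomputed_difference <- round_half_up(raw)
  counts
}

#' Recompute relative predictive performance from the published MSE table
#'
#' Divides each measure's individual-predictor MSE by its reference-predictor
#' MSE, rounded to one decimal for comparison with the printed ratios.
#'
#' @param mse Tibble as returned by [reference_stability_mse()].
#' @return The tibble with `recomputed_relative` (1 decimal) and
#'   `recomputed_relative_raw` appended.
#' @export
reference_relative_mse <- function(mse = reference_stability_mse()) {
  mse$recomputed_relative_raw <- mse$mse_individual_x100 / mse$mse_reference_x100
  mse$recomputed_relative <- round_half_up(mse$recomputed_relative_raw, 1)
  mse
}
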