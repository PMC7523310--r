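#' Fit baseline standardisation parameters
#'
#' Density measures are compared on a common scale by centring each
#' transformed measure at its baseline mean and scaling by its baseline
#' inter-quartile range (IQR), so a unit on the standardised scale is one
#' baseline IQR. Quartiles use linear interpolation between order statistics
#' (quantile type 7); this convention is fixed for reproducibility.
#'
#' @param x Transformed-scale baseline values (at least 4, non-degenerate IQR).
#' @param measure Optional measure name carried in the result.
#' @return An object of class `standardization_params` with elements
#'   `measure`, `baseline_mean`, `baseline_iqr`.
#' @export
fit_standardization <- function(x, measure = NA_character_) {
  x <- x[!is.na(x)]
  if (length(x) < 4) {
    stop("at least 4 baseline values are required to fit standardisation",
         call. = FALSE)
  }
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr <= 0) {
    stop("baseline IQR is zero for measure '", measure,
         "'; standardisation undefined", call. = FALSE)
  }
  structure(
    list(measure = measure, baseline_mean = mean(x), baseline_iqr = iqr),
    class = "standardization_params"
  )
}

#' Standardise transformed density values
#'
#' @param x Transformed-scale values.
#' @param params A `standardization_params` object from [fit_standardization()].
#' @return `(x - baseline_mean) / baseline_iqr`.
#' @export
standardize <- function(x, params) {
  stopifnot(inherits(params, "standardization_params"))
  (x - params$baseline_mean) / params$baseline_iqr
}

#' @rdname standardize
#' @export
unstandardize <- function(x, params) {
  stopifnot(inherits(params, "standardization_params"))
  x * params$baseline_iqr + params$baseline_mean
}

#' Repeated-measures correlation between two density measures
#'
#' Weighted Pearson correlation over all paired visits, with each observation
#' of woman i weighted 1/n_i (n_i = her number of paired visits) so that every
#' woman contributes equal total weight regardless of follow-up length. This
#' targets the between-women association of the two measures while using all
#' repeated observations.
#'
#' @param x,y Paired visit-level values of two measures.
#' @param id Woman identifier for each observation.
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) if either
#'   measure has zero weighted variance.
#' @export
repeated_measures_correlation <- function(x, y, id) {
  stopifnot(length(x) == length(y), length(x) == length(id))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]; id <- id[keep]
  if (length(unique(id)) < 3) {
    stop("at least 3 women with paired observations are required", call. = FALSE)
  }
  n_i <- table(id)
  w <- 1 / as.numeric(n_i[match(id, names(n_i))])
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) {
    warning("zero variance in one of the measures; correlation undefined")
    return(NA_real_)
  }
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Pairwise repeated-measures correlation matrix
#'
#' @param records Long tibble with columns `participant_id`, `time`,
#'   `measure`, `value` (transformed or raw; correlation is invariant to
#'   monotone affine rescaling only, so supply a common scale).
#' @param measures Character vector of measure names to correlate.
#' @return A symmetric correlation matrix.
#' @export
correlation_table <- function(records, measures = NULL) {
  if (is.null(measures)) measures <- unique(records$measure)
  wide <- tidyr::pivot_wider(
    records[records$measure %in% measures,
            c("participant_id", "time", "measure", "value")],
    names_from = "measure", values_from = "value"
  )
  k <- length(measures)
  out <- matrix(NA_real_, k, k, dimnames = list(measures, measures))
  for (i in seq_len(k)) {
    out[i, i] <- 1
    for (j in seq_len(k)) {
      if (j <= i) next
      out[i, j] <- out[j, i] <- repeated_measures_correlation(
        wide[[measures[i]]], wide[[measures[j]]], wide$participant_id
      )
    }
  }
  out
}
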