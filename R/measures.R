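#' Define a density measure
#'
#' A measure specification names a density reading, the physical quantity it
#' reports, and the variance-stabilising transformation applied before
#' modelling: percentage (area-based) density is square-root transformed,
#' while volumetric percentage density and dense volume are natural-log
#' transformed.
#'
#' @param name Measure name, e.g. `"volpara_pct"`.
#' @param quantity One of `"area_percent"`, `"volumetric_percent"`,
#'   `"dense_area"`, `"dense_volume"`, `"breast_area"`, `"total_volume"`.
#' @param transform `"sqrt"` or `"log"`. Defaults to the conventional
#'   transform for the quantity (log for volumetric percent and dense volume,
#'   sqrt otherwise).
#' @return A one-row tibble with columns `name`, `quantity`, `transform`.
#' @export
measure_spec <- function(name,
                         quantity = c("area_percent", "volumetric_percent",
                                      "dense_area", "dense_volume",
                                      "breast_area", "total_volume"),
                         transform = NULL) {
  quantity <- match.arg(quantity)
  default <- if (quantity %in% c("volumetric_percent", "dense_volume")) "log" else "sqrt"
  if (is.null(transform)) transform <- default
  transform <- match.arg(transform, c("sqrt", "log"))
  if (quantity %in% c("volumetric_percent", "dense_volume") && transform != "log") {
    stop("quantity '", quantity, "' must use the log transform", call. = FALSE)
  }
  if (quantity == "area_percent" && transform != "sqrt") {
    stop("area percentage density must use the sqrt transform", call. = FALSE)
  }
  tibble::tibble(name = name, quantity = quantity, transform = transform)
}

#' Default automated percentage density measures
#'
#' The four fully automated percentage density measures used throughout the
#' package: three area-based readings (square-root transformed) and one
#' volumetric reading (log transformed).
#'
#' @return A tibble of measure specifications.
#' @export
default_measures <- function() {
  dplyr::bind_rows(
    measure_spec("stratus_pct", "area_percent"),
    measure_spec("densitas_pct", "area_percent"),
    measure_spec("nnvas_pct", "area_percent"),
    measure_spec("volpara_pct", "volumetric_percent")
  )
}

#' Transform raw density values to the modelling scale
#'
#' @param value Numeric vector of raw density values.
#' @param transform `"sqrt"` or `"log"`.
#' @param measure Optional measure name used in error messages.
#' @return Transformed values (strictly monotone in `value`).
#' @export
transform_value <- function(value, transform = c("sqrt", "log"), measure = NULL) {
  transform <- match.arg(transform)
  label <- if (is.null(measure)) "" else paste0(" for measure '", measure, "'")
  ok <- !is.na(value)
  if (transform == "log") {
    bad <- which(ok & value <= 0)
    if (length(bad) > 0) {
      stop("log transform requires positive values", label,
           "; offending records: ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
    log(value)
  } else {
    bad <- which(ok & value < 0)
    if (length(bad) > 0) {
      stop("sqrt transform requires non-negative values", label,
           "; offending records: ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
    sqrt(value)
  }
}

#' Invert a density transform
#'
#' @param value Transformed values.
#' @param transform `"sqrt"` or `"log"`.
#' @return Values on the native measurement scale.
#' @export
inverse_transform_value <- function(value, transform = c("sqrt", "log")) {
  transform <- match.arg(transform)
  if (transform == "log") exp(value) else value^2
}
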