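#' Read a long-format cohort file
#'
#' The ingestion format is one CSV with a row per (participant, visit,
#' measure): columns `participant_id`, `group` (`tamoxifen`/`control`),
#' `age_baseline`, `bmi`, `baseline_year`, `treatment_stop`, `time`,
#' `measure`, `value`; missing values are empty fields. `treatment_stop` is
#' years since baseline at drug cessation (empty for controls and for women
#' who completed therapy).
#'
#' @param path Path to the CSV file.
#' @return A list with tibbles `participants` (one row per woman) and
#'   `records` (one row per woman-visit-measure, raw scale).
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  required <- c("participant_id", "group", "age_baseline", "bmi",
                "baseline_year", "treatment_stop", "time", "measure", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  participants <- dplyr::distinct(
    df, .data$participant_id, .data$group, .data$age_baseline, .data$bmi,
    .data$baseline_year, .data$treatment_stop
  )
  names(participants)[names(participants) == "participant_id"] <- "id"
  if (anyDuplicated(participants$id) > 0) {
    stop("inconsistent participant covariates across rows", call. = FALSE)
  }
  validate_participants(participants)
  records <- df[, c("participant_id", "time", "measure", "value")]
  list(participants = participants, records = records)
}

#' Write a cohort in the long ingestion format
#'
#' @param cohort A list with `participants` and `records` as produced by
#'   [generate_cohort()] or [read_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- dplyr::left_join(
    cohort$records,
    dplyr::rename(cohort$participants[, c("id", "group", "age_baseline",
                                          "bmi", "baseline_year",
                                          "treatment_stop")],
                  participant_id = "id"),
    by = "participant_id"
  )
  df <- df[, c("participant_id", "group", "age_baseline", "bmi",
               "baseline_year", "treatment_stop", "time", "measure", "value")]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

validate_participants <- function(participants) {
  stopifnot(all(c("id", "group", "age_baseline", "bmi", "baseline_year",
                  "treatment_stop") %in% names(participants)))
  if (!all(participants$group %in% c("tamoxifen", "control"))) {
    stop("group must be 'tamoxifen' or 'control'", call. = FALSE)
  }
  if (any(participants$age_baseline <= 0, na.rm = TRUE)) {
    stop("age_baseline must be positive", call. = FALSE)
  }
  stop_t <- participants$treatment_stop
  if (any(!is.na(stop_t) & participants$group == "control")) {
    stop("controls cannot have a treatment_stop", call. = FALSE)
  }
  if (any(!is.na(stop_t) & stop_t < 0)) {
    stop("treatment_stop must be non-negative", call. = FALSE)
  }
  invisible(participants)
}

#' Aggregate per-image density values at one visit
#'
#' The per-visit density is the arithmetic mean over all available views and
#' both breasts (up to four images: MLO and CC of each side). Missing
#' individual images are dropped rather than discarding the visit.
#'
#' @param per_image_values Numeric vector of per-image density values.
#' @return Their mean.
#' @export
aggregate_views <- function(per_image_values) {
  v <- per_image_values[!is.na(per_image_values)]
  if (length(v) == 0) {
    stop("no usable images at this visit", call. = FALSE)
  }
  mean(v)
}

#' Keep only visits at which every required measure is available
#'
#' To compare measures on identical visits, a (woman, visit) is retained only
#' when all required measures have a non-missing value there; otherwise every
#' measure at that visit is dropped together.
#'
#' @param records Long tibble (`participant_id`, `time`, `measure`, `value`).
#' @param required_measures Character vector of measure names that must all
#'   be present.
#' @return The filtered records.
#' @export
filter_complete_timepoints <- function(records, required_measures) {
  if (nrow(records) == 0) return(records)
  ok <- records[!is.na(records$value) & records$measure %in% required_measures, ]
  complete <- dplyr::summarise(
    dplyr::group_by(ok, .data$participant_id, .data$time),
    n_measures = dplyr::n_distinct(.data$measure), .groups = "drop"
  )
  complete <- complete[complete$n_measures == length(required_measures), ]
  dplyr::semi_join(records, complete, by = c("participant_id", "time"))
}

#' Censor treated women's records at drug cessation
#'
#' Only mammograms taken during active treatment are analysed: records of a
#' tamoxifen-group woman after her `treatment_stop` are dropped. The baseline
#' visit (time 0, before drug start) is always retained; control records pass
#' through unchanged.
#'
#' @param records Long tibble of density records.
#' @param participants Participant tibble with `id`, `group`, `treatment_stop`.
#' @return The censored records.
#' @export
censor_on_treatment <- function(records, participants) {
  stops <- participants$treatment_stop[match(records$participant_id,
                                             participants$id)]
  grp <- participants$group[match(records$participant_id, participants$id)]
  keep <- records$time == 0 | is.na(stops) | grp != "tamoxifen" |
    records$time <= stops
  records[keep, , drop = FALSE]
}

#' Match controls to cases by age and baseline year
#'
#' Each case receives up to `max_per_case` controls with baseline age within
#' one year and the same baseline calendar year; each control is used at most
#' once. When more eligible controls exist than needed, the smallest absolute
#' age difference wins, with lexicographic id as the deterministic tie-break.
#'
#' @param cases,pool Participant tibbles (disjoint).
#' @param max_per_case Maximum controls per case (default 2).
#' @return A tibble with columns `case_id`, `control_id`.
#' @export
match_controls <- function(cases, pool, max_per_case = 2) {
  if (length(intersect(cases$id, pool$id)) > 0) {
    stop("case and control pools must be disjoint", call. = FALSE)
  }
  used <- character(0)
  out <- vector("list", nrow(cases))
  case_order <- order(cases$id)
  for (k in case_order) {
    eligible <- pool[abs(pool$age_baseline - cases$age_baseline[k]) <= 1 &
                       pool$baseline_year == cases$baseline_year[k] &
                       !(pool$id %in% used), , drop = FALSE]
    if (nrow(eligible) == 0) next
    pref <- order(abs(eligible$age_baseline - cases$age_baseline[k]),
                  eligible$id)
    take <- eligible$id[pref][seq_len(min(max_per_case, nrow(eligible)))]
    used <- c(used, take)
    out[[k]] <- tibble::tibble(case_id = cases$id[k], control_id = take)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(case_id = character(0), control_id = character(0))
  }
  res
}

#' Build the nested analysis samples
#'
#' Sample A contains women with density at baseline; B those additionally
#' with a year-1 visit; C the subset of B with a year-2 visit. Membership is
#' assessed on records that have already been view-aggregated,
#' completeness-filtered and treatment-censored. Each sample carries all
#' qualifying visits of its members (the longitudinal model uses full
#' trajectories).
#'
#' @param records Filtered long records.
#' @param participants Participant tibble.
#' @return A named list of `analysis_sample` objects `A`, `B`, `C`.
#' @export
build_samples <- function(records, participants) {
  times <- split(records$time, records$participant_id)
  has <- function(t) names(times)[vapply(times, function(v) t %in% v, logical(1))]
  ids_a <- has(0)
  ids_b <- intersect(ids_a, has(1))
  ids_c <- intersect(ids_b, has(2))
  mk <- function(label, ids) {
    structure(
      list(label = label, participant_ids = sort(ids),
           records = records[records$participant_id %in% ids, , drop = FALSE],
           participants = participants[participants$id %in% ids, , drop = FALSE]),
      class = "analysis_sample"
    )
  }
  list(A = mk("A", ids_a), B = mk("B", ids_b), C = mk("C", ids_c))
}

#' @export
print.analysis_sample <- function(x, ...) {
  cat("Analysis sample", x$label, "-", length(x$participant_ids), "women,",
      nrow(x$records), "records\n")
  invisible(x)
}

#' Descriptive summary of a numeric vector
#'
#' Standard descriptive statistics; for distributions of density change the
#' mean/SD ratio is a unit-free effect size. With fewer than two values, or a
#' constant vector, SD-based statistics are returned as `NA` and flagged.
#'
#' @param x Numeric values (missing dropped).
#' @return One-row tibble: `n`, `median`, `q1`, `q3`, `min`, `max`, `mean`,
#'   `sd`, `mean_sd`, `flag`.
#' @export
summarize_values <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) {
    return(tibble::tibble(n = 0L, median = NA_real_, q1 = NA_real_,
                          q3 = NA_real_, min = NA_real_, max = NA_real_,
                          mean = NA_real_, sd = NA_real_, mean_sd = NA_real_,
                          flag = "empty"))
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  s <- if (n >= 2) stats::sd(x) else NA_real_
  flag <- if (n < 2) "sd undefined (n < 2)"
          else if (s == 0) "mean/SD undefined (constant)"
          else NA_character_
  tibble::tibble(
    n = n, median = q[2], q1 = q[1], q3 = q[3], min = min(x), max = max(x),
    mean = mean(x), sd = s,
    mean_sd = if (!is.na(s) && s > 0) mean(x) / s else NA_real_,
    flag = flag
  )
}

#' Baseline / year-1 descriptive table
#'
#' Summaries of each measure at baseline (T0), year 1 (T1) and the within-
#' woman change T1 - T0, by treatment group, on the native measurement scale.
#'
#' @param records Long records (raw scale).
#' @param participants Participant tibble.
#' @param measures Measure names (default: all in `records`).
#' @return A tidy tibble of descriptive statistics.
#' @export
density_summary_table <- function(records, participants, measures = NULL) {
  if (is.null(measures)) measures <- unique(records$measure)
  grp <- participants$group[match(records$participant_id, participants$id)]
  records <- dplyr::mutate(records, group = grp)
  rows <- list()
  for (m in measures) {
    rm_ <- records[records$measure == m, ]
    for (g in c("tamoxifen", "control")) {
      rg <- rm_[rm_$group == g, ]
      b <- rg$value[rg$time == 0]
      y1 <- rg$value[rg$time == 1]
      wide <- merge(rg[rg$time == 0, c("participant_id", "value")],
                    rg[rg$time == 1, c("participant_id", "value")],
                    by = "participant_id")
      chg <- wide$value.y - wide$value.x
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(measure = m, group = g,
                       statistic = c("T0", "T1", "T1-T0")),
        dplyr::bind_rows(summarize_values(b), summarize_values(y1),
                         summarize_values(chg))
      )
    }
  }
  dplyr::bind_rows(rows)
}
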