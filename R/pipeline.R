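#' Run the full density-change analysis pipeline
#'
#' Executes, in order: ingestion, completeness filtering (visits must carry
#' every analysed measure), on-treatment censoring, nested sample
#' construction (A/B/C), BMI mean imputation, transformation and baseline-IQR
#' standardisation, descriptive summaries, repeated-measures correlations,
#' the step-and-ramp mixed model per measure (with profile CIs for the
#' treatment terms, ICC with cluster-bootstrap CI, and the treated-group
#' sensitivity refit), control-calibrated cutpoint classification at both
#' horizons, and the prequential stability test.
#'
#' @param cohort A cohort list (`participants` + `records`), a path to a
#'   long-format CSV, or a [generator_config()] (which is generated first).
#' @param measure_specs Tibble mapping `name` to `transform` for the measures
#'   to analyse (default [default_measures()], restricted to measures present
#'   in the data).
#' @param reference_count Control-group decrease count the cutpoints are
#'   calibrated to; default 16% of sample-C controls (rounded).
#' @param boot Bootstrap resamples for the ICC and relative-MSE intervals.
#' @param seed Integer seed controlling every random element.
#' @param profile_parms Fixed effects given profile-likelihood CIs.
#' @return A `report_bundle` list with elements `table1` (descriptives),
#'   `table2` (correlation matrix), `model_table`, `table3` (cutpoint
#'   classification), `table4` (stability), `trajectory` (mean standardised
#'   density per group and visit), `samples`, `meta`.
#' @export
run_pipeline <- function(cohort,
                         measure_specs = default_measures(),
                         reference_count = NULL,
                         boot = 200,
                         seed = 1,
                         profile_parms = c("group_step", "group_ramp")) {
  if (inherits(cohort, "generator_config")) cohort <- generate_cohort(cohort)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  participants <- validate_participants(cohort$participants)
  records <- cohort$records

  specs <- measure_specs[measure_specs$name %in% unique(records$measure), ]
  if (nrow(specs) == 0) stop("no analysable measures in the data", call. = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  records <- stage("completeness filter",
                   filter_complete_timepoints(records, specs$name))
  records <- stage("treatment censoring",
                   censor_on_treatment(records, participants))
  samples <- stage("sample construction", build_samples(records, participants))
  participants <- stage("BMI imputation", impute_bmi(participants))

  rec_a <- samples$A$records
  table1 <- stage("descriptives",
                  density_summary_table(rec_a, participants, specs$name))

  ## transformed and standardised records (sample A baseline anchors) -----
  transformed <- dplyr::bind_rows(lapply(seq_len(nrow(specs)), function(j) {
    r <- records[records$measure == specs$name[j], ]
    r$value <- transform_value(r$value, specs$transform[j], specs$name[j])
    r
  }))
  std_params <- lapply(seq_len(nrow(specs)), function(j) {
    base <- transformed[transformed$measure == specs$name[j] &
                          transformed$time == 0 &
                          transformed$participant_id %in%
                            samples$A$participant_ids, ]
    fit_standardization(base$value, specs$name[j])
  })
  names(std_params) <- specs$name
  standardized <- dplyr::bind_rows(lapply(specs$name, function(m) {
    r <- transformed[transformed$measure == m, ]
    r$value <- standardize(r$value, std_params[[m]])
    r
  }))

  ## correlations between measures (control group, sample A) --------------
  ctrl_ids <- participants$id[participants$group == "control"]
  tr_ctrl <- transformed[transformed$participant_id %in%
                           intersect(ctrl_ids, samples$A$participant_ids), ]
  table2 <- stage("correlation", correlation_table(tr_ctrl, specs$name))

  ## mixed models ----------------------------------------------------------
  model_rows <- list()
  icc_results <- list()
  for (j in seq_along(specs$name)) {
    m <- specs$name[j]
    rs <- standardized[standardized$measure == m &
                         standardized$participant_id %in%
                           samples$A$participant_ids, ]
    mf <- build_design(rs, participants)
    fit <- stage(paste0("lmm fit (", m, ")"), fit_density_lmm(mf))
    cis <- lapply(profile_parms, function(p) profile_ci(fit, p))
    names(cis) <- profile_parms
    icc <- stage(paste0("ICC bootstrap (", m, ")"),
                 bootstrap_icc(mf, n_resamples = boot, seed = seed + j))
    icc_results[[m]] <- icc
    tam <- stage(paste0("tamoxifen-only refit (", m, ")"),
                 fit_tamoxifen_only(mf))
    beta_rows <- tibble::tibble(
      measure = m, term = names(fit$beta), estimate = unname(fit$beta),
      ci_low = NA_real_, ci_high = NA_real_, method = NA_character_
    )
    for (p in profile_parms) {
      k <- which(beta_rows$term == p)
      beta_rows$ci_low[k] <- cis[[p]]["low"]
      beta_rows$ci_high[k] <- cis[[p]]["high"]
      beta_rows$method[k] <- attr(cis[[p]], "method")
    }
    extra <- tibble::tibble(
      measure = m,
      term = c("var_intercept", "var_slope", "cov_int_slope", "var_resid",
               "loglik", "icc", "corr_int_slope_tamoxifen"),
      estimate = c(fit$var_intercept, fit$var_slope, fit$cov_int_slope,
                   fit$var_resid, fit$loglik, icc$icc, tam$corr_int_slope),
      ci_low = c(rep(NA_real_, 5), icc$ci_low, NA_real_),
      ci_high = c(rep(NA_real_, 5), icc$ci_high, NA_real_),
      method = c(rep(NA_character_, 5), "cluster bootstrap", NA_character_)
    )
    model_rows[[m]] <- dplyr::bind_rows(beta_rows, extra)
  }
  model_table <- dplyr::bind_rows(model_rows)

  ## cutpoints and classification (sample C, transformed scale) -----------
  tam_ids <- participants$id[participants$group == "tamoxifen"]
  c_ids <- samples$C$participant_ids
  n_ctrl_c <- length(intersect(c_ids, ctrl_ids))
  if (is.null(reference_count)) {
    reference_count <- round_half_up(0.16 * n_ctrl_c)
  }
  table3_rows <- list()
  for (m in specs$name) {
    tr <- transformed[transformed$measure == m &
                        transformed$participant_id %in% c_ids, ]
    wide <- tidyr::pivot_wider(tr[tr$time %in% c(0, 1, 2), ],
                               names_from = "time", values_from = "value",
                               names_prefix = "t")
    wide <- wide[stats::complete.cases(wide[, c("t0", "t1", "t2")]), ]
    d1 <- wide$t1 - wide$t0
    d2 <- wide$t2 - wide$t0
    is_t <- wide$participant_id %in% tam_ids
    cut <- stage(paste0("cutpoint calibration (", m, ")"),
                 calibrate_cutpoint(d1[!is_t], reference_count))
    for (h in c("T1_T0", "T2_T0")) {
      dh <- if (h == "T1_T0") d1 else d2
      cr <- cutpoint_result(dh[is_t], dh[!is_t], cut, measure = m, horizon = h)
      table3_rows[[paste(m, h)]] <- tibble::tibble(
        measure = m, horizon = h,
        no_change_cut = 0, decrease_cut = cut,
        decrease_cut_x10 = 10 * cut,
        tam_no_change = cr$counts["no_change", "tamoxifen"],
        tam_intermediate = cr$counts["intermediate", "tamoxifen"],
        tam_decrease = cr$counts["decrease", "tamoxifen"],
        ctrl_no_change = cr$counts["no_change", "control"],
        ctrl_intermediate = cr$counts["intermediate", "control"],
        ctrl_decrease = cr$counts["decrease", "control"],
        decrease_difference = cr$decrease_difference,
        ci_low = cr$ci_low, ci_high = cr$ci_high,
        t1_t2_disagreement = if (h == "T2_T0")
          threshold_agreement(d1[is_t], d2[is_t], cut) else NA_real_
      )
    }
  }
  table3 <- dplyr::bind_rows(table3_rows)

  ## stability (sample C tamoxifen group, standardised scale) -------------
  table4_rows <- list()
  for (j in seq_along(specs$name)) {
    m <- specs$name[j]
    rs <- standardized[standardized$measure == m &
                         standardized$participant_id %in% c_ids, ]
    pairs <- change_pairs(rs, participants, group = "tamoxifen")
    sr <- stage(paste0("stability (", m, ")"),
                bootstrap_relative(pairs, n_resamples = boot,
                                   seed = seed + 100 + j))
    table4_rows[[m]] <- tibble::tibble(
      measure = m, n = sr$n,
      mse_reference_x100 = 100 * sr$mse_reference,
      mse_individual_x100 = 100 * sr$mse_individual,
      relative = sr$relative, ci_low = sr$ci_low, ci_high = sr$ci_high
    )
  }
  table4 <- dplyr::bind_rows(table4_rows)

  ## mean standardised trajectory (sample A) ------------------------------
  grp <- participants$group[match(standardized$participant_id, participants$id)]
  traj <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(standardized, group = grp),
                    .data$measure, .data$group, .data$time),
    n = dplyr::n(), mean = mean(.data$value),
    se = stats::sd(.data$value) / sqrt(dplyr::n()), .groups = "drop"
  )

  structure(
    list(table1 = table1, table2 = table2, model_table = model_table,
         table3 = table3, table4 = table4, trajectory = traj,
         samples = lapply(samples, function(s) s$participant_ids),
         icc = icc_results,
         meta = list(seed = seed, boot = boot,
                     reference_count = reference_count,
                     measures = specs,
                     n_women = nrow(participants),
                     clip_events = cohort$clip_events %||% NA_integer_)),
    class = "report_bundle"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.report_bundle <- function(x, ...) {
  cat("Density-change report bundle\n")
  cat(sprintf("  women: %d (samples A/B/C: %d/%d/%d)\n", x$meta$n_women,
              length(x$samples$A), length(x$samples$B), length(x$samples$C)))
  cat("  measures:", paste(x$meta$measures$name, collapse = ", "), "\n")
  cat(sprintf("  seed %d, %d bootstrap resamples, reference count %d\n",
              x$meta$seed, x$meta$boot, x$meta$reference_count))
  cat("  tables: table1, table2, model_table, table3, table4, trajectory\n")
  invisible(x)
}

#' Write every table of a report bundle as CSV
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$table1, file.path(dir, "table1_descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$table2),
                   file.path(dir, "table2_correlations.csv"))
  utils::write.csv(bundle$model_table, file.path(dir, "model_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$table3, file.path(dir, "table3_cutpoints.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$table4, file.path(dir, "table4_stability.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$trajectory, file.path(dir, "trajectory.csv"),
                   row.names = FALSE)
  invisible(dir)
}
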