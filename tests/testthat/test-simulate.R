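test_that("generation is deterministic given the config seed", {
  cfg <- generator_config(n_cases = 25, seed = 61)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$records, c2$records)
  c3 <- generate_cohort(generator_config(n_cases = 25, seed = 62))
  expect_false(identical(c1$records$value, c3$records$value))
})

test_that("with all variances zero the trajectory equals the design mean exactly", {
  cfg <- generator_config(
    n_cases = 10, var_intercept = 0, var_slope = 0, corr_int_slope = 0,
    var_resid = 0, var_resid_baseline = 0, missing_density_rate = 0,
    seed = 63
  )
  coh <- generate_cohort(cfg)
  grp <- coh$participants$group[match(coh$records$participant_id,
                                      coh$participants$id)]
  g <- as.numeric(grp == "tamoxifen")
  t <- coh$records$time
  lin <- -0.21 * g * (t >= 1) - 0.045 * g * pmax(t - 1, 0)
  # volumetric measure: log-scale median plus IQR-scaled mean effect
  vol <- coh$records$measure == "volpara_pct"
  expect_equal(coh$records$value[vol],
               exp(log(8.6) + (log(15.7) - log(5.4)) * lin[vol]),
               tolerance = 1e-12)
  # area measure: sqrt-scale median plus IQR-scaled mean effect
  st <- coh$records$measure == "stratus_pct"
  expect_equal(coh$records$value[st],
               (sqrt(37.8) + (sqrt(56.8) - sqrt(13.5)) * lin[st])^2,
               tolerance = 1e-12)
})

test_that("generated baselines reproduce the target medians and quartiles", {
  coh <- generate_cohort(generator_config(n_cases = 1000,
                                          n_controls_per_case = 0,
                                          seed = 64))
  base <- coh$records[coh$records$time == 0, ]
  v <- base$value[base$measure == "volpara_pct"]
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(q[2], 8.6, tolerance = 0.08)   # relative scale
  expect_equal(q[1], 5.4, tolerance = 0.10)
  expect_equal(q[3], 15.7, tolerance = 0.10)
  s <- base$value[base$measure == "stratus_pct"]
  qs <- stats::quantile(s, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(qs[2], 37.8, tolerance = 0.10)
  expect_equal(qs[3] - qs[1], 56.8 - 13.5, tolerance = 0.15)
})

test_that("percent measures stay within [0, 100] and clipping is counted", {
  coh <- generate_cohort(generator_config(n_cases = 400, seed = 65))
  pct <- coh$records$value[coh$records$measure != "volpara_dv"]
  expect_true(all(pct >= 0 & pct <= 100))
  expect_true(is.numeric(coh$clip_events) && coh$clip_events >= 0)
})

test_that("treatment-stop and follow-up distributions match the configuration", {
  coh <- generate_cohort(generator_config(n_cases = 1500,
                                          n_controls_per_case = 0,
                                          seed = 66))
  stop_t <- coh$participants$treatment_stop
  expect_lt(abs(mean(is.na(stop_t)) - 76 / 146), 0.05)
  expect_lt(abs(mean(!is.na(stop_t) & stop_t <= 1) - 32 / 146), 0.05)
  # women keep no post-cessation follow-up visits
  times <- split(coh$records$time, coh$records$participant_id)
  for (id in sample(coh$participants$id[!is.na(stop_t)], 50)) {
    s <- stop_t[coh$participants$id == id]
    expect_true(all(times[[id]] == 0 | times[[id]] <= s))
  }
})

test_that("matched controls respect the age and calendar-year constraints", {
  coh <- generate_cohort(generator_config(n_cases = 80, seed = 67))
  ctrl <- coh$participants[coh$participants$group == "control", ]
  cases <- coh$participants[coh$participants$group == "tamoxifen", ]
  i <- match(ctrl$match_id, cases$id)
  expect_false(anyNA(i))
  expect_true(all(abs(ctrl$age_baseline - cases$age_baseline[i]) <= 1))
  expect_true(all(ctrl$baseline_year == cases$baseline_year[i]))
  expect_true(all(is.na(ctrl$treatment_stop)))
})

test_that("generated percentage measures are strongly cross-correlated", {
  coh <- generate_cohort(generator_config(n_cases = 200, seed = 68))
  ctrl_ids <- coh$participants$id[coh$participants$group == "control"]
  rec <- coh$records[coh$records$participant_id %in% ctrl_ids, ]
  specs <- default_measures()
  rec <- dplyr::bind_rows(lapply(seq_len(nrow(specs)), function(j) {
    r <- rec[rec$measure == specs$name[j], ]
    r$value <- transform_value(r$value, specs$transform[j])
    r
  }))
  ct <- correlation_table(rec, specs$name)
  off_diag <- ct[upper.tri(ct)]
  expect_true(all(off_diag > 0.8))
})

test_that("samples nest after filtering a generated cohort", {
  coh <- generate_cohort(generator_config(n_cases = 60, seed = 69))
  recs <- filter_complete_timepoints(coh$records, default_measures()$name)
  recs <- censor_on_treatment(recs, coh$participants)
  s <- build_samples(recs, coh$participants)
  expect_true(all(s$B$participant_ids %in% s$A$participant_ids))
  expect_true(all(s$C$participant_ids %in% s$B$participant_ids))
  expect_gt(length(s$C$participant_ids), 0)
  expect_lt(length(s$C$participant_ids), length(s$A$participant_ids))
})

test_that("under the null scenario the treatment-step CI covers zero at its nominal rate", {
  scen <- scenario_library(seed = 1)$null
  covered <- 0
  n_rep <- 30
  for (s in seq_len(n_rep)) {
    cfg <- scen
    cfg$n_cases <- 100
    cfg$seed <- 700 + s
    coh <- generate_cohort(cfg)
    r <- coh$records[coh$records$measure == "volpara_pct", ]
    r <- censor_on_treatment(r, coh$participants)
    r$value <- transform_value(r$value, "log")
    r$value <- standardize(r$value,
                           fit_standardization(r$value[r$time == 0]))
    mf <- build_design(r, impute_bmi(coh$participants))
    fit <- fit_density_lmm(mf)
    se <- sqrt(diag(as.matrix(stats::vcov(fit$model))))[["group_step"]]
    est <- fit$beta[["group_step"]]
    if (est - 1.96 * se <= 0 && 0 <= est + 1.96 * se) covered <- covered + 1
  }
  expect_gte(covered, 24)  # ~95% nominal; pr(<24/30) is negligible
})

test_that("the scenario library spans the intended regimes", {
  lib <- scenario_library(seed = 5)
  expect_named(lib, c("paper_like", "noise_dominant", "signal_dominant",
                      "null"))
  expect_equal(lib$noise_dominant$var_slope, 0)
  expect_equal(lib$noise_dominant$var_resid_baseline, 0)
  expect_equal(unname(lib$noise_dominant$beta["group_step"]), 0)
  expect_lt(lib$paper_like$beta[["group_step"]], 0)
  expect_gt(lib$signal_dominant$var_slope, lib$signal_dominant$var_resid)
  expect_equal(unname(lib$null$beta[["group_step"]]), 0)
  expect_equal(lib$null$var_slope, lib$paper_like$var_slope)
})
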