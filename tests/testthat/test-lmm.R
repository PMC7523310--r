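test_that("missing BMI is imputed by the pooled observed mean", {
  p <- make_participants(3, seed = 1)
  p$bmi <- c(20, 30, NA)
  expect_equal(impute_bmi(p)$bmi, c(20, 30, 25))
  p2 <- make_participants(5, seed = 2)
  expect_identical(impute_bmi(p2), p2)
  p$bmi <- NA_real_
  expect_error(impute_bmi(p), "all BMI")
  p3 <- make_participants(100, seed = 3, bmi_missing = 0.3)
  obs_mean <- mean(p3$bmi, na.rm = TRUE)
  imp <- impute_bmi(p3)
  expect_true(all(imp$bmi[is.na(p3$bmi)] == obs_mean))
})

test_that("design rows encode the step-and-ramp time structure", {
  parts <- tibble::tibble(
    id = c("t", "c"), group = c("tamoxifen", "control"),
    age_baseline = c(40, 45), bmi = c(25, 30), baseline_year = 2011,
    treatment_stop = NA_real_
  )
  rec <- tibble::tibble(participant_id = c("c", "t", "t"), time = c(0, 1, 4),
                        value = 0)
  X <- design_matrix(build_design(rec, parts))
  expect_equal(unname(X[1, ]), c(1, 0, 9, 6, 0, 0, 0, 0))       # control, t=0
  expect_equal(unname(X[2, ]), c(1, 1, 8, 5, 1, 0, 1, 0))       # tamoxifen, t=1
  expect_equal(unname(X[3, ]), c(1, 1, 8, 5, 1, 3, 1, 3))       # tamoxifen, t=4
  # interaction columns are exact products; ramp > 0 implies step = 1
  expect_true(all(X[, "group_step"] == X[, "group"] * X[, "step"]))
  expect_true(all(X[, "group_ramp"] == X[, "group"] * X[, "ramp"]))
  expect_true(all(X[X[, "ramp"] > 0, "step"] == 1))
  expect_error(build_design(tibble::tibble(participant_id = "zz", time = 0,
                                           value = 0), parts),
               "unknown participant")
  parts$bmi[1] <- NA
  expect_error(build_design(rec, parts), "imputed")
})

test_that("noise-free responses are interpolated exactly", {
  parts <- make_participants(40, seed = 2)
  rec <- tidyr::expand_grid(participant_id = parts$id, time = 0:3)
  rec$value <- 0
  mf <- build_design(rec, parts)
  beta <- c(0.5, -0.2, 0.1, -0.05, -0.3, -0.08, -0.21, -0.045)
  mf$y <- as.numeric(design_matrix(mf) %*% beta)
  fit <- fit_density_lmm(mf)
  expect_equal(unname(fit$beta), beta, tolerance = 1e-7)
})

test_that("adding a constant to all responses shifts only the intercept", {
  mf <- make_mf(n = 120, seed = 4)
  f0 <- fit_density_lmm(mf)
  mf2 <- mf
  mf2$y <- mf$y + 2.5
  f1 <- fit_density_lmm(mf2)
  expect_equal(unname(f1$beta["intercept"] - f0$beta["intercept"]), 2.5,
               tolerance = 1e-5)
  expect_equal(f1$beta[-1], f0$beta[-1], tolerance = 1e-5)
  expect_equal(f1$var_intercept, f0$var_intercept, tolerance = 1e-5)
  expect_equal(f1$var_resid, f0$var_resid, tolerance = 1e-5)
})

test_that("a single visit per woman leaves the slope unidentifiable and errors", {
  parts <- make_participants(30, seed = 5)
  rec <- tibble::tibble(participant_id = parts$id, time = 0,
                        value = stats::rnorm(30))
  mf <- build_design(rec, parts)
  expect_error(fit_density_lmm(mf), "unidentifiable")
})

test_that("ML fit maximises the marginal likelihood (independent oracle)", {
  truth <- list(beta = c(intercept = 0.2, group = 0, age5 = 0, bmi5 = 0,
                         step = -0.1, ramp = 0, group_step = -0.21,
                         group_ramp = -0.045),
                var_int = 0.45, var_slope = 0.01, corr = -0.4,
                var_resid = 0.06)
  for (s in 1:3) {
    mf <- make_mf(n = 150, beta = truth$beta, var_int = truth$var_int,
                  var_slope = truth$var_slope, corr = truth$corr,
                  var_resid = truth$var_resid, seed = s)
    fit <- fit_density_lmm(mf)
    # the oracle log-likelihood agrees with lme4 at the fitted parameters
    ll_hat <- mdchange:::lmm_marginal_loglik(
      mf, fit$beta, fit$var_intercept, fit$var_slope, fit$cov_int_slope,
      fit$var_resid
    )
    expect_equal(ll_hat, fit$loglik, tolerance = 1e-4)
    # and the fit is at least as good as the generating parameters
    ll_truth <- mdchange:::lmm_marginal_loglik(
      mf, truth$beta, truth$var_int, truth$var_slope,
      truth$corr * sqrt(truth$var_int * truth$var_slope), truth$var_resid
    )
    expect_gte(fit$loglik, ll_truth - 1e-6)
  }
})

fake_fit <- function(vi, vs, cov, vr, converged = TRUE) {
  structure(list(var_intercept = vi, var_slope = vs, cov_int_slope = cov,
                 var_resid = vr, converged = converged),
            class = "lmm_fit")
}

test_that("the ICC is the between-woman share of variance", {
  expect_equal(icc_from_fit(fake_fit(9, 0, 0, 1)), 0.9)
  expect_equal(icc_from_fit(fake_fit(0, 0, 0, 1)), 0)
  # with a random slope the between-woman variance grows with time
  f <- fake_fit(4, 1, 0, 1)
  expect_equal(icc_from_fit(f, time = 0), 4 / 5)
  expect_equal(icc_from_fit(f, time = 2), 8 / 9)
  # the measurement-error share is the complement of the ICC
  expect_equal(icc_from_fit(f) + measurement_error_share(f), 1)
  expect_error(icc_from_fit(fake_fit(9, 0, 0, 1, converged = FALSE)),
               "non-converged")
})

test_that("the model recovers a generating ICC of 0.9 at n = 300", {
  mf <- make_mf(n = 300, seed = 8)
  fit <- fit_density_lmm(mf)
  expect_gt(icc_from_fit(fit), 0.85)
  expect_lt(icc_from_fit(fit), 0.95)
})

test_that("profile intervals nest, contain the estimate, and approach Wald at large n", {
  mf <- make_mf(n = 800, visits = 0:3, seed = 9)
  fit <- fit_density_lmm(mf)
  ci95 <- profile_ci(fit, "group_step", 0.95)
  ci99 <- profile_ci(fit, "group_step", 0.99)
  expect_equal(attr(ci95, "method"), "profile")
  expect_lt(ci99["low"], ci95["low"])
  expect_gt(ci99["high"], ci95["high"])
  est <- fit$beta["group_step"]
  expect_true(ci95["low"] < est && est < ci95["high"])
  wald <- suppressWarnings(
    stats::confint(fit$model, parm = "group_step", method = "Wald")
  )
  w_prof <- ci95["high"] - ci95["low"]
  w_wald <- wald[1, 2] - wald[1, 1]
  expect_lt(abs(w_prof - w_wald) / w_wald, 0.05)
})

test_that("the cluster bootstrap for the ICC is seed-reproducible and consistent", {
  mf75 <- make_mf(n = 75, seed = 10)
  b1 <- bootstrap_icc(mf75, n_resamples = 60, seed = 42)
  b2 <- bootstrap_icc(mf75, n_resamples = 60, seed = 42)
  expect_identical(b1[c("ci_low", "ci_high")], b2[c("ci_low", "ci_high")])
  expect_lt(b1$ci_low, b1$icc + 0.02)
  expect_gt(b1$ci_high, b1$icc - 0.02)
  # CI width shrinks roughly like 1/sqrt(n) between n = 75 and n = 300
  mf300 <- make_mf(n = 300, seed = 10)
  b3 <- bootstrap_icc(mf300, n_resamples = 120, seed = 43)
  b4 <- bootstrap_icc(mf75, n_resamples = 120, seed = 43)
  ratio <- (b4$ci_high - b4$ci_low) / (b3$ci_high - b3$ci_low)
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.2)
})

test_that("the treated-group refit has five fixed effects and recovers the intercept-slope correlation", {
  mf <- make_mf(n = 600, tam_frac = 0.5, corr = -0.45, seed = 12)
  tam <- fit_tamoxifen_only(mf)
  expect_equal(names(tam$beta), c("intercept", "age5", "bmi5", "step", "ramp"))
  expect_gt(tam$corr_int_slope, -0.6)
  expect_lt(tam$corr_int_slope, -0.3)
  mf0 <- make_mf(n = 600, tam_frac = 0.5, corr = 0, seed = 13)
  tam0 <- fit_tamoxifen_only(mf0)
  expect_lt(abs(tam0$corr_int_slope), 0.15)
})
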