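#' Impute missing body mass index by the pooled mean
#'
#' Missing BMI is replaced by the mean of the observed BMI values, pooled
#' over both treatment groups; observed values are unchanged.
#'
#' @param participants Participant tibble.
#' @return The tibble with complete `bmi`.
#' @export
impute_bmi <- function(participants) {
  obs <- participants$bmi[!is.na(participants$bmi)]
  if (length(obs) == 0) stop("all BMI values are missing", call. = FALSE)
  participants$bmi[is.na(participants$bmi)] <- mean(obs)
  participants
}

# canonical fixed-effect names, in design order
lmm_beta_names <- c("intercept", "group", "age5", "bmi5",
                    "step", "ramp", "group_step", "group_ramp")

#' Build the longitudinal model frame
#'
#' One row per (woman, visit) with the response (standardised density) and
#' the eight fixed-effect columns of the step-and-ramp model: intercept,
#' treatment group, age (per 5 years), BMI (per 5 kg/m2), a year-1 step
#' `1{t >= 1}`, a post-year-1 ramp `max(t - 1, 0)`, and the group
#' interactions with step and ramp. The step and its group interaction carry
#' the acute year-1 change; the ramp terms carry the yearly rate of change
#' from year 2 onwards.
#'
#' @param records_std Tibble with `participant_id`, `time`, `value`
#'   (standardised scale, a single measure).
#' @param participants Participant tibble with imputed BMI.
#' @return A tibble with columns `participant_id`, `time`, `y`, `group`,
#'   `age5`, `bmi5`, `step`, `ramp`, `group_step`, `group_ramp`.
#' @export
build_design <- function(records_std, participants) {
  unknown <- setdiff(unique(records_std$participant_id), participants$id)
  if (length(unknown) > 0) {
    stop("unknown participant ids: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  idx <- match(records_std$participant_id, participants$id)
  if (anyNA(participants$bmi[idx])) {
    stop("BMI must be imputed before building the design (see impute_bmi)",
         call. = FALSE)
  }
  t <- records_std$time
  g <- as.numeric(participants$group[idx] == "tamoxifen")
  step <- as.numeric(t >= 1)
  ramp <- pmax(t - 1, 0)
  tibble::tibble(
    participant_id = records_std$participant_id,
    time = t,
    y = records_std$value,
    group = g,
    age5 = participants$age_baseline[idx] / 5,
    bmi5 = participants$bmi[idx] / 5,
    step = step,
    ramp = ramp,
    group_step = g * step,
    group_ramp = g * ramp
  )
}

#' Fixed-effect design matrix of a model frame
#'
#' @param mf Model frame from [build_design()].
#' @return Numeric matrix with the eight columns in canonical order.
#' @export
design_matrix <- function(mf) {
  X <- cbind(1, mf$group, mf$age5, mf$bmi5, mf$step, mf$ramp,
             mf$group_step, mf$group_ramp)
  colnames(X) <- lmm_beta_names
  X
}

lmm_fit_from_lmer <- function(model, beta_names, n_women) {
  vc <- lme4::VarCorr(model)
  G <- vc$participant_id
  beta <- as.numeric(lme4::fixef(model))
  names(beta) <- beta_names
  msgs <- model@optinfo$conv$lme4$messages
  singular <- lme4::isSingular(model, tol = 1e-5)
  non_singular_msgs <- msgs[!grepl("singular|boundary", msgs, ignore.case = TRUE)]
  converged <- model@optinfo$conv$opt == 0 && length(non_singular_msgs) == 0
  structure(
    list(
      beta = beta,
      var_intercept = unname(G[1, 1]),
      var_slope = unname(G[2, 2]),
      cov_int_slope = unname(G[1, 2]),
      corr_int_slope = unname(attr(G, "correlation")[1, 2]),
      var_resid = stats::sigma(model)^2,
      loglik = as.numeric(stats::logLik(model)),
      converged = converged,
      singular = singular,
      messages = msgs,
      n_women = n_women,
      n_obs = stats::nobs(model),
      model = model
    ),
    class = "lmm_fit"
  )
}

#' Fit the step-and-ramp linear mixed model by maximum likelihood
#'
#' A normal linear mixed model with the eight fixed effects of
#' [build_design()] and, per woman, a bivariate-normal random intercept and
#' random slope in time since baseline. Fitted by maximum likelihood (not
#' REML) via `lme4::lmer`.
#'
#' @param mf Model frame from [build_design()].
#' @param control `lme4::lmerControl` options.
#' @return An object of class `lmm_fit`: `beta` (8 named estimates on the
#'   standardised scale), variance components (`var_intercept`, `var_slope`,
#'   `cov_int_slope`, `var_resid`), `corr_int_slope`, `loglik`, `converged`,
#'   `singular`, and the underlying `lmerMod` as `model`.
#' @export
fit_density_lmm <- function(mf, control = NULL) {
  check_slope_identifiable(mf)
  model <- fit_lmer_robust(
    y ~ group + age5 + bmi5 + step + ramp + group_step + group_ramp +
      (1 + time | participant_id),
    mf, control
  )
  lmm_fit_from_lmer(model, lmm_beta_names, length(unique(mf$participant_id)))
}

# Fit by ML; if the first optimizer raises a (frequently spurious) gradient
# convergence warning, retry with bobyqa before flagging non-convergence.
fit_lmer_robust <- function(formula, data, control = NULL) {
  quiet_lmer <- function(ctrl) {
    withCallingHandlers(
      suppressWarnings(lme4::lmer(formula, data = data, REML = FALSE,
                                  control = ctrl)),
      message = function(m) invokeRestart("muffleMessage")
    )
  }
  if (!is.null(control)) return(quiet_lmer(control))
  model <- quiet_lmer(lme4::lmerControl())
  msgs <- model@optinfo$conv$lme4$messages
  if (length(msgs[!grepl("singular|boundary", msgs, ignore.case = TRUE)]) > 0) {
    model2 <- quiet_lmer(lme4::lmerControl(
      optimizer = "bobyqa", optCtrl = list(maxfun = 1e5)
    ))
    msgs2 <- model2@optinfo$conv$lme4$messages
    if (length(msgs2[!grepl("singular|boundary", msgs2,
                            ignore.case = TRUE)]) == 0 ||
        as.numeric(stats::logLik(model2)) >= as.numeric(stats::logLik(model))) {
      model <- model2
    }
  }
  model
}

#' Sensitivity refit in the tamoxifen group alone
#'
#' Refits the model on treated women only, dropping the group main effect and
#' its interactions (5 fixed effects: intercept, age, BMI, step, ramp) with
#' the same random intercept + slope structure. The reported
#' intercept-slope correlation indicates whether women with higher baseline
#' density experience larger declines.
#'
#' @param mf Model frame (both groups are accepted; treated rows are used).
#' @param control `lme4::lmerControl` options.
#' @return An `lmm_fit` with 5 fixed effects.
#' @export
fit_tamoxifen_only <- function(mf, control = NULL) {
  mft <- mf[mf$group == 1, , drop = FALSE]
  if (nrow(mft) == 0) stop("no tamoxifen-group records", call. = FALSE)
  check_slope_identifiable(mft)
  model <- fit_lmer_robust(
    y ~ age5 + bmi5 + step + ramp + (1 + time | participant_id), mft, control
  )
  lmm_fit_from_lmer(model, c("intercept", "age5", "bmi5", "step", "ramp"),
                    length(unique(mft$participant_id)))
}

check_slope_identifiable <- function(mf) {
  nv <- table(mf$participant_id)
  if (max(nv) < 2) {
    stop("random slope unidentifiable: no woman has more than one visit",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (ML),", x$n_women, "women,", x$n_obs, "observations\n")
  cat("log-likelihood:", format(x$loglik, digits = 6),
      if (!x$converged) "[NOT CONVERGED]" else "",
      if (x$singular) "[singular fit]" else "", "\n")
  print(round(x$beta, 4))
  cat(sprintf("var(intercept) %.4f  var(slope) %.4f  corr %.3f  var(resid) %.4f\n",
              x$var_intercept, x$var_slope, x$corr_int_slope, x$var_resid))
  invisible(x)
}

#' Intraclass correlation from a fitted model
#'
#' Reliability is summarised as the between-woman share of total variance:
#' `var_between(t) / (var_between(t) + var_resid)`, where with a random slope
#' the between-woman variance is time-dependent,
#' `var_intercept + 2t cov + t^2 var_slope`; the default evaluates at
#' baseline (t = 0). One minus the ICC is the measurement-error share of
#' variance. The complementary ratio (residual over total) is available as
#' [measurement_error_share()].
#'
#' @param fit An `lmm_fit` (must have converged).
#' @param time Time (years) at which between-woman variance is evaluated.
#' @return ICC in `[0, 1]`.
#' @export
icc_from_fit <- function(fit, time = 0) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$converged) {
    stop("ICC requested from a non-converged fit", call. = FALSE)
  }
  between <- fit$var_intercept + 2 * time * fit$cov_int_slope +
    time^2 * fit$var_slope
  between / (between + fit$var_resid)
}

#' @rdname icc_from_fit
#' @export
measurement_error_share <- function(fit, time = 0) {
  1 - icc_from_fit(fit, time)
}

#' Profile-likelihood confidence interval for a fixed effect
#'
#' Bounds are where twice the drop in profile log-likelihood equals the
#' chi-square(1) quantile for the requested level (3.841 at 95%). If
#' profiling fails to bracket, a Wald interval is returned and flagged via
#' the `method` attribute.
#'
#' @param fit An `lmm_fit`.
#' @param parm Canonical fixed-effect name (e.g. `"group_step"`) or index.
#' @param level Confidence level.
#' @return Numeric `c(low, high)` with attribute `method` (`"profile"` or
#'   `"wald"`).
#' @export
profile_ci <- function(fit, parm, level = 0.95) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  nm <- names(fit$beta)
  if (is.numeric(parm)) parm <- nm[parm]
  if (!parm %in% nm) stop("unknown fixed effect '", parm, "'", call. = FALSE)
  lmer_name <- if (parm == "intercept") "(Intercept)" else parm
  ci <- tryCatch(
    suppressWarnings(suppressMessages(
      stats::confint(fit$model, parm = lmer_name, method = "profile",
                     level = level, quiet = TRUE)
    )),
    error = function(e) NULL
  )
  method <- "profile"
  if (is.null(ci) || anyNA(ci)) {
    ci <- suppressWarnings(
      stats::confint(fit$model, parm = lmer_name, method = "Wald",
                     level = level)
    )
    method <- "wald"
  }
  out <- as.numeric(ci[1, ])
  names(out) <- c("low", "high")
  attr(out, "method") <- method
  out
}

#' Cluster-bootstrap confidence interval for the ICC
#'
#' Non-parametric bootstrap resampling women (clusters) with replacement,
#' preserving each woman's whole trajectory; the model is refitted on each
#' resample and the percentile interval of the resampled ICCs is returned.
#'
#' @param mf Model frame used for the original fit.
#' @param n_resamples Number of bootstrap resamples (default 3000).
#' @param seed Integer seed (required; results are seed-reproducible).
#' @param level Confidence level.
#' @param time Time at which the ICC is evaluated.
#' @param tamoxifen_only Fit the reduced treated-group model instead.
#' @return An `icc_result` list: `icc` (point estimate from the original
#'   fit), `ci_low`, `ci_high`, `n_resamples`, `n_failures`.
#' @export
bootstrap_icc <- function(mf, n_resamples = 3000, seed, level = 0.95,
                          time = 0, tamoxifen_only = FALSE) {
  stopifnot(!missing(seed))
  fitter <- if (tamoxifen_only) fit_tamoxifen_only else fit_density_lmm
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit0 <- fitter(mf)
  if (!fit0$converged) stop("original fit did not converge", call. = FALSE)
  icc0 <- icc_from_fit(fit0, time)
  ids <- unique(mf$participant_id)
  by_id <- split(seq_len(nrow(mf)), mf$participant_id)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  draws <- rep(NA_real_, n_resamples)
  for (b in seq_len(n_resamples)) {
    take <- sample(ids, length(ids), replace = TRUE)
    rows <- unlist(by_id[take], use.names = FALSE)
    nb <- mf[rows, , drop = FALSE]
    nb$participant_id <- rep(paste0(take, "#", seq_along(take)),
                             lengths(by_id[take]))
    fb <- tryCatch(suppressWarnings(fitter(nb, control = ctrl)),
                   error = function(e) NULL)
    if (!is.null(fb)) {
      between <- fb$var_intercept + 2 * time * fb$cov_int_slope +
        time^2 * fb$var_slope
      draws[b] <- between / (between + fb$var_resid)
    }
  }
  n_fail <- sum(is.na(draws))
  if (n_fail > 0.05 * n_resamples) {
    stop("bootstrap refit failures exceed 5% (", n_fail, " of ", n_resamples,
         ")", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  qs <- stats::quantile(draws[!is.na(draws)], c(alpha, 1 - alpha),
                        type = 7, names = FALSE)
  structure(
    list(icc = icc0, ci_low = qs[1], ci_high = qs[2],
         n_resamples = n_resamples, n_failures = n_fail, level = level,
         time = time),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC %.3f (%d%% CI %.3f-%.3f; %d resamples, %d failures)\n",
              x$icc, round(100 * x$level), x$ci_low, x$ci_high,
              x$n_resamples, x$n_failures))
  invisible(x)
}

# Marginal Gaussian log-likelihood of the random intercept+slope model at
# given parameters; used as an independent oracle in tests.
lmm_marginal_loglik <- function(mf, beta, var_intercept, var_slope,
                                cov_int_slope, var_resid) {
  X <- design_matrix(mf)[, seq_along(beta), drop = FALSE]
  r <- mf$y - as.numeric(X %*% beta)
  G <- matrix(c(var_intercept, cov_int_slope, cov_int_slope, var_slope), 2, 2)
  ll <- 0
  for (rows in split(seq_len(nrow(mf)), mf$participant_id)) {
    Z <- cbind(1, mf$time[rows])
    V <- Z %*% G %*% t(Z) + diag(var_resid, length(rows))
    ch <- chol(V)
    u <- backsolve(ch, r[rows], transpose = TRUE)
    ll <- ll - 0.5 * (length(rows) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        sum(u^2))
  }
  ll
}
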