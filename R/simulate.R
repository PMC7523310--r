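#' Default baseline distribution targets for the automated measures
#'
#' Native-scale baseline median and quartiles that the generated cohorts are
#' moment-matched to, for the four automated percentage density measures
#' (typical values in premenopausal high-risk screening populations).
#'
#' @return Tibble with `name`, `quantity`, `transform`, `median`, `q1`, `q3`.
#' @export
default_measure_targets <- function() {
  tibble::tibble(
    name = c("stratus_pct", "densitas_pct", "nnvas_pct", "volpara_pct"),
    quantity = c("area_percent", "area_percent", "area_percent",
                 "volumetric_percent"),
    transform = c("sqrt", "sqrt", "sqrt", "log"),
    median = c(37.8, 41.0, 41.1, 8.6),
    q1 = c(13.5, 32.0, 29.7, 5.4),
    q3 = c(56.8, 49.5, 54.5, 15.7)
  )
}

NORMAL_IQR <- stats::qnorm(0.75) - stats::qnorm(0.25)  # 1.34898

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate a tamoxifen-prevention cohort: two age-matched groups
#' (up to two controls per case, age within 1 year, same baseline year),
#' four automated percentage density measures with realistic baseline
#' distributions and high cross-measure correlation, a treated-group step
#' decline at year 1 plus a yearly ramp thereafter, woman-level random
#' intercept/slope heterogeneity with negative intercept-slope correlation,
#' residual noise giving baseline ICC 0.9, staggered follow-up (median 3
#' years), missing BMI, and treatment-cessation attrition.
#'
#' All effects and variance components are expressed on the standardised
#' scale whose unit is the observed baseline inter-quartile range of the
#' transformed measure; with the default variance components the observed
#' baseline of each generated measure has (approximately) the target median
#' and IQR, and the baseline ICC is `var_intercept / (var_intercept +
#' var_resid)`.
#'
#' @param n_cases Number of tamoxifen-group women.
#' @param n_controls_per_case Maximum matched controls per case.
#' @param control_availability Probability that each control beyond the first
#'   is available (0.37 yields about 1.37 controls per case).
#' @param age_median,age_sd,age_range Case baseline-age distribution (normal,
#'   truncated to `age_range`); control age is the case age plus Uniform(-1,1).
#' @param baseline_years Calendar years of staggered entry.
#' @param bmi_meanlog,bmi_sdlog Log-normal BMI distribution (kg/m2).
#' @param bmi_missing Fraction of women with missing BMI.
#' @param measures Tibble of measure targets (see [default_measure_targets()]).
#' @param latent_correlation Cross-measure correlation of baseline
#'   transformed density (one-factor structure).
#' @param beta Named true fixed effects, standardised scale, in canonical
#'   order (`intercept`, `group`, `age5`, `bmi5`, `step`, `ramp`,
#'   `group_step`, `group_ramp`).
#' @param var_intercept,var_slope,corr_int_slope,var_resid Variance
#'   components on the standardised scale; the defaults give baseline ICC 0.9
#'   and intercept-slope correlation -0.45.
#' @param var_resid_baseline Residual variance at the baseline visit
#'   (defaults to `var_resid`; set 0 to pin the baseline).
#' @param resid_correlation Cross-measure correlation of within-visit
#'   residuals.
#' @param adherence Named proportions of treated women by stop time:
#'   `never`, `y1` ... `y5` (uniform within the year interval), `complete`.
#' @param followup_years Administrative follow-up (years) drawn uniformly
#'   from this set per woman; `1:5` gives median 3 years.
#' @param max_followup Last scheduled annual visit.
#' @param missing_density_rate Per-measure missingness at follow-up visits
#'   (baseline readings are always complete).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cases = 126,
                             n_controls_per_case = 2,
                             control_availability = 0.37,
                             age_median = 42, age_sd = 5,
                             age_range = c(30, 55),
                             baseline_years = 2010:2013,
                             bmi_meanlog = log(25.5), bmi_sdlog = 0.23,
                             bmi_missing = 0.10,
                             measures = default_measure_targets(),
                             latent_correlation = 0.9,
                             beta = c(intercept = 0, group = 0, age5 = 0,
                                      bmi5 = 0, step = 0, ramp = 0,
                                      group_step = -0.21, group_ramp = -0.045),
                             var_intercept = 0.9 / NORMAL_IQR^2,
                             var_slope = 0.0064,
                             corr_int_slope = -0.45,
                             var_resid = 0.1 / NORMAL_IQR^2,
                             var_resid_baseline = var_resid,
                             resid_correlation = 0.3,
                             adherence = c(never = 2, y1 = 30, y2 = 11,
                                           y3 = 17, y4 = 7, y5 = 3,
                                           complete = 76) / 146,
                             followup_years = 1:5,
                             max_followup = 5,
                             missing_density_rate = 0.05,
                             seed = 1) {
  beta_full <- c(intercept = 0, group = 0, age5 = 0, bmi5 = 0, step = 0,
                 ramp = 0, group_step = 0, group_ramp = 0)
  beta_full[names(beta)] <- beta
  stopifnot(
    n_cases >= 1, n_controls_per_case >= 0,
    control_availability >= 0, control_availability <= 1,
    var_intercept >= 0, var_slope >= 0, var_resid >= 0,
    var_resid_baseline >= 0,
    latent_correlation >= 0, latent_correlation <= 1,
    abs(corr_int_slope) <= 1,
    resid_correlation >= 0, resid_correlation < 1,
    missing_density_rate >= 0, missing_density_rate < 1,
    abs(sum(adherence) - 1) < 1e-8
  )
  if (var_slope > 0 && latent_correlation > 0 &&
      abs(corr_int_slope) > sqrt(latent_correlation)) {
    stop("|corr_int_slope| cannot exceed sqrt(latent_correlation) under the ",
         "one-factor structure", call. = FALSE)
  }
  structure(
    list(n_cases = n_cases, n_controls_per_case = n_controls_per_case,
         control_availability = control_availability,
         age_median = age_median, age_sd = age_sd, age_range = age_range,
         baseline_years = baseline_years,
         bmi_meanlog = bmi_meanlog, bmi_sdlog = bmi_sdlog,
         bmi_missing = bmi_missing,
         measures = measures, latent_correlation = latent_correlation,
         beta = beta_full,
         var_intercept = var_intercept, var_slope = var_slope,
         corr_int_slope = corr_int_slope,
         cov_int_slope = corr_int_slope * sqrt(var_intercept * var_slope),
         var_resid = var_resid, var_resid_baseline = var_resid_baseline,
         resid_correlation = resid_correlation,
         adherence = adherence, followup_years = followup_years,
         max_followup = max_followup,
         missing_density_rate = missing_density_rate, seed = seed),
    class = "generator_config"
  )
}

# Fit a scaled-beta baseline marginal (native percent scale) so that, on the
# sqrt scale, the between-woman distribution has the target median and the
# target IQR shrunk to the between-woman share.
fit_beta_marginal <- function(median, q1, q3, iqr_t_target) {
  med_t <- sqrt(median)
  loss <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    q <- sqrt(100 * stats::qbeta(c(0.25, 0.5, 0.75), a, b))
    (q[2] - med_t)^2 + ((q[3] - q[1]) - iqr_t_target)^2
  }
  m <- median / 100
  init <- log(c(max(m * 6, 0.2), max((1 - m) * 6, 0.2)))
  opt <- stats::optim(init, loss, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(shape1 = exp(opt$par[1]), shape2 = exp(opt$par[2]),
       loss = opt$value)
}

#' Generate a synthetic longitudinal density cohort
#'
#' Draws a cohort under the configured data-generating process and returns it
#' in the ingestion format (see [read_cohort()]): a matched two-group study
#' with annual visits, correlated multi-measure baseline densities mapped to
#' the native measurement scale, woman-level random intercepts and slopes, a
#' treated-group step-and-ramp mean trajectory, treatment-cessation
#' truncation, staggered administrative follow-up, and per-measure visit
#' missingness. Percent values are clipped into `[0, 100]` where the latent
#' trajectory leaves the representable range; clip events are counted in the
#' `clip_events` element.
#'
#' @param config A [generator_config()].
#' @return List with `participants`, `records` (raw scale), `clip_events`,
#'   `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  ## participants -------------------------------------------------------
  nc <- config$n_cases
  case_age <- pmin(pmax(stats::rnorm(nc, config$age_median, config$age_sd),
                        config$age_range[1]), config$age_range[2])
  case_year <- sample(config$baseline_years, nc, replace = TRUE)
  case_ids <- sprintf("T%04d", seq_len(nc))

  ctrl_rows <- list()
  if (config$n_controls_per_case >= 1) {
    for (k in seq_len(nc)) {
      extra <- if (config$n_controls_per_case > 1) {
        stats::rbinom(config$n_controls_per_case - 1, 1,
                      config$control_availability)
      } else integer(0)
      n_k <- 1 + sum(extra)
      ctrl_rows[[k]] <- tibble::tibble(
        id = sprintf("C%04d_%d", k, seq_len(n_k)),
        age_baseline = pmin(pmax(case_age[k] + stats::runif(n_k, -1, 1),
                                 config$age_range[1] - 1),
                            config$age_range[2] + 1),
        baseline_year = case_year[k],
        match_id = case_ids[k]
      )
    }
  }
  controls <- dplyr::bind_rows(ctrl_rows)
  participants <- dplyr::bind_rows(
    tibble::tibble(id = case_ids, group = "tamoxifen",
                   age_baseline = case_age, baseline_year = case_year,
                   match_id = NA_character_),
    dplyr::mutate(controls, group = "control")
  )
  n <- nrow(participants)
  bmi_true <- stats::rlnorm(n, config$bmi_meanlog, config$bmi_sdlog)
  participants$bmi <- ifelse(stats::runif(n) < config$bmi_missing,
                             NA_real_, bmi_true)

  ## adherence and follow-up -------------------------------------------
  is_tam <- participants$group == "tamoxifen"
  stop_t <- rep(NA_real_, n)
  cat_draw <- sample(names(config$adherence), sum(is_tam), replace = TRUE,
                     prob = config$adherence)
  stop_tam <- rep(NA_real_, sum(is_tam))
  stop_tam[cat_draw == "never"] <- 0
  for (k in 1:5) {
    sel <- cat_draw == paste0("y", k)
    stop_tam[sel] <- stats::runif(sum(sel), k - 1, k)
  }
  stop_t[is_tam] <- stop_tam
  participants$treatment_stop <- stop_t

  followup <- if (length(config$followup_years) == 1) {
    rep(config$followup_years, n)
  } else {
    sample(config$followup_years, n, replace = TRUE)
  }

  ## visit grid ---------------------------------------------------------
  visit_list <- lapply(seq_len(n), function(i) {
    t <- 0:min(config$max_followup, followup[i])
    if (is_tam[i] && !is.na(stop_t[i])) t <- t[t == 0 | t <= stop_t[i]]
    t
  })
  grid <- tibble::tibble(
    row = rep(seq_len(n), lengths(visit_list)),
    time = unlist(visit_list)
  )
  m_obs <- nrow(grid)

  ## woman-level latents -------------------------------------------------
  lam <- config$latent_correlation
  v0 <- stats::rnorm(n)
  u1 <- if (config$var_slope > 0) {
    rho1 <- if (lam > 0) config$corr_int_slope / sqrt(lam) else 0
    sqrt(config$var_slope) *
      (rho1 * v0 + sqrt(1 - rho1^2) * stats::rnorm(n))
  } else {
    rep(0, n)
  }

  ## fixed-effect mean per row (time part + covariates) ------------------
  g <- as.numeric(is_tam)[grid$row]
  step <- as.numeric(grid$time >= 1)
  ramp <- pmax(grid$time - 1, 0)
  b <- config$beta
  xbeta <- b["intercept"] + b["group"] * g +
    b["age5"] * participants$age_baseline[grid$row] / 5 +
    b["bmi5"] * bmi_true[grid$row] / 5 +
    b["step"] * step + b["ramp"] * ramp +
    b["group_step"] * g * step + b["group_ramp"] * g * ramp

  ## residual common factor (cross-measure correlation) ------------------
  r <- config$resid_correlation
  e_common <- stats::rnorm(m_obs)
  resid_sd_row <- ifelse(grid$time == 0,
                         sqrt(config$var_resid_baseline),
                         sqrt(config$var_resid))

  ## per-measure values ---------------------------------------------------
  clip_events <- 0L
  recs <- vector("list", nrow(config$measures))
  for (j in seq_len(nrow(config$measures))) {
    ms <- config$measures[j, ]
    z <- sqrt(lam) * v0 + sqrt(1 - lam) * stats::rnorm(n)
    if (ms$transform == "log") {
      u_m <- log(ms$q3) - log(ms$q1)
      B <- log(ms$median) + sqrt(config$var_intercept) * u_m * z
    } else {
      u_m <- sqrt(ms$q3) - sqrt(ms$q1)
      if (config$var_intercept == 0) {
        B <- rep(sqrt(ms$median), n)
      } else {
        bm <- fit_beta_marginal(ms$median, ms$q1, ms$q3,
                                NORMAL_IQR * sqrt(config$var_intercept) * u_m)
        B <- sqrt(100 * stats::qbeta(stats::pnorm(z), bm$shape1, bm$shape2))
      }
    }
    e <- resid_sd_row * (sqrt(r) * e_common +
                           sqrt(1 - r) * stats::rnorm(m_obs))
    tv <- B[grid$row] + u_m * (xbeta + u1[grid$row] * grid$time + e)
    if (ms$transform == "log") {
      value <- exp(tv)
      if (ms$quantity == "volumetric_percent") {
        over <- value > 100
        clip_events <- clip_events + sum(over)
        value[over] <- 100
      }
    } else {
      below <- tv < 0
      over <- tv > 10
      clip_events <- clip_events + sum(below) + sum(over)
      tv[below] <- 0
      tv[over] <- 10
      value <- tv^2
    }
    recs[[j]] <- tibble::tibble(
      participant_id = participants$id[grid$row],
      time = grid$time, measure = ms$name, value = value
    )
  }
  records <- dplyr::bind_rows(recs)

  ## follow-up missingness ------------------------------------------------
  if (config$missing_density_rate > 0) {
    drop <- records$time > 0 &
      stats::runif(nrow(records)) < config$missing_density_rate
    records <- records[!drop, , drop = FALSE]
  }

  participants <- participants[, c("id", "group", "age_baseline", "bmi",
                                   "baseline_year", "treatment_stop",
                                   "match_id")]
  validate_participants(participants)
  list(participants = participants, records = records,
       clip_events = clip_events, config = config)
}

#' Named library of generator scenarios
#'
#' * `paper_like`: the default configuration (treated-group step -0.21 and
#'   ramp -0.045 IQR units, ICC 0.9, intercept-slope correlation -0.45,
#'   attrition and missingness on).
#' * `noise_dominant`: no between-woman slope variance, no treatment effects,
#'   baseline pinned (zero baseline residual), full follow-up and no
#'   missingness — the idealised regime in which the relative MSE of the
#'   stability test converges to its closed-form limit of 2.
#' * `signal_dominant`: slope variance much larger than residual noise, so
#'   individual 1-year change genuinely predicts 2-year change (relative
#'   MSE below 1).
#' * `null`: no treatment effects (type-I-error checks).
#'
#' @param seed Seed stored in every scenario config.
#' @return Named list of `generator_config` objects.
#' @export
scenario_library <- function(seed = 1) {
  zero_beta <- c(group_step = 0, group_ramp = 0)
  list(
    paper_like = generator_config(seed = seed),
    noise_dominant = generator_config(
      beta = zero_beta, var_slope = 0, corr_int_slope = 0,
      var_resid_baseline = 0,
      adherence = c(never = 0, y1 = 0, y2 = 0, y3 = 0, y4 = 0, y5 = 0,
                    complete = 1),
      followup_years = 5, missing_density_rate = 0, seed = seed
    ),
    signal_dominant = generator_config(var_slope = 0.3, seed = seed),
    null = generator_config(beta = zero_beta, seed = seed)
  )
}
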