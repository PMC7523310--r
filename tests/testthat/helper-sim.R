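# Simulation helpers shared across test files. These generate data directly
# from the statistical model under test (independently of generate_cohort),
# so they can serve as oracle-side data for the estimation code.

# Participants table for hand-built cohorts.
make_participants <- function(n, tam_frac = 0.5, seed = 1,
                              bmi_missing = 0) {
  set.seed(seed)
  n_tam <- round(n * tam_frac)
  tibble::tibble(
    id = sprintf("P%04d", seq_len(n)),
    group = rep(c("tamoxifen", "control"), c(n_tam, n - n_tam)),
    age_baseline = stats::runif(n, 35, 50),
    bmi = ifelse(stats::runif(n) < bmi_missing, NA_real_,
                 stats::runif(n, 20, 32)),
    baseline_year = 2011,
    treatment_stop = NA_real_
  )
}

# Model frame drawn exactly from the random intercept+slope model.
make_mf <- function(n = 300, visits = 0:3, tam_frac = 0.5,
                    beta = c(intercept = 0, group = 0, age5 = 0, bmi5 = 0,
                             step = 0, ramp = 0, group_step = -0.21,
                             group_ramp = -0.045),
                    var_int = 0.9 / 1.34898^2, var_slope = 0.0064,
                    corr = -0.45, var_resid = 0.1 / 1.34898^2,
                    seed = 1) {
  parts <- make_participants(n, tam_frac, seed)
  set.seed(seed + 1e6)
  cov_is <- corr * sqrt(var_int * var_slope)
  S <- matrix(c(var_int, cov_is, cov_is, var_slope), 2)
  re <- if (all(S == 0)) matrix(0, n, 2) else
    matrix(stats::rnorm(2 * n), n) %*% chol(S + diag(1e-12, 2))
  rec <- tidyr::expand_grid(participant_id = parts$id, time = visits)
  rec$value <- 0
  mf <- build_design(rec, parts)
  X <- design_matrix(mf)
  i <- match(mf$participant_id, parts$id)
  mf$y <- as.numeric(X %*% beta) + re[i, 1] + re[i, 2] * mf$time +
    stats::rnorm(nrow(mf), 0, sqrt(var_resid))
  mf
}

# Change pairs delta1 = d + s + e1, delta2 = d + s + e2 with slope signal
# variance tau2 and independent noise variance sigma2 at each horizon.
make_pairs <- function(n, tau2, sigma2, d = 0, seed = 1) {
  set.seed(seed)
  s <- stats::rnorm(n, 0, sqrt(tau2))
  tibble::tibble(
    participant_id = sprintf("W%05d", seq_len(n)),
    delta1 = d + s + stats::rnorm(n, 0, sqrt(sigma2)),
    delta2 = d + s + stats::rnorm(n, 0, sqrt(sigma2))
  )
}

# Small long-format records table from a named list id -> times, with one or
# more measures all present at every listed visit.
make_records <- function(visits_by_id, measures = "m1", value = 1) {
  dplyr::bind_rows(lapply(names(visits_by_id), function(id) {
    tidyr::expand_grid(participant_id = id, time = visits_by_id[[id]],
                       measure = measures)
  })) |>
    dplyr::mutate(value = value)
}
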