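test_that("aggregate_views averages available images and rejects empty visits", {
  expect_equal(aggregate_views(c(10, 20, 30, 40)), 25)
  expect_equal(aggregate_views(7), 7)
  expect_equal(aggregate_views(c(0, 0, 0, 0)), 0)
  expect_equal(aggregate_views(c(10, NA, 20, NA)), 15)
  expect_error(aggregate_views(numeric(0)), "no usable images")
  expect_error(aggregate_views(c(NA_real_, NA_real_)), "no usable images")
})

test_that("incomplete visits are dropped wholesale by the completeness filter", {
  rec <- tibble::tibble(
    participant_id = c(rep("a", 4), rep("a", 3), "b"),
    time = c(rep(0, 4), rep(1, 3), 0),
    measure = c(paste0("m", 1:4), paste0("m", 1:3), "m1"),
    value = 1
  )
  out <- filter_complete_timepoints(rec, paste0("m", 1:4))
  # a's baseline has 4 of 4 -> kept; a's year 1 has 3 of 4 -> all 3 removed;
  # b has only m1 -> removed
  expect_equal(nrow(out), 4)
  expect_true(all(out$participant_id == "a" & out$time == 0))
  empty <- rec[0, ]
  expect_equal(nrow(filter_complete_timepoints(empty, "m1")), 0)
  # a missing value counts as absent
  rec$value[2] <- NA
  expect_equal(nrow(filter_complete_timepoints(rec, paste0("m", 1:4))), 0)
})

test_that("completeness filtering is idempotent and commutes with censoring", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 8
    parts <- make_participants(n, tam_frac = 0.5, seed = rep)
    parts$treatment_stop[1:2] <- c(1.5, 0.4)
    rec <- dplyr::bind_rows(lapply(parts$id, function(id) {
      t <- sort(sample(0:4, sample(2:5, 1)))
      m <- lapply(t, function(tt) sample(c("m1", "m2", "m3"),
                                         sample(1:3, 1)))
      tibble::tibble(participant_id = id, time = rep(t, lengths(m)),
                     measure = unlist(m), value = stats::runif(sum(lengths(m))))
    }))
    f1 <- filter_complete_timepoints(rec, c("m1", "m2", "m3"))
    expect_identical(filter_complete_timepoints(f1, c("m1", "m2", "m3")), f1)
    a <- censor_on_treatment(f1, parts)
    b <- filter_complete_timepoints(censor_on_treatment(rec, parts),
                                    c("m1", "m2", "m3"))
    expect_identical(dplyr::arrange(a, participant_id, time, measure),
                     dplyr::arrange(b, participant_id, time, measure))
  }
})

test_that("records after drug cessation are censored, baseline always kept", {
  parts <- tibble::tibble(
    id = c("t1", "t2", "t3", "c1"),
    group = c("tamoxifen", "tamoxifen", "tamoxifen", "control"),
    age_baseline = 42, bmi = 25, baseline_year = 2011,
    treatment_stop = c(2.5, NA, 0.5, NA)
  )
  rec <- make_records(list(t1 = 0:3, t2 = 0:5, t3 = 0:1, c1 = 0:5))
  out <- censor_on_treatment(rec, parts)
  expect_equal(out$time[out$participant_id == "t1"], 0:2)
  expect_equal(out$time[out$participant_id == "t2"], 0:5)
  expect_equal(out$time[out$participant_id == "t3"], 0)
  expect_equal(out$time[out$participant_id == "c1"], 0:5)
})

test_that("controls are matched within one year of age and the same baseline year", {
  cases <- tibble::tibble(id = "case1", group = "tamoxifen",
                          age_baseline = 42, bmi = 25, baseline_year = 2011,
                          treatment_stop = NA_real_)
  pool <- tibble::tibble(
    id = c("p1", "p2", "p3"), group = "control",
    age_baseline = c(41.5, 44, 42), bmi = 25,
    baseline_year = c(2011, 2011, 2012), treatment_stop = NA_real_
  )
  m <- match_controls(cases, pool)
  expect_equal(m$control_id, "p1")  # p2 too old, p3 wrong year
  expect_equal(nrow(match_controls(cases, pool[0, ])), 0)
})

test_that("over-supplied matches break ties by age difference then id", {
  cases <- tibble::tibble(id = "case1", group = "tamoxifen",
                          age_baseline = 42, bmi = 25, baseline_year = 2011,
                          treatment_stop = NA_real_)
  pool <- tibble::tibble(
    id = c("p1", "p2", "p3", "p4", "p5"), group = "control",
    age_baseline = c(42.9, 42.1, 41.9, 43.5, 42.1), bmi = 25,
    baseline_year = 2011, treatment_stop = NA_real_
  )
  m <- match_controls(cases, pool, max_per_case = 2)
  # |diff|: p1 .9, p2 .1, p3 .1, p5 .1; p4 ineligible; ties p2/p3/p5 at .1
  # resolved lexicographically -> p2 then p3
  expect_equal(sort(m$control_id), c("p2", "p3"))
})

test_that("matching never reuses a control and always satisfies both constraints", {
  set.seed(33)
  for (rep in 1:5) {
    cases <- make_participants(6, tam_frac = 1, seed = rep)
    pool <- make_participants(15, tam_frac = 0, seed = rep + 50)
    pool$id <- paste0("pool", seq_len(nrow(pool)))
    pool$baseline_year <- sample(2010:2012, 15, replace = TRUE)
    cases$baseline_year <- sample(2010:2012, 6, replace = TRUE)
    m <- match_controls(cases, pool)
    expect_false(anyDuplicated(m$control_id) > 0)
    for (k in seq_len(nrow(m))) {
      ca <- cases[cases$id == m$case_id[k], ]
      co <- pool[pool$id == m$control_id[k], ]
      expect_lte(abs(ca$age_baseline - co$age_baseline), 1)
      expect_equal(ca$baseline_year, co$baseline_year)
    }
    counts <- table(m$case_id)
    expect_true(all(counts <= 2))
  }
})

test_that("sample membership follows available visits; C nested in B nested in A", {
  parts <- make_participants(4, seed = 2)
  parts$id <- c("w1", "w2", "w3", "w4")
  rec <- make_records(list(w1 = 0, w2 = c(0, 1, 2), w3 = c(0, 2),
                           w4 = c(1, 2)))
  s <- build_samples(rec, parts)
  expect_equal(s$A$participant_ids, c("w1", "w2", "w3"))
  expect_equal(s$B$participant_ids, "w2")
  expect_equal(s$C$participant_ids, "w2")
  expect_true(all(s$C$participant_ids %in% s$B$participant_ids))
  expect_true(all(s$B$participant_ids %in% s$A$participant_ids))
  # every subset of {0,1,2} lands in the right samples
  subsets <- list(0, 1, 2, c(0, 1), c(0, 2), c(1, 2), c(0, 1, 2))
  for (ss in subsets) {
    p1 <- make_participants(1, seed = 9)
    r1 <- make_records(stats::setNames(list(ss), p1$id))
    s1 <- build_samples(r1, p1)
    expect_equal(length(s1$A$participant_ids), as.integer(0 %in% ss))
    expect_equal(length(s1$B$participant_ids), as.integer(all(c(0, 1) %in% ss)))
    expect_equal(length(s1$C$participant_ids), as.integer(all(c(0, 1, 2) %in% ss)))
  }
})

test_that("summaries report standard statistics and the mean/SD effect size", {
  s <- summarize_values(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sqrt(2.5))
  s2 <- summarize_values(rep(4, 6))
  expect_equal(s2$sd, 0)
  expect_true(is.na(s2$mean_sd))
  expect_match(s2$flag, "constant")
  expect_match(summarize_values(5)$flag, "n < 2")
  # a change distribution with mean -6.4 and SD 9.8 has mean/SD -0.65 at 2 dp
  expect_equal(round(-6.4 / 9.8, 2), -0.65)
})

test_that("cohorts survive a write/read round trip in the ingestion format", {
  coh <- generate_cohort(generator_config(n_cases = 12, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$participants$id, coh$participants$id)
  expect_equal(back$participants$bmi, coh$participants$bmi)
  expect_equal(back$participants$treatment_stop,
               coh$participants$treatment_stop)
  expect_equal(back$records$value, coh$records$value, tolerance = 1e-12)
  expect_equal(back$records$measure, coh$records$measure)
})
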