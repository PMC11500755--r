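test_that("sliding-window arithmetic matches the standard scheme", {
  expect_equal(count_windows(c(-600, 200), 200, 50), 13)
  expect_equal(count_windows(c(0, 200), 200, 50), 1)
  expect_equal(28 * count_windows(c(-600, 200), 200, 50), 364)
  expect_equal(window_starts(), seq(-600, 0, by = 50))
  expect_error(count_windows(c(-600, 200), 200, 0), "positive")
  expect_error(count_windows(c(0, 100), 200, 50), "longer")
})

fake_roi_series <- function(n_sub = 2, pct_value = 10) {
  meta <- do.call(rbind, lapply(seq_len(n_sub), function(s)
    data.frame(subject = paste0("sub-", s),
               task = rep(c("congruent_reading", "incongruent_reading",
                            "stroop"), each = 4),
               trial_number = rep(1:4, 3), rt = 900)))
  pct <- matrix(pct_value, nrow(meta), 80)
  list(LOG_left = list(pct = pct, baseline = matrix(0, nrow(meta), 40),
                       meta = meta))
}

parts2 <- data.frame(subject = c("sub-1", "sub-2"), age = c(14, 10),
                     sex = c(1, 0), lesion = c(0, 1), n_asm = c(3, 2))

test_that("window table has one row per subject x trial x window", {
  rs <- fake_roi_series()
  wt <- build_window_table(rs, parts2)
  expect_equal(nrow(wt), 2 * 12 * 13)
  expect_true(all(wt$amplitude == 10))  # constant series -> constant means
  expect_equal(sort(unique(wt$window_start)), seq(-600, 0, 50))
  expect_equal(unique(wt$task[wt$subject == "sub-1"][1:12 * 13]),
               c(0, 1))
})

test_that("window means equal hand-computed bin averages", {
  rs <- fake_roi_series()
  # two trials with a recognizable ramp over the 80 bins
  rs$LOG_left$pct[1, ] <- seq_len(80)
  rs$LOG_left$pct[2, ] <- rep(c(1, 2), 40)
  wt <- build_window_table(rs, parts2)
  bin_starts <- seq(-600, 190, by = 10)
  w0 <- -500
  cols <- which(bin_starts >= w0 & bin_starts < w0 + 200)
  r1 <- wt[wt$window_start == w0 & wt$subject == "sub-1" &
             wt$trial_number == 1 & wt$task == 0, ]
  expect_equal(r1$amplitude[1], mean(seq_len(80)[cols]))
})

test_that("missing covariates are reported by subject and field", {
  rs <- fake_roi_series()
  p_bad <- parts2
  p_bad$age[2] <- NA
  expect_error(build_window_table(rs, p_bad), "age.*sub-2")
})

test_that("with no between-subject variance the mixed fit matches OLS", {
  set.seed(20)
  df <- data.frame(
    subject = rep(c("sub-1", "sub-2", "sub-3"), each = 40),
    roi = "LOG_left", window_start = -500,
    task = rep(rep(0:1, each = 20), 3),
    trial_number = rep(1:20, 6),
    age = rep(c(14, 15, 16), each = 40),
    sex = 0, lesion = 0, n_asm = 0)
  df$amplitude <- 2 + 5 * df$task + rnorm(nrow(df))
  fit <- fit_window_model(df, covariates = c("trial_number", "age"))
  ols <- stats::lm(amplitude ~ task + trial_number + age, df)
  expect_equal(fit$coefficient, unname(coef(ols)["task"]), tolerance = 0.02)
  expect_equal(fit$df, nrow(df) - 4)
})

test_that("singular covariates are dropped with a warning and refit", {
  set.seed(21)
  # four subjects whose sex/lesion/medication profile has full rank, but a
  # constant age column that must be dropped
  prof <- data.frame(sex = c(0, 1, 0, 1), lesion = c(0, 0, 1, 1),
                     n_asm = c(1, 2, 3, 5))
  df <- data.frame(
    subject = rep(paste0("sub-", 1:4), each = 30),
    roi = "LOG_left", window_start = -500,
    task = rep(rep(0:1, each = 15), 4),
    trial_number = rep(1:15, 8),
    age = 14, sex = rep(prof$sex, each = 30),
    lesion = rep(prof$lesion, each = 30),
    n_asm = rep(prof$n_asm, each = 30))
  df$amplitude <- 1 + 3 * df$task + rnorm(nrow(df))
  expect_warning(fit <- fit_window_model(df), "age")
  expect_equal(fit$dropped, "age")
  expect_equal(fit$df, nrow(df) - 6)  # intercept + task + trial + 3 kept
  expect_equal(fit$coefficient, 3, tolerance = 0.3)
  expect_error(fit_window_model(df[df$subject == "sub-1", ]), "2 subjects")
})

test_that("the pooled FDR flags match the brute-force oracle", {
  set.seed(22)
  eff <- data.frame(roi = rep(paste0("R", 1:28), each = 13),
                    window_start = rep(seq(-600, 0, 50), 28),
                    coefficient = rnorm(364))
  eff$p <- runif(364)^3
  flagged <- fdr_across_tests(eff, 0.05)
  expect_equal(flagged$q_significant, bh_oracle(eff$p, 0.05))
  expect_equal(flagged$preference[flagged$q_significant & flagged$coefficient > 0][1],
               "stroop")
  all1 <- transform(eff, p = 1)
  expect_false(any(fdr_across_tests(all1, 0.05)$q_significant))
  one <- transform(eff, p = c(1e-6, rep(1, 363)))
  expect_equal(sum(fdr_across_tests(one, 0.05)$q_significant), 1)
})

test_that("RT mixed model reproduces the cohort degrees of freedom", {
  coh <- simulate_cohort(cohort_config(seed = 23), signals = FALSE)
  m <- fit_rt_model(coh$events, subjects = coh$participants$subject)
  expect_equal(m$df, 838)      # 840 trials - 2 fixed coefficients
  expect_equal(m$n_obs, 840)
  expect_gt(m$coefficient, 200)
  expect_lt(m$coefficient, 360)
  m2 <- fit_rt_model(coh$events, "incongruent_vs_congruent",
                     subjects = coh$participants$subject)
  expect_equal(m2$df, 558)     # 560 reading trials - 2
  ev1 <- coh$events[[1]]
  pooled <- cbind(subject = "sub-1", ev1[ev1$task == "stroop", ])
  pooled2 <- rbind(pooled, transform(pooled, subject = "sub-2"))
  expect_error(fit_rt_model(pooled2), "both task levels")
})
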