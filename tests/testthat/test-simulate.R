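test_that("the default cohort has 7 subjects with 3 x 40 trials each", {
  coh <- simulate_cohort(cohort_config(seed = 1), signals = FALSE)
  expect_length(coh$events, 7)
  for (ev in coh$events) {
    expect_equal(nrow(ev), 120)
    expect_equal(as.vector(table(ev$task)), rep(40, 3))
    expect_true(all(ev$response_onset > ev$stimulus_onset))
    expect_equal(ev$rt, ev$response_onset - ev$stimulus_onset)
  }
  expect_equal(nrow(coh$participants), 7)
})

test_that("stimulus onsets are spaced by display plus a 2000-2500 ms ISI", {
  coh <- simulate_cohort(cohort_config(seed = 2), signals = FALSE)
  ev <- coh$events[[1]]
  for (task in unique(ev$task)) {
    on <- ev$stimulus_onset[ev$task == task]
    gaps <- diff(on) - coh$config$stim_duration_ms
    expect_true(all(gaps >= 2000 - 1 & gaps <= 2500 + 1))
  }
})

test_that("a minimal cohort yields exactly one stimulus and response event", {
  cfg <- cohort_config(n_subjects = 1, trials_per_task = 1, tasks = "stroop",
                       effect_map = default_effect_map()[0, ],
                       rois = "LOG_left", channels_per_roi = 2,
                       covariates = default_covariates()[1, ], seed = 3)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$events[[1]]), 1)
  expect_true(is.matrix(coh$recordings[[1]]$samples))
})

test_that("identical seeds give bit-identical cohorts", {
  cfg <- cohort_config(n_subjects = 2, trials_per_task = 3,
                       channels_per_roi = 1, seed = 4)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$events, c2$events)
  expect_identical(c1$recordings, c2$recordings)
  expect_identical(c1$streamlines, c2$streamlines)
  c3 <- simulate_cohort(cohort_config(n_subjects = 2, trials_per_task = 3,
                                      channels_per_roi = 1, seed = 5))
  expect_false(identical(c1$events, c3$events))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(cohort_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_config(trials_per_task = -1), "trials_per_task")
  expect_error(cohort_config(rt_means = c(congruent_reading = -5,
                                          incongruent_reading = 1034,
                                          stroop = 1211)), "rt_means")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(cohort_config(rois = "nowhere"), "rois")
  expect_error(effect_spec("LOG_left", direction = -1, amplitude_pct = 5,
                           window = c(0, -100)), "window")
  expect_error(effect_spec("LOG_left", direction = 2, amplitude_pct = 5,
                           window = c(-100, 0)), "direction")
})

test_that("response times follow mean + subject intercept + trial noise", {
  cfg0 <- cohort_config(rt_sds = c(congruent_reading = 0,
                                   incongruent_reading = 0, stroop = 0),
                        rt_subject_sd = 0)
  rt <- simulate_response_times("congruent_reading", 0, cfg0, 5)
  expect_equal(rt, rep(826, 5))  # zero noise: exactly the configured mean
  rt2 <- simulate_response_times("stroop", 50, cfg0, 3)
  expect_equal(rt2, rep(1261, 3))
  cfg <- cohort_config()
  big <- simulate_response_times("congruent_reading", 0, cfg, 10000,
                                 seed = 6)
  se <- sd(big) / sqrt(length(big))
  expect_lt(abs(mean(big) - 826), 3 * se)
  expect_true(all(big >= 200))
  expect_error(simulate_response_times("naming", 0, cfg, 5), "task")
  expect_error(simulate_response_times("stroop", 0, cfg, -3), "non-negative")
})

test_that("a zero-gain injection is the identity", {
  tr <- rnorm(3000)
  expect_identical(inject_high_gamma(tr, 1000, 200, gain = 0), tr)
  expect_error(inject_high_gamma(tr, 2900, 200, gain = 0.1), "bounds")
  expect_error(inject_high_gamma(tr, 100, 200, gain = -0.5), ">= 0")
})

test_that("injection only touches samples inside the burst window", {
  tr <- hgconn:::pink_noise(6000, 10, 1, 1000, 25)
  tr2 <- inject_high_gamma(tr, 3000, 200, gain = 0.3, seed = 11)
  expect_identical(tr2[1:3000], tr[1:3000])
  expect_identical(tr2[3202:6000], tr[3202:6000])
  expect_false(identical(tr2[3001:3200], tr[3001:3200]))
})

test_that("injected bursts are calibrated in percent-change units", {
  # measure the 70-110 Hz percent change a gain-0.2 burst produces on a
  # pink-noise background, over seeded replicates
  k <- design_demod_kernel()
  f <- seq(70, 110, 5)
  reps <- 200
  meas <- vapply(seq_len(reps), function(i) {
    tr <- hgconn:::pink_noise(4000, 5000 + i, 1, 1000, 25)
    tr2 <- inject_high_gamma(tr, 1800, 200, gain = 0.2, seed = i)
    ctr <- round(seq(1805, 1995, 10)) + 1
    base <- round(seq(205, 1595, 10)) + 1
    a0 <- mean(rowMeans(hgconn:::demod_amplitude_at(tr2, base, k, f)))
    ab <- mean(rowMeans(hgconn:::demod_amplitude_at(tr2, ctr, k, f)))
    100 * (ab - a0) / a0
  }, numeric(1))
  expect_equal(mean(meas), 20, tolerance = 0.2)  # 20% +/- 4 points
})

test_that("streamlines connect the requested parcels within bounds", {
  parcels <- default_parcels()
  spec <- rbind(c("LOG_left", "pFG_left"))
  set <- simulate_streamlines(parcels, spec, n_per_pair = 10, seed = 12)
  expect_equal(length(unique(set$streamline_id)), 10)
  pa <- parcels[parcels$label == "LOG_left", ]
  pb <- parcels[parcels$label == "pFG_left", ]
  for (pts in split(set[c("x", "y", "z")], set$streamline_id)) {
    ends <- as.matrix(pts[c(1, nrow(pts)), ])
    da <- min(sqrt(colSums((t(ends) - unlist(pa[c("x", "y", "z")]))^2)))
    db <- min(sqrt(colSums((t(ends) - unlist(pb[c("x", "y", "z")]))^2)))
    expect_lt(da, pa$radius + 1e-9)
    expect_lt(db, pb$radius + 1e-9)
    expect_lt(streamline_length(as.matrix(pts)), 250)
  }
  empty <- simulate_streamlines(parcels, NULL, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(simulate_streamlines(parcels[0, ], spec), "empty")
  expect_error(simulate_streamlines(parcels, rbind(c("LOG_left", "X"))),
               "absent")
})

test_that("all-low QA streamlines are removed by the default filter", {
  set <- simulate_streamlines(default_parcels(), default_adjacency_spec(),
                              n_per_pair = 5, seed = 13, qa_low_frac = 1)
  kept <- filter_streamlines(set, filter_config())
  expect_equal(nrow(kept), 0)
})

test_that("cohort truth lists the expected containment and support edges", {
  coh <- simulate_cohort(cohort_config(seed = 14), signals = FALSE)
  tr <- coh$truth
  key <- paste(tr$edges$roi_a, tr$edges$roi_b, tr$edges$window_start)
  expect_true("LOG_left pFG_left -500" %in% key)
  expect_true(all(c("aMFG_left pMFG_left -600", "pMFG_left PreCG_left -600",
                    "aMFG_left PreCG_left -600") %in% key))
  # support covers every containment edge
  skey <- paste(tr$edge_support$roi_a, tr$edge_support$roi_b,
                tr$edge_support$window_start)
  expect_true(all(key %in% skey))
  expect_true(isSymmetric(tr$adjacency))
})
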