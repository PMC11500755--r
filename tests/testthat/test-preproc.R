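make_channels <- function(n, flagged = integer(0), flag = "soz") {
  ch <- data.frame(channel_id = paste0("e", seq_len(n)),
                   roi = "LOG_left", artifact = FALSE, soz = FALSE,
                   spikes = FALSE, lesion = FALSE)
  if (length(flagged)) ch[[flag]][flagged] <- TRUE
  ch
}

test_that("channel selection excludes exactly the flagged channels", {
  ch <- make_channels(6)
  expect_true(all(select_channels(ch)))
  ch$soz[2] <- TRUE
  ch$artifact[5] <- TRUE
  expect_equal(select_channels(ch), c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  # a 600-site grid with 53 flagged sites keeps 547
  big <- make_channels(600, flagged = seq_len(53), flag = "spikes")
  expect_equal(sum(select_channels(big)), 547)
  bad <- make_channels(3)
  bad$lesion <- c(0, 2, 0)
  expect_error(select_channels(bad), "0/1")
  expect_error(select_channels(data.frame()), "non-empty")
})

test_that("common average reference removes the cross-channel mean", {
  x <- matrix(c(3, -1), 1, 2)
  expect_equal(as.vector(common_average_reference(x)), c(2, -2))
  set.seed(1)
  r <- matrix(rnorm(5000), ncol = 5)
  post <- common_average_reference(r)
  expect_lt(max(abs(rowMeans(post))), 1e-9)
  # adding a common offset changes nothing
  expect_equal(common_average_reference(r + 42), post,
               tolerance = 1e-10, ignore_attr = TRUE)
  # idempotent
  expect_equal(common_average_reference(post), post,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(common_average_reference(r, include = c(TRUE, rep(FALSE, 4))),
               "at least 2")
})

test_that("excluded channels pass through the reference unreferenced", {
  set.seed(2)
  r <- matrix(rnorm(400), ncol = 4)
  inc <- c(TRUE, TRUE, TRUE, FALSE)
  post <- common_average_reference(r, include = inc)
  expect_equal(post[, 4], r[, 4])
  expect_lt(max(abs(rowMeans(post[, 1:3]))), 1e-9)
  expect_equal(attr(post, "car_referenced"), inc)
})

test_that("epoching yields exactly span/10 bins on both locks", {
  ev <- data.frame(stimulus_onset = c(1000, 3000),
                   response_onset = c(1900, 4100))
  x <- matrix(rnorm(12000), ncol = 2)
  ep_s <- epoch(x, 1000, ev, "stimulus", c(-200, 600))
  ep_r <- epoch(x, 1000, ev, "response", c(-600, 200))
  expect_equal(dim(ep_s), c(2, 2, 80))
  expect_equal(dim(ep_r), c(2, 2, 80))
  expect_equal(attr(ep_s, "bin_starts"), seq(-200, 590, by = 10))
  ev_bad <- data.frame(stimulus_onset = c(100, 3000),
                       response_onset = c(900, 4100))
  expect_error(epoch(x, 1000, ev_bad, "stimulus", c(-200, 600)), "trial 1")
  expect_error(epoch(x, 1000, ev, "stimulus", c(-200, 605)), "whole number")
})

test_that("epoch bins are half-open [t, t+10) means of the raw samples", {
  # signal equal to its sample index makes bin means analytic
  x <- matrix(seq_len(5000), ncol = 1)
  ev <- data.frame(stimulus_onset = 2000, response_onset = 2500)
  ep <- epoch(x, 1000, ev, "stimulus", c(0, 30))
  # bin [0,10) covers samples 2001..2010 (t0 = 0 -> sample index = ms + 1)
  expect_equal(ep[1, 1, ], c(mean(2001:2010), mean(2011:2020),
                             mean(2021:2030)))
})

test_that("baseline mean isolates the 1800-2200 ms window", {
  ev <- data.frame(stimulus_onset = 0, response_onset = 3000)
  # amplitude series on the 10-ms grid: A = 1 inside 1800-2200 ms
  # post-response, 2 elsewhere
  amp <- rep(2, 1000)
  amp[(3000 + 1800) / 10 + seq_len(40)] <- 1
  base <- epoch(matrix(amp, ncol = 1), 100, ev, "response", c(1800, 2200))
  expect_equal(as.vector(baseline_mean(base)), 1)
  const <- epoch(matrix(5, 1000, 1), 100, ev, "response", c(1800, 2200))
  expect_equal(as.vector(baseline_mean(const)), 5)
})

test_that("baseline mean reproduces hand-computed trial values", {
  ev <- data.frame(stimulus_onset = c(0, 0, 0),
                   response_onset = c(100, 200, 300))
  series <- matrix(rep(1:3, each = 300) + rep(seq(0.01, 3, 0.01), 3),
                   ncol = 1)
  ep <- epoch(series, 100, ev, "response", c(1800, 2200))
  bm <- baseline_mean(ep)
  hand <- sapply(1:3, function(tr) {
    i0 <- (ev$response_onset[tr] + 1800) / 10 + 1
    mean(series[i0:(i0 + 39), 1])
  })
  expect_equal(as.vector(bm), hand)
})

test_that("ROI aggregation averages included channels and applies the site rule", {
  ch <- data.frame(channel_id = paste0("e", 1:4),
                   roi = c("LOG_left", "LOG_left", "pFG_left", "pFG_left"),
                   artifact = c(FALSE, FALSE, FALSE, TRUE),
                   soz = FALSE, spikes = FALSE, lesion = FALSE)
  ep <- array(0, c(2, 4, 3))
  ep[, 1, ] <- 10; ep[, 2, ] <- 20; ep[, 3, ] <- 7; ep[, 4, ] <- 99
  agg <- roi_aggregate(ep, ch, min_sites = 1)
  expect_equal(agg$LOG_left, matrix(15, 2, 3))   # mean of 10 and 20
  expect_equal(agg$pFG_left, matrix(7, 2, 3))    # flagged channel ignored
  # below the cohort-wide site threshold the region disappears
  agg5 <- roi_aggregate(ep, ch, min_sites = 5,
                        site_counts = c(LOG_left = 6, pFG_left = 4))
  expect_true("LOG_left" %in% names(agg5))
  expect_false("pFG_left" %in% names(agg5))
  # linearity under scalar scaling
  agg2 <- roi_aggregate(2 * ep, ch, min_sites = 1)
  expect_equal(agg2$LOG_left, 2 * agg$LOG_left)
})
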