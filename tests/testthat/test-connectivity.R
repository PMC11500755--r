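test_that("streamline length is the Euclidean segment sum", {
  expect_equal(streamline_length(rbind(c(0, 0, 0), c(30, 0, 0))), 30)
  expect_equal(streamline_length(rbind(c(0, 0, 0), c(10, 0, 0),
                                       c(10, 10, 0))), 20)
  set.seed(30)
  pts <- matrix(rnorm(150), ncol = 3)
  hand <- 0
  for (i in 2:50) hand <- hand + sqrt(sum((pts[i, ] - pts[i - 1, ])^2))
  expect_equal(streamline_length(pts), hand)
  expect_error(streamline_length(rbind(c(0, 0, 0))), "2 points")
})

test_that("maximum turning angle matches pairwise arccos evaluation", {
  line <- cbind(0:5, 0, 0)
  expect_equal(max_turning_angle(line), 0)
  bend <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(max_turning_angle(bend), 90)
  set.seed(31)
  pts <- matrix(cumsum(rnorm(60, 1, 0.2)), ncol = 3)
  hand <- 0
  for (i in 3:nrow(pts)) {
    u <- pts[i - 1, ] - pts[i - 2, ]
    v <- pts[i, ] - pts[i - 1, ]
    ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    hand <- max(hand, ang)
  }
  expect_equal(max_turning_angle(pts), hand)
  degen <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_error(max_turning_angle(degen), "zero-length")
  expect_error(max_turning_angle(bend[1:2, ]), "3 points")
})

# build one straight-line streamline between two points
mk_sl <- function(id, from, to, qa = 0.2, n = 10, tract = "t") {
  tt <- seq(0, 1, length.out = n)
  data.frame(streamline_id = id, point_index = seq_len(n),
             x = from[1] + tt * (to[1] - from[1]),
             y = from[2] + tt * (to[2] - from[2]),
             z = from[3] + tt * (to[3] - from[3]), qa = qa, tract = tract)
}

test_that("the filter applies QA, length, angle and exclusion rules", {
  good <- mk_sl(1, c(0, 0, 0), c(0, 100, 0))
  low_qa <- mk_sl(2, c(0, 0, 0), c(0, 100, 0), qa = 0.04)
  too_long <- mk_sl(3, c(0, 0, 0), c(0, 300, 0))
  too_short <- mk_sl(4, c(0, 0, 0), c(0, 10, 0))
  kinked <- mk_sl(5, c(0, 0, 0), c(0, 50, 0))
  kinked[8:10, c("x", "y", "z")] <- kinked[8:10, c("y", "x", "z")] + 5
  through_mask <- mk_sl(6, c(-40, -60, -35), c(40, 0, -35))
  set <- rbind(good, low_qa, too_long, too_short, kinked, through_mask)
  class(set) <- c("streamline_set", "data.frame")
  cfg <- filter_config(exclusion_regions = default_exclusion_regions())
  kept <- filter_streamlines(set, cfg)
  expect_equal(unique(kept$streamline_id), 1)
  # boundary: exactly 0.05 QA passes, 20 mm passes
  edge <- rbind(mk_sl(7, c(0, 50, 50), c(0, 70, 50), qa = 0.05))
  class(edge) <- class(set)
  expect_equal(nrow(filter_streamlines(edge, cfg)), nrow(edge))
})

test_that("a designed 100-streamline fixture filters to its known truth set", {
  set.seed(32)
  rows <- list()
  should_pass <- logical(100)
  for (i in 1:100) {
    qa <- sample(c(0.01, 0.2), 1)
    len <- sample(c(10, 120, 280), 1)
    from <- c(0, 50, 40) + rnorm(3)
    rows[[i]] <- mk_sl(i, from, from + c(0, len, 0), qa = qa)
    should_pass[i] <- qa >= 0.05 && len >= 20 && len <= 250
  }
  set <- do.call(rbind, rows)
  class(set) <- c("streamline_set", "data.frame")
  kept <- filter_streamlines(set, filter_config())
  expect_setequal(unique(kept$streamline_id), which(should_pass))
})

test_that("tightening the filter never increases survivors", {
  set <- simulate_streamlines(default_parcels(), default_adjacency_spec(),
                              n_per_pair = 10, seed = 33, qa_low_frac = 0.4)
  n_loose <- length(unique(filter_streamlines(set,
    filter_config(qa_min = 0.01, length_range = c(5, 400)))$streamline_id))
  n_mid <- length(unique(filter_streamlines(set,
    filter_config())$streamline_id))
  n_tight <- length(unique(filter_streamlines(set,
    filter_config(qa_min = 0.3, length_range = c(25, 60),
                  angle_max = 20))$streamline_id))
  expect_lte(n_mid, n_loose)
  expect_lte(n_tight, n_mid)
})

test_that("endpoint adjacency is symmetric with an empty diagonal", {
  parcels <- default_parcels()
  set <- mk_sl(1, c(-40, -78, 0), c(-40, -55, -18))  # LOG_left -> pFG_left
  class(set) <- c("streamline_set", "data.frame")
  adj <- endpoint_adjacency(set, parcels)
  expect_true(adj["LOG_left", "pFG_left"])
  expect_true(adj["pFG_left", "LOG_left"])
  expect_true(all(diag(adj) == 0))
  expect_equal(sum(adj), 2)
  # endpoints in no parcel contribute nothing
  lost <- mk_sl(2, c(200, 200, 200), c(-40, -55, -18))
  class(lost) <- class(set)
  expect_equal(sum(endpoint_adjacency(lost, parcels)), 0)
  expect_error(endpoint_adjacency(set, parcels[0, ]), "empty")
})

test_that("generator truth adjacency is reconstructed from its streamlines", {
  coh <- simulate_cohort(cohort_config(seed = 34), signals = FALSE)
  kept <- filter_streamlines(coh$streamlines,
                             filter_config(exclusion_regions =
                                             default_exclusion_regions()))
  adj <- endpoint_adjacency(kept, default_parcels())
  expect_equal(adj, coh$truth$adjacency)
})

mk_effects <- function(df) {
  df$sign <- sign(df$coefficient)
  df$q_significant <- df$sig
  df
}

test_that("the edge rule needs adjacency, simultaneity and a shared sign", {
  adj <- matrix(FALSE, 3, 3,
                dimnames = list(c("LOG_left", "pFG_left", "MTG_left"),
                                c("LOG_left", "pFG_left", "MTG_left")))
  adj["LOG_left", "pFG_left"] <- adj["pFG_left", "LOG_left"] <- TRUE
  eff <- mk_effects(data.frame(
    roi = c("LOG_left", "pFG_left", "MTG_left"),
    window_start = -500, coefficient = c(-16, -14, -4), sig = TRUE))
  e <- task_preferential_edges(eff, adj)
  expect_equal(nrow(e), 1)
  expect_equal(e$preference, "reading")
  expect_equal(e$window_start, -500)
  # opposite signs: no edge
  eff2 <- mk_effects(transform(eff, coefficient = c(-16, 14, -4)))
  expect_equal(nrow(task_preferential_edges(eff2, adj)), 0)
  # non-significant partner: no edge
  eff3 <- eff; eff3$q_significant[2] <- FALSE
  expect_equal(nrow(task_preferential_edges(eff3, adj)), 0)
  expect_error(task_preferential_edges(
    mk_effects(data.frame(roi = "SFG_left", window_start = -500,
                          coefficient = 1, sig = TRUE)), adj), "absent")
})

test_that("edge sets equal the brute-force triple loop on random inputs", {
  set.seed(35)
  rois <- paste0("R", 1:20)
  for (rep in 1:5) {
    adj <- matrix(runif(400) < 0.25, 20, 20,
                  dimnames = list(rois, rois))
    adj <- adj | t(adj); diag(adj) <- FALSE
    eff <- mk_effects(data.frame(
      roi = rep(rois, 13), window_start = rep(seq(-600, 0, 50), each = 20),
      coefficient = rnorm(260), sig = runif(260) < 0.3))
    e <- task_preferential_edges(eff, adj)
    got <- sort(paste(e$roi_a, e$roi_b, e$window_start,
                      ifelse(e$preference == "stroop", 1, -1)))
    expect_equal(got, edge_oracle(eff, adj))
    # removing adjacency rows never adds edges
    adj2 <- adj; adj2[3, ] <- FALSE; adj2[, 3] <- FALSE
    e2 <- task_preferential_edges(eff, adj2)
    expect_true(all(paste(e2$roi_a, e2$roi_b, e2$window_start) %in%
                      paste(e$roi_a, e$roi_b, e$window_start)))
  }
})

test_that("atlas export round-trips losslessly", {
  dir <- tempfile("atlas")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  e0 <- task_preferential_edges(
    mk_effects(data.frame(roi = c("A", "B"), window_start = -500,
                          coefficient = c(1, 1), sig = FALSE)),
    matrix(TRUE, 2, 2, dimnames = list(c("A", "B"), c("A", "B"))))
  export_atlas(e0, file.path(dir, "empty"))
  back0 <- read_atlas(file.path(dir, "empty"))
  expect_equal(nrow(back0), 0)
  e3 <- data.frame(roi_a = c("LOG_left", "pFG_left", "aMFG_left"),
                   roi_b = c("pFG_left", "MTG_left", "pMFG_left"),
                   window_start = c(-500, -500, -600),
                   preference = c("reading", "reading", "stroop"),
                   coefficient_a = c(-16.6, -14, 5.9),
                   coefficient_b = c(-14, -4.6, 4.0))
  export_atlas(e3, file.path(dir, "three"))
  back <- read_atlas(file.path(dir, "three"))
  rownames(back) <- NULL
  expect_equal(back, e3[order(e3$window_start, e3$roi_a), ],
               ignore_attr = TRUE)
})
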