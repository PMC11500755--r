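# Synthetic iEEG cohort generator: pink-noise recordings with calibrated
# narrowband high-gamma bursts, behavioral response times, subject
# covariates, and streamline sets, all a pure function of one integer seed.

.hg_cache <- new.env(parent = emptyenv())

# First-order pole/zero cascade giving a -10 dB/decade power slope (1/f)
# between ~0.2 and ~350 Hz: poles log-spaced every half decade, zeros at the
# log-midpoints, mapped to z by the matched-z transform.
pink_sections <- function(rate) {
  fp <- 0.2 * sqrt(10)^(0:6)
  fz <- fp * 10^0.25
  list(p = exp(-2 * pi * fp / rate), z = exp(-2 * pi * fz / rate))
}

# sd of the unit-input cascade output, measured once per rate and cached, so
# generated traces can be scaled to a requested RMS deterministically.
pink_gain <- function(rate) {
  key <- paste0("pinkgain_", rate)
  if (is.null(.hg_cache[[key]])) {
    d <- pink_sections(rate)
    .hg_cache[[key]] <- sd(cpp_pink_noise(200000L, 987654321, 0, d$p, d$z))
  }
  .hg_cache[[key]]
}

# Seeded pink noise scaled to RMS `sd_uv`. `stream` decorrelates channels.
pink_noise <- function(n, seed, stream, rate = 1000, sd_uv = 1) {
  d <- pink_sections(rate)
  cpp_pink_noise(as.integer(n), seed, stream, d$p, d$z) *
    (sd_uv / pink_gain(rate))
}

# Brick-wall band-pass by FFT masking; input and output are real.
bandlimit <- function(x, band, rate) {
  n <- length(x)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)
  mask <- f >= band[1] & f <= band[2]
  Re(fft(fft(x) * mask, inverse = TRUE)) / n
}

# Flat-top envelope with raised-cosine ramps. Ramps live inside the window.
burst_envelope <- function(duration_ms, ramp_ms, rate) {
  len <- round(duration_ms * rate / 1000)
  r <- max(1L, round(ramp_ms * rate / 1000))
  if (2 * r > len) r <- floor(len / 2)
  env <- rep(1, len)
  up <- 0.5 * (1 - cos(pi * (seq_len(r) - 0.5) / r))
  env[seq_len(r)] <- up
  env[len + 1 - seq_len(r)] <- up
  env
}

# Expected per-bin band amplitude of a unit-RMS narrowband burst as the
# demodulator sees it, averaged over seeded realizations; cached.
unit_burst_profile <- function(duration_ms, band, ramp_ms, kernel,
                               n_rep = 24) {
  rate <- kernel$rate
  key <- paste("uprof", duration_ms, band[1], band[2], ramp_ms, rate,
               round(kernel$temporal_fwhm_ms, 3), sep = "_")
  if (!is.null(.hg_cache[[key]])) return(.hg_cache[[key]])
  len <- round(duration_ms * rate / 1000)
  pad <- kernel$half_support
  env <- burst_envelope(duration_ms, ramp_ms, rate)
  centers <- pad + round((seq(5, duration_ms - 5, by = 10)) * rate / 1000)
  freqs <- seq(band[1], band[2], by = 5)
  acc <- 0
  for (r in seq_len(n_rep)) {
    w <- cpp_gaussian_noise(len, 271828182, 1000 + r)
    nb <- bandlimit(w, band, rate)
    nb <- nb / sd(nb)
    x <- c(numeric(pad), nb * env, numeric(pad))
    amp <- demod_amplitude_at(x, centers, kernel, freqs)
    acc <- acc + rowMeans(amp)
  }
  .hg_cache[[key]] <- acc / n_rep
}

# Demodulated band-amplitude floor of unit-RMS pink noise; cached per
# (rate, band, kernel). Scales linearly with the noise RMS.
pink_band_floor <- function(band, kernel) {
  rate <- kernel$rate
  key <- paste("floor", band[1], band[2], rate,
               round(kernel$temporal_fwhm_ms, 3), sep = "_")
  if (!is.null(.hg_cache[[key]])) return(.hg_cache[[key]])
  n <- 6 * rate
  x <- pink_noise(n, 314159265, 0, rate, 1)
  pad <- kernel$half_support
  centers <- seq(pad + 1, n - pad, by = rate / 100)
  freqs <- seq(band[1], band[2], by = 5)
  .hg_cache[[key]] <- mean(rowMeans(demod_amplitude_at(x, centers, kernel,
                                                       freqs)))
}

# Burst scale achieving a target window-mean percent change of 100*gain over
# a noise floor A0. Amplitudes of the independent background and burst add in
# quadrature, so the expected percent change in bin b for scale s is
# 100*(sqrt(A0^2 + (s*a_u(b))^2)/A0 - 1); solve for the window mean.
burst_scale_for_gain <- function(gain, floor_amp, profile) {
  if (gain == 0) return(0)
  f <- function(s)
    mean(sqrt(floor_amp^2 + (s * profile)^2)) / floor_amp - 1 - gain
  upper <- 10 * (1 + gain) * floor_amp / max(profile)
  uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' Inject a calibrated high-gamma burst into a voltage trace
#'
#' Adds an amplitude-modulated narrowband (default 70-110 Hz) noise burst to
#' `trace`, scaled so that the percent-change band amplitude measured by the
#' demodulation pipeline over the burst window is approximately `100 * gain`
#' relative to the trace's own noise floor. The envelope is flat with
#' raised-cosine ramps, which keeps the per-bin and window-mean responses
#' close and avoids ringing on the 10-ms analysis grid. Because the burst is
#' independent noise, amplitudes add in quadrature; the calibration inverts
#' that relation.
#'
#' @param trace numeric voltage vector.
#' @param onset_ms,duration_ms burst placement, ms from the start of `trace`;
#'   must lie inside it.
#' @param gain target fractional amplitude increase (>= 0); 0 returns the
#'   trace unchanged.
#' @param band Hz range of the burst carrier.
#' @param rate sampling rate, Hz.
#' @param seed integer seed for the burst noise realization.
#' @param ramp_ms envelope ramp length.
#' @param kernel demodulation kernel defining the measuring instrument
#'   (default: the standard 31.6-ms kernel).
#' @param calibration optional list `(floor_amp, profile)` precomputed by the
#'   caller (the cohort generator shares one across bursts); when NULL the
#'   floor is measured from `trace` outside the burst window.
#' @return the trace with the burst added.
#' @export
inject_high_gamma <- function(trace, onset_ms, duration_ms, gain,
                              band = c(70, 110), rate = 1000, seed = 1,
                              ramp_ms = 20, kernel = NULL,
                              calibration = NULL) {
  if (!is.finite(gain) || gain < 0)
    stop("gain must be >= 0 (decreases are modeled as increases on the ",
         "other side of a contrast)")
  n <- length(trace)
  len <- round(duration_ms * rate / 1000)
  i0 <- round(onset_ms * rate / 1000) + 1
  if (onset_ms < 0 || i0 + len - 1 > n)
    stop("burst [", onset_ms, ", ", onset_ms + duration_ms,
         "] ms exceeds trace bounds")
  if (gain == 0) return(trace)
  kernel <- kernel %||% design_demod_kernel(rate = rate)
  profile <- unit_burst_profile(duration_ms, band, ramp_ms, kernel)
  if (is.null(calibration)) {
    pad <- kernel$half_support
    centers <- seq(pad + 1, n - pad, by = rate / 100)
    keep <- centers < i0 - pad | centers > i0 + len - 1 + pad
    if (sum(keep) < 10)
      stop("trace too short to measure its noise floor outside the burst")
    freqs <- seq(band[1], band[2], by = 5)
    floor_amp <- mean(rowMeans(demod_amplitude_at(trace, centers[keep],
                                                  kernel, freqs)))
    if (floor_amp <= 0) stop("cannot calibrate against a silent trace")
  } else {
    floor_amp <- calibration$floor_amp
    if (!is.null(calibration$profile)) profile <- calibration$profile
  }
  s <- burst_scale_for_gain(gain, floor_amp, profile)
  w <- cpp_gaussian_noise(len, seed, 77)
  nb <- bandlimit(w, band, rate)
  nb <- nb / sd(nb)
  idx <- i0:(i0 + len - 1)
  trace[idx] <- trace[idx] + s * nb * burst_envelope(duration_ms, ramp_ms, rate)
  trace
}

#' Simulate response times for one subject and task
#'
#' Generative model: task mean + subject intercept + Gaussian trial noise,
#' truncated below at `config$rt_trunc` ms (by resampling). The trial noise
#' SD is derived from the configured pooled task SD by removing the subject
#' variance: `sqrt(rt_sds[task]^2 - rt_subject_sd^2)`.
#'
#' @param task task label present in `config$tasks`.
#' @param subject_effect this subject's RT intercept, ms.
#' @param config a [cohort_config()].
#' @param n number of trials (>= 0).
#' @param seed optional seed (NULL: use the current RNG stream).
#' @return numeric vector of `n` response times in ms.
#' @export
simulate_response_times <- function(task, subject_effect = 0, config, n,
                                    seed = NULL) {
  if (!task %in% config$tasks) stop("unknown task label: ", task)
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n))
    stop("n must be a non-negative integer")
  trial_sd <- sqrt(max(0, config$rt_sds[[task]]^2 - config$rt_subject_sd^2))
  with_local_seed(seed, {
    rt <- config$rt_means[[task]] + subject_effect + rnorm(n, 0, trial_sd)
    bad <- which(rt < config$rt_trunc)
    guard <- 0
    while (length(bad) && guard < 1000) {
      rt[bad] <- config$rt_means[[task]] + subject_effect +
        rnorm(length(bad), 0, trial_sd)
      bad <- bad[rt[bad] < config$rt_trunc]
      guard <- guard + 1
    }
    if (length(bad)) rt[bad] <- config$rt_trunc
    rt
  })
}

#' Simulate a tractography streamline set
#'
#' Draws `n_per_pair` smooth polylines (quadratic Bezier arcs with randomized
#' bow) between each requested parcel pair, endpoints sampled inside the
#' parcel spheres, with per-streamline quantitative anisotropy sampled above
#' or below the usual 0.05 threshold in configurable proportions so the
#' downstream filter has work to do.
#'
#' @param parcel_layout data.frame (label, x, y, z, radius), mm.
#' @param adjacency_spec two-column matrix/data.frame of ROI label pairs; an
#'   empty spec yields an empty set.
#' @param n_per_pair streamlines per pair.
#' @param seed integer seed.
#' @param qa_low_frac fraction of streamlines with QA below 0.05.
#' @param qa_range,qa_low_range QA sampling ranges for the two groups.
#' @param n_points vertices per polyline.
#' @return a `streamline_set`: long data.frame (streamline_id, point_index,
#'   x, y, z, qa, tract).
#' @export
simulate_streamlines <- function(parcel_layout, adjacency_spec,
                                 n_per_pair = 25, seed = 1,
                                 qa_low_frac = 0.2,
                                 qa_range = c(0.06, 0.5),
                                 qa_low_range = c(0.005, 0.045),
                                 n_points = 40) {
  if (is.null(parcel_layout) || nrow(parcel_layout) == 0)
    stop("parcel layout is empty")
  empty <- data.frame(streamline_id = integer(), point_index = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      qa = numeric(), tract = character())
  class(empty) <- c("streamline_set", "data.frame")
  if (is.null(adjacency_spec) || nrow(adjacency_spec) == 0) return(empty)
  adjacency_spec <- as.matrix(adjacency_spec)
  missing <- setdiff(unique(c(adjacency_spec)), parcel_layout$label)
  if (length(missing)) stop("adjacency_spec names ROIs absent from the ",
                            "parcel layout: ", paste(missing, collapse = ", "))
  with_local_seed(seed, {
    rows <- list()
    id <- 0L
    tvec <- seq(0, 1, length.out = n_points)
    for (k in seq_len(nrow(adjacency_spec))) {
      pa <- parcel_layout[parcel_layout$label == adjacency_spec[k, 1], ]
      pb <- parcel_layout[parcel_layout$label == adjacency_spec[k, 2], ]
      for (j in seq_len(n_per_pair)) {
        id <- id + 1L
        a <- unlist(pa[c("x", "y", "z")]) + runif_ball(pa$radius * 0.6)
        b <- unlist(pb[c("x", "y", "z")]) + runif_ball(pb$radius * 0.6)
        chord <- b - a
        perp <- pracma_nullspace_vec(chord)
        ctrl <- (a + b) / 2 + perp * sqrt(sum(chord^2)) * runif(1, 0.1, 0.25)
        pts <- outer((1 - tvec)^2, a) + outer(2 * tvec * (1 - tvec), ctrl) +
          outer(tvec^2, b)
        qa <- if (runif(1) < qa_low_frac) runif(1, qa_low_range[1], qa_low_range[2])
              else runif(1, qa_range[1], qa_range[2])
        rows[[id]] <- data.frame(streamline_id = id,
                                 point_index = seq_len(n_points),
                                 x = pts[, 1], y = pts[, 2], z = pts[, 3],
                                 qa = qa,
                                 tract = paste(adjacency_spec[k, ],
                                               collapse = "-"))
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("streamline_set", "data.frame")
    out
  })
}

# uniform point in a ball of given radius
runif_ball <- function(radius) {
  v <- rnorm(3)
  v / sqrt(sum(v^2)) * radius * runif(1)^(1 / 3)
}

# a random unit vector perpendicular to v
pracma_nullspace_vec <- function(v) {
  u <- rnorm(3)
  u <- u - v * sum(u * v) / sum(v^2)
  u / sqrt(sum(u^2))
}

#' Simulate a full synthetic iEEG cohort
#'
#' Generates, for each subject: a continuous multichannel pink-noise
#' recording with calibrated high-gamma bursts injected per the configured
#' effect map, an event table (three task blocks of `trials_per_task` trials,
#' stimulus onsets spaced by the display duration plus a uniform 2000-2500 ms
#' inter-stimulus interval, response onset = stimulus onset + simulated RT),
#' and a channel table (electrode sites per ROI plus flagged channels).
#' Cohort-level outputs are the participants table, a streamline set over the
#' synthetic parcels, and a `truth` record (injected effects, channel map,
#' adjacency, expected connectivity edges) for parameter-recovery testing;
#' analysis functions never read `truth`.
#'
#' Burst amplitudes are calibrated so the *window-mean* percent-change
#' amplitude recovered by the default pipeline (including the common average
#' reference over the subject's included channels) equals the configured
#' effect size.
#'
#' @param config a [cohort_config()].
#' @param signals generate voltage recordings (TRUE) or only behavior,
#'   channels, streamlines and truth (FALSE; much faster when only the
#'   response-time models are of interest).
#' @return an `ieeg_cohort` list: `config`, `recordings`, `events`,
#'   `channels` (per-subject lists), `participants`, `streamlines`, `truth`.
#' @export
simulate_cohort <- function(config, signals = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  rate <- config$sampling_rate
  kernel <- design_demod_kernel(rate = rate)
  ns <- config$n_subjects
  with_local_seed(config$seed, {
    subj_int <- rnorm(ns, 0, config$rt_subject_sd)
    events <- vector("list", ns)
    channels <- vector("list", ns)
    recordings <- vector("list", ns)
    subj_ids <- paste0("sub-", seq_len(ns))

    # channel layout (identical structure across subjects)
    flag_names <- c("artifact", "soz", "spikes", "lesion")
    for (s in seq_len(ns)) {
      roi_rep <- rep(config$rois, each = config$channels_per_roi)
      ch <- data.frame(
        channel_id = sprintf("%s_%s_e%d", subj_ids[s], roi_rep,
                             sequence(rep(config$channels_per_roi,
                                          length(config$rois)))),
        roi = roi_rep, artifact = FALSE, soz = FALSE, spikes = FALSE,
        lesion = FALSE, stringsAsFactors = FALSE)
      if (config$n_flagged_per_subject > 0) {
        for (k in seq_len(config$n_flagged_per_subject)) {
          fl <- flag_names[(s + k - 2) %% 4 + 1]
          bad <- data.frame(channel_id = sprintf("%s_bad_e%d", subj_ids[s], k),
                            roi = config$rois[(k - 1) %% length(config$rois) + 1],
                            artifact = FALSE, soz = FALSE, spikes = FALSE,
                            lesion = FALSE, stringsAsFactors = FALSE)
          bad[[fl]] <- TRUE
          ch <- rbind(ch, bad)
        }
      }
      ch$include <- select_channels(ch)
      channels[[s]] <- ch
    }

    # events: consecutive task blocks, 5 s between blocks
    for (s in seq_len(ns)) {
      ev <- list()
      t_cursor <- 3000
      gid <- 0L
      for (task in config$tasks) {
        rts <- simulate_response_times(task, subj_int[s], config,
                                       config$trials_per_task)
        for (i in seq_len(config$trials_per_task)) {
          gid <- gid + 1L
          onset <- round(t_cursor)
          rt <- round(rts[i])
          ev[[gid]] <- data.frame(trial_id = gid, task = task,
                                  trial_number = i, stimulus_onset = onset,
                                  response_onset = onset + rt, rt = rt)
          t_cursor <- onset + config$stim_duration_ms +
            runif(1, config$isi_range_ms[1], config$isi_range_ms[2])
        }
        t_cursor <- t_cursor + 5000
      }
      events[[s]] <- do.call(rbind, ev)
    }

    if (signals) {
      floor_unit <- pink_band_floor(config$band, kernel)
      n_inc <- sum(channels[[1]]$include)
      # Bursts are injected zero-sum across the included channels (burst on
      # its own channel, exact counterweight spread over the others), so the
      # common average of the injected component vanishes and CAR passes it
      # through unchanged. The floor the effect is measured against is the
      # post-CAR pink floor, sqrt(1 - 1/n) of the raw floor; the incoherent
      # counterweights of the m-1 sibling channels of the same region feed a
      # small variance back, corrected by the feedback factor below.
      floor_amp <- floor_unit * config$noise_sd *
        if (n_inc >= 2) sqrt(1 - 1 / n_inc) else 1
      em <- config$effect_map
      for (s in seq_len(ns)) {
        ev <- events[[s]]
        ch <- channels[[s]]
        inc <- which(ch$include)
        n_samp <- max(ev$response_onset) + 2600
        n_samp <- max(n_samp, max(ev$stimulus_onset) + 1000)
        X <- matrix(0, n_samp, nrow(ch))
        for (c_i in seq_len(nrow(ch)))
          X[, c_i] <- pink_noise(n_samp, config$seed, s * 10000 + c_i,
                                 rate, config$noise_sd)
        if (!is.null(em) && nrow(em) && length(inc) >= 1) {
          S <- numeric(n_samp)  # running sum of injected bursts
          zs <- length(inc) >= 2
          own_gain <- if (zs) length(inc) / (length(inc) - 1) else 1
          for (e_i in seq_len(nrow(em))) {
            eff <- em[e_i, ]
            dur <- eff$window_end - eff$window_start
            prof <- unit_burst_profile(dur, config$band,
                                       config$burst_ramp_ms, kernel)
            tasks_on <- effect_tasks(eff$contrast, eff$direction,
                                     config$tasks)
            trials_on <- which(ev$task %in% tasks_on)
            cols <- which(ch$roi == eff$roi & ch$include)
            if (!length(trials_on) || !length(cols)) next
            s_eff <- burst_scale_for_gain(eff$amplitude_pct / 100,
                                          floor_amp, prof)
            feedback <- if (zs)
              1 + (length(cols) - 1) / (length(inc) - 1)^2 else 1
            scale <- s_eff / sqrt(feedback)
            len <- round(dur * rate / 1000)
            env <- burst_envelope(dur, config$burst_ramp_ms, rate)
            nbw <- length(trials_on) * length(cols)
            w <- matrix(cpp_gaussian_noise(len * nbw, config$seed,
                                           s * 100000 + e_i * 1000),
                        len, nbw)
            nb <- bandlimit_mat(w, config$band, rate)
            nb <- sweep(nb, 2, apply(nb, 2, sd), "/") * env * scale
            col_j <- 0L
            for (tr in trials_on) {
              lock_t <- if (eff$lock == "response") ev$response_onset[tr]
                        else ev$stimulus_onset[tr]
              i0 <- round(lock_t + eff$window_start) + 1
              idx <- i0:(i0 + len - 1)
              for (cc in cols) {
                col_j <- col_j + 1L
                X[idx, cc] <- X[idx, cc] + nb[, col_j] * own_gain
                S[idx] <- S[idx] + nb[, col_j]
              }
            }
          }
          if (zs && any(S != 0)) {
            counter <- S / (length(inc) - 1)
            for (cc in inc) X[, cc] <- X[, cc] - counter
          }
        }
        recordings[[s]] <- structure(
          list(samples = X, rate = rate, channel_ids = ch$channel_id,
               t0 = 0), class = "ieeg_recording")
      }
    }

    participants <- cbind(subject = subj_ids,
                          config$covariates[, c("age", "sex", "lesion",
                                                "n_asm")])
    rownames(participants) <- NULL
    parcels <- default_parcels()
    adj_spec <- default_adjacency_spec()
    adj_spec <- adj_spec[adj_spec[, 1] %in% parcels$label &
                           adj_spec[, 2] %in% parcels$label, , drop = FALSE]
    streamlines <- simulate_streamlines(
      parcels, adj_spec, n_per_pair = config$streamlines_per_pair,
      seed = config$seed + 7919, qa_low_frac = config$qa_low_frac)

    truth <- cohort_truth(config, subj_int, channels, adj_spec, parcels)
    structure(list(config = config, recordings = recordings, events = events,
                   channels = channels, participants = participants,
                   streamlines = streamlines, truth = truth),
              class = "ieeg_cohort")
  })
}

# tasks carrying the burst for a given contrast side
effect_tasks <- function(contrast, direction, tasks) {
  side <- if (contrast == "stroop_vs_reading") {
    if (direction > 0) "stroop" else c("congruent_reading",
                                       "incongruent_reading")
  } else {
    if (direction > 0) "incongruent_reading" else "congruent_reading"
  }
  intersect(side, tasks)
}

bandlimit_mat <- function(w, band, rate) {
  n <- nrow(w)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)
  mask <- f >= band[1] & f <= band[2]
  Re(mvfft(mvfft(w) * mask, inverse = TRUE)) / n
}

# Ground-truth record: never consumed by analysis functions.
cohort_truth <- function(config, subj_int, channels, adj_spec, parcels) {
  labels <- parcels$label
  adjacency <- matrix(FALSE, length(labels), length(labels),
                      dimnames = list(labels, labels))
  if (nrow(adj_spec)) for (k in seq_len(nrow(adj_spec))) {
    adjacency[adj_spec[k, 1], adj_spec[k, 2]] <- TRUE
    adjacency[adj_spec[k, 2], adj_spec[k, 1]] <- TRUE
  }
  starts <- window_starts()
  em <- config$effect_map
  edges <- list(); support <- list()
  if (!is.null(em) && nrow(em) && nrow(adj_spec)) {
    for (k in seq_len(nrow(adj_spec))) {
      a <- adj_spec[k, 1]; b <- adj_spec[k, 2]
      ea <- em[em$roi == a & em$lock == "response", ]
      eb <- em[em$roi == b & em$lock == "response", ]
      for (ia in seq_len(nrow(ea))) for (ib in seq_len(nrow(eb))) {
        if (ea$contrast[ia] != eb$contrast[ib] ||
            ea$direction[ia] != eb$direction[ib]) next
        contained <- starts[starts >= ea$window_start[ia] &
                              starts + 200 <= ea$window_end[ia] &
                              starts >= eb$window_start[ib] &
                              starts + 200 <= eb$window_end[ib]]
        overlap <- starts[starts < ea$window_end[ia] &
                            starts + 200 > ea$window_start[ia] &
                            starts < eb$window_end[ib] &
                            starts + 200 > eb$window_start[ib]]
        if (length(contained))
          edges[[length(edges) + 1]] <- data.frame(
            roi_a = a, roi_b = b, window_start = contained,
            direction = ea$direction[ia], contrast = ea$contrast[ia])
        if (length(overlap))
          support[[length(support) + 1]] <- data.frame(
            roi_a = a, roi_b = b, window_start = overlap,
            direction = ea$direction[ia], contrast = ea$contrast[ia])
      }
    }
  }
  list(subject_intercepts = subj_int,
       rt_means = config$rt_means,
       effect_map = em,
       channel_map = lapply(channels, function(ch)
         setNames(ch$roi, ch$channel_id)),
       adjacency = adjacency,
       edges = if (length(edges)) do.call(rbind, edges) else NULL,
       edge_support = if (length(support)) do.call(rbind, support) else NULL)
}

#' @export
print.ieeg_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic iEEG cohort: %d subjects, %d trials each, %s recordings\n",
    length(x$events), nrow(x$events[[1]]),
    if (is.null(x$recordings[[1]])) "no" else
      sprintf("%d-channel", ncol(x$recordings[[1]]$samples))))
  invisible(x)
}

#' Null high-gamma dataset for calibration studies
#'
#' Generates `n_trials` of pure pink-noise signal (no injected effect), runs
#' the standard demodulation and percent-change normalization, and returns
#' the response-locked analysis bins together with the baseline bins - the
#' inputs of [permutation_vs_baseline()]. Used to measure the empirical size
#' of the permutation test.
#'
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @param noise_sd pink-noise RMS, microvolts.
#' @param band,rate high-gamma band and sampling rate.
#' @param kernel demodulation kernel (default standard).
#' @return list with `task` (trials x 80 percent change), `baseline`
#'   (trials x 40 percent change).
#' @export
simulate_null_highgamma <- function(n_trials = 40, seed = 1, noise_sd = 25,
                                    band = c(70, 110), rate = 1000,
                                    kernel = NULL) {
  kernel <- kernel %||% design_demod_kernel(rate = rate)
  pad <- kernel$half_support
  # per-trial segment: response at local time 680 ms, spans the [-600, 200]
  # analysis window and the [1800, 2200] baseline, plus kernel margins
  resp_local <- 600 + pad
  seg_len <- resp_local + 2200 + pad + 10
  x <- pink_noise(seg_len * n_trials, seed, 0, rate, noise_sd)
  rel_task <- round((seq(-600, 190, by = 10) + 5) * rate / 1000)
  rel_base <- round((seq(1800, 2190, by = 10) + 5) * rate / 1000)
  freqs <- seq(band[1], band[2], by = 5)
  offs <- (seq_len(n_trials) - 1) * seg_len + resp_local
  centers <- as.vector(outer(c(rel_task, rel_base), offs, "+"))
  amp <- rowMeans(demod_amplitude_at(x, centers, kernel, freqs))
  A <- matrix(amp, ncol = n_trials)  # (80 + 40) x trials
  task_amp <- t(A[seq_along(rel_task), , drop = FALSE])
  base_amp <- t(A[length(rel_task) + seq_along(rel_base), , drop = FALSE])
  b <- rowMeans(base_amp)
  list(task = percent_change(task_amp, b),
       baseline = percent_change(base_amp, b))
}
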