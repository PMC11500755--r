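# High-level drivers chaining the preprocessing, time-frequency, and
# statistics modules over a whole cohort. Analysis functions consume only
# recordings/events/channels/streamlines - never the generator's truth.

#' Cohort-level high-gamma percent-change series
#'
#' For every subject: select channels, apply the common average reference
#' over the included channels, demodulate the high-gamma band at the 10-ms
#' bin centers of the event-locked analysis window and of the 1800-2200 ms
#' post-response baseline, normalize to percent change against each trial's
#' baseline mean, and average channels into regions (subject-first, so
#' electrode-rich subjects do not dominate). Trials are then pooled across
#' subjects per region.
#'
#' @param cohort an `ieeg_cohort` (or any list with `recordings`, `events`,
#'   `channels`, `participants` of the same shape).
#' @param rois restrict the computation to these regions (default: all).
#' @param lock `"response"` (window -600..200 ms) or `"stimulus"`
#'   (-200..600 ms); the baseline is always response-locked.
#' @param min_sites cohort-wide minimum sites per region (default 5).
#' @param kernel demodulation kernel (default: standard 31.6-ms kernel).
#' @param band high-gamma band (default from the cohort config, else
#'   70-110 Hz).
#' @param car_mode reference mode for [common_average_reference()].
#' @return list with `roi_series` (per region: `pct` trials x 80,
#'   `baseline` trials x 40, `meta` data.frame subject/task/trial_number/rt),
#'   `bin_starts`, `lock`, `site_counts`.
#' @export
cohort_highgamma <- function(cohort, rois = NULL,
                             lock = c("response", "stimulus"),
                             min_sites = 5, kernel = NULL, band = NULL,
                             car_mode = "included") {
  lock <- match.arg(lock)
  rate <- cohort$recordings[[1]]$rate
  kernel <- kernel %||% design_demod_kernel(rate = rate)
  band <- band %||% cohort$config$band %||% c(70, 110)
  freqs <- seq(band[1], band[2], by = 5)
  win <- if (lock == "response") c(-600, 200) else c(-200, 600)
  bin_starts <- seq(win[1], win[2] - 10, by = 10)
  rel_task <- bin_starts + 5
  rel_base <- seq(1800, 2190, by = 10) + 5

  # cohort-wide included site counts per region (inclusion rule)
  inc_rois <- unlist(lapply(cohort$channels, function(ch)
    ch$roi[select_channels(ch)]))
  site_counts <- table(inc_rois)
  keep_rois <- names(site_counts)[site_counts >= min_sites]
  if (!is.null(rois)) keep_rois <- intersect(keep_rois, rois)

  acc <- list()
  for (s in seq_along(cohort$recordings)) {
    rec <- cohort$recordings[[s]]
    ch <- cohort$channels[[s]]
    ev <- cohort$events[[s]]
    include <- select_channels(ch)
    ref <- rowMeans(rec$samples[, if (car_mode == "included") include else
      rep(TRUE, ncol(rec$samples)), drop = FALSE])
    locks <- if (lock == "response") ev$response_onset else ev$stimulus_onset
    task_centers <- as.vector(outer(rel_task, locks, "+"))
    base_centers <- as.vector(outer(rel_base, ev$response_onset, "+"))
    centers <- round(c(task_centers, base_centers)) + 1
    nt <- nrow(ev); nb <- length(rel_task); nbl <- length(rel_base)
    use_cols <- which(include & ch$roi %in% keep_rois)
    if (!length(use_cols)) next
    pct_epochs <- array(NA_real_, c(nt, length(use_cols), nb))
    base_epochs <- array(NA_real_, c(nt, length(use_cols), nbl))
    for (k in seq_along(use_cols)) {
      x <- rec$samples[, use_cols[k]] - ref
      amp <- rowMeans(demod_amplitude_at(x, centers, kernel, freqs))
      task_amp <- matrix(amp[seq_len(nb * nt)], nb, nt)
      base_amp <- matrix(amp[nb * nt + seq_len(nbl * nt)], nbl, nt)
      bmean <- colMeans(base_amp)
      pct_epochs[, k, ] <- percent_change(t(task_amp), bmean)
      base_epochs[, k, ] <- percent_change(t(base_amp), bmean)
    }
    roi_mats <- roi_aggregate(pct_epochs, ch[use_cols, , drop = FALSE],
                              min_sites = 0)
    roi_base <- roi_aggregate(base_epochs, ch[use_cols, , drop = FALSE],
                              min_sites = 0)
    subj <- cohort$participants$subject[s]
    meta <- data.frame(subject = subj, task = ev$task,
                       trial_number = ev$trial_number, rt = ev$rt)
    for (r in names(roi_mats)) {
      if (is.null(acc[[r]]))
        acc[[r]] <- list(pct = NULL, baseline = NULL, meta = NULL)
      acc[[r]]$pct <- rbind(acc[[r]]$pct, roi_mats[[r]])
      acc[[r]]$baseline <- rbind(acc[[r]]$baseline, roi_base[[r]])
      acc[[r]]$meta <- rbind(acc[[r]]$meta, meta)
    }
  }
  list(roi_series = acc, bin_starts = bin_starts, lock = lock,
       site_counts = site_counts)
}

#' Sliding-window mixed-model contrasts for a cohort
#'
#' Chains [build_window_table()], [fit_all_windows()] and
#' [fdr_across_tests()] over the output of [cohort_highgamma()].
#'
#' @param hg a [cohort_highgamma()] result (response-locked).
#' @param participants cohort participants table.
#' @param contrast task contrast.
#' @param q FDR level over all region x window tests.
#' @param span,win,step sliding-window scheme.
#' @return list: `window_table`, `effects` (flagged).
#' @export
run_window_contrasts <- function(hg, participants,
                                 contrast = "stroop_vs_reading", q = 0.05,
                                 span = c(-600, 200), win = 200, step = 50) {
  wt <- build_window_table(hg$roi_series, participants,
                           bin_starts = hg$bin_starts, contrast = contrast,
                           span = span, win = win, step = step)
  effects <- fdr_across_tests(fit_all_windows(wt), q)
  list(window_table = wt, effects = effects)
}

#' Streamline-gated connectivity atlas for a cohort
#'
#' Filters the cohort's streamlines, derives region adjacency from surviving
#' endpoints, and applies the simultaneity-plus-adjacency edge rule to the
#' flagged mixed-model effects.
#'
#' @param cohort an `ieeg_cohort`.
#' @param effects flagged effects from [run_window_contrasts()].
#' @param filter_cfg a [filter_config()]; defaults include the standard
#'   exclusion masks.
#' @param parcels parcel layout (default synthetic centroids).
#' @param tolerance endpoint tolerance, mm.
#' @param sig_col significance column gating edges.
#' @return list: `streamlines` (filtered), `adjacency`, `edges`.
#' @export
build_atlas <- function(cohort, effects,
                        filter_cfg = filter_config(
                          exclusion_regions = default_exclusion_regions()),
                        parcels = default_parcels(), tolerance = 3,
                        sig_col = "q_significant") {
  kept <- filter_streamlines(cohort$streamlines, filter_cfg)
  adjacency <- endpoint_adjacency(kept, parcels, tolerance)
  edges <- task_preferential_edges(effects, adjacency, sig_col)
  list(streamlines = kept, adjacency = adjacency, edges = edges)
}

#' Full analysis pipeline on one cohort
#'
#' Recording-to-atlas convenience wrapper: high-gamma series, mixed-model
#' window contrasts, and the streamline-gated edge set.
#'
#' @inheritParams cohort_highgamma
#' @inheritParams run_window_contrasts
#' @return list: `hg`, `window_table`, `effects`, `atlas`.
#' @export
run_pipeline <- function(cohort, rois = NULL,
                         contrast = "stroop_vs_reading", q = 0.05,
                         min_sites = 5) {
  hg <- cohort_highgamma(cohort, rois = rois, min_sites = min_sites)
  wc <- run_window_contrasts(hg, cohort$participants, contrast, q)
  atlas <- build_atlas(cohort, wc$effects)
  list(hg = hg, window_table = wc$window_table, effects = wc$effects,
       atlas = atlas)
}

#' Edge-recovery metrics against a known truth
#'
#' Sensitivity: fraction of ground-truth edges (region pair x window x
#' direction, windows fully contained in both injected effect windows)
#' present in the emitted edge set. False-edge rate: fraction of emitted
#' edges with no support in the truth (neither region pair x window overlaps
#' an injected effect with that direction).
#'
#' @param edges emitted [task_preferential_edges()] table.
#' @param truth the cohort generator's `truth` record.
#' @return list: `sensitivity`, `false_edge_rate`, `n_truth`, `n_emitted`.
#' @export
evaluate_edges <- function(edges, truth) {
  key <- function(d) {
    pref <- if (!is.null(d$preference)) d$preference
            else ifelse(d$direction > 0, "stroop", "reading")
    a <- pmin(d$roi_a, d$roi_b); b <- pmax(d$roi_a, d$roi_b)
    paste(a, b, d$window_start, pref)
  }
  tk <- if (!is.null(truth$edges)) key(truth$edges) else character(0)
  sk <- if (!is.null(truth$edge_support)) key(truth$edge_support) else
    character(0)
  ek <- if (nrow(edges)) key(edges) else character(0)
  list(sensitivity = if (length(tk)) mean(tk %in% ek) else NA_real_,
       false_edge_rate = if (length(ek)) mean(!ek %in% sk) else 0,
       n_truth = length(tk), n_emitted = length(ek))
}
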