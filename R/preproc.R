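#' Channel inclusion mask
#'
#' A channel is analyzed only if none of its exclusion flags is set: artifact
#' contamination, seizure-onset zone, interictal spike discharges, or an
#' MRI-visible lesion.
#'
#' @param channels data.frame with columns `channel_id` plus logical/0-1 flag
#'   columns `artifact`, `soz`, `spikes`, `lesion`.
#' @return logical vector, TRUE where the channel is kept.
#' @export
select_channels <- function(channels) {
  if (!is.data.frame(channels) || nrow(channels) == 0)
    stop("channels table must be a non-empty data.frame")
  flags <- c("artifact", "soz", "spikes", "lesion")
  missing <- setdiff(flags, names(channels))
  if (length(missing)) stop("channels table lacks flag column(s): ",
                            paste(missing, collapse = ", "))
  fm <- sapply(flags, function(f) {
    v <- channels[[f]]
    if (is.logical(v)) return(v)
    if (is.numeric(v) && all(v %in% c(0, 1))) return(v == 1)
    stop("flag column '", f, "' must be logical or 0/1")
  })
  fm <- matrix(fm, nrow = nrow(channels))
  rowSums(fm) == 0
}

#' Common average reference
#'
#' Re-references a multichannel recording by subtracting, at every sample, the
#' mean voltage across the reference channels. By default the reference is
#' computed from (and applied to) included channels only, so that artifactual
#' or epileptic channels cannot contaminate it; `mode = "all"` reproduces a
#' reference over every channel. Excluded channels are passed through
#' unreferenced and flagged in the `car_referenced` attribute.
#'
#' @param x time x channels voltage matrix.
#' @param include logical per-channel mask (default: all included).
#' @param mode `"included"` or `"all"`: which channels enter the reference.
#' @return matrix of the same shape; attribute `car_referenced` marks the
#'   channels from which the mean was removed.
#' @export
common_average_reference <- function(x, include = NULL,
                                     mode = c("included", "all")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(x))
  include <- include %||% rep(TRUE, ncol(x))
  if (length(include) != ncol(x))
    stop("include mask length must match the number of channels")
  if (sum(include) < 2)
    stop("common average reference needs at least 2 included channels")
  ref_cols <- if (mode == "included") include else rep(TRUE, ncol(x))
  ref <- rowMeans(x[, ref_cols, drop = FALSE])
  out <- x
  out[, include] <- x[, include, drop = FALSE] - ref
  attr(out, "car_referenced") <- include
  out
}

#' Event-locked epoching on a fixed bin grid
#'
#' Cuts a per-channel series into trials x channels x bins around each
#' event's lock time. Bins are half-open `[t, t + bin)` ms relative to the
#' lock; a 1000-Hz voltage series is averaged within each bin, while a series
#' already sampled on the bin grid is picked up directly. The standard
#' analysis windows are `[-200, 600]` ms stimulus-locked and `[-600, 200]` ms
#' response-locked, 80 bins each.
#'
#' @param x time x channels matrix sampled at `rate` Hz, first sample at
#'   `t0` ms.
#' @param rate sampling rate of `x` in Hz.
#' @param events data.frame with `stimulus_onset` and `response_onset` (ms).
#' @param lock `"stimulus"` or `"response"`.
#' @param window numeric length 2: ms relative to lock; must be a whole
#'   number of bins.
#' @param bin bin width in ms (default 10).
#' @param t0 time of the first sample of `x`, ms.
#' @return array trials x channels x bins with attributes `lock` and
#'   `bin_starts` (ms relative to lock).
#' @export
epoch <- function(x, rate, events, lock = c("stimulus", "response"),
                  window, bin = 10, t0 = 0) {
  lock <- match.arg(lock)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  span <- window[2] - window[1]
  if (span <= 0 || span %% bin != 0)
    stop("window must span a positive whole number of ", bin, "-ms bins")
  nb <- span / bin
  locks <- if (lock == "stimulus") events$stimulus_onset else events$response_onset
  n <- nrow(x)
  spb <- rate * bin / 1000  # samples per bin
  out <- array(NA_real_, c(length(locks), ncol(x), nb))
  for (i in seq_along(locks)) {
    t_start <- locks[i] + window[1]
    s0 <- (t_start - t0) * rate / 1000 + 1
    s1 <- s0 + nb * spb - 1
    if (s0 < 1 || s1 > n)
      stop("epoch window exceeds recording bounds for trial ", i)
    seg <- x[seq(s0, s1), , drop = FALSE]
    if (spb == 1) {
      out[i, , ] <- t(seg)
    } else {
      grp <- rep(seq_len(nb), each = spb)
      for (ch in seq_len(ncol(x)))
        out[i, ch, ] <- tapply(seg[, ch], grp, mean)
    }
  }
  attr(out, "lock") <- lock
  attr(out, "bin_starts") <- seq(window[1], window[2] - bin, by = bin)
  out
}

#' Baseline mean amplitude
#'
#' Per-trial, per-channel mean amplitude over the baseline epoch (the 40
#' 10-ms bins between 1800 and 2200 ms post-response onset, which fall in the
#' quiet stretch between a trial's response and the next stimulus).
#'
#' @param epochs trials x channels x bins amplitude array (e.g. from
#'   [epoch()] of a demodulated amplitude series over `[1800, 2200]` ms
#'   response-locked), or a trials x bins matrix for a single channel.
#' @return trials x channels matrix of baseline means.
#' @export
baseline_mean <- function(epochs) {
  if (is.matrix(epochs)) epochs <- array(epochs, c(nrow(epochs), 1, ncol(epochs)))
  stopifnot(length(dim(epochs)) == 3)
  apply(epochs, c(1, 2), mean)
}

#' Aggregate channel epochs into ROI series
#'
#' Averages percent-change epochs across a region's included channels, per
#' trial and bin. Regions whose cohort-wide site count falls below
#' `min_sites` are dropped (the study's inclusion rule of at least 5 sites
#' per analyzed region).
#'
#' @param epochs trials x channels x bins array for one subject.
#' @param channels channel table for the same channels (column `roi`, and
#'   optionally the exclusion flags consumed by [select_channels()]).
#' @param min_sites minimum cohort-wide sites per ROI (default 5).
#' @param site_counts optional named cohort-wide site counts per ROI; when
#'   NULL, this subject's own included-channel counts are used.
#' @return named list of trials x bins matrices, one per surviving ROI.
#' @export
roi_aggregate <- function(epochs, channels, min_sites = 5,
                          site_counts = NULL) {
  stopifnot(length(dim(epochs)) == 3, dim(epochs)[2] == nrow(channels))
  include <- if (all(c("artifact", "soz", "spikes", "lesion") %in%
                       names(channels))) select_channels(channels)
             else rep(TRUE, nrow(channels))
  rois <- unique(channels$roi[include & channels$roi != "unassigned"])
  if (is.null(site_counts))
    site_counts <- table(channels$roi[include])
  out <- list()
  for (r in rois) {
    if (is.na(site_counts[r]) || site_counts[r] < min_sites) next
    idx <- which(include & channels$roi == r)
    m <- epochs[, idx, , drop = FALSE]
    out[[r]] <- apply(m, c(1, 3), mean)
  }
  out
}
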