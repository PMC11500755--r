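#' Permutation-test configuration
#'
#' @param n_permutations Monte-Carlo permutations (default 1000).
#' @param alpha two-sided per-bin significance level (default 0.05).
#' @param fdr_q Benjamini-Hochberg level applied across the 80 analysis bins.
#' @param min_duration_ms minimum run of consecutive significant bins
#'   (default 40 ms, i.e. three high-gamma cycles); must be a multiple of the
#'   10-ms bin.
#' @param seed optional seed for the permutation draws.
#' @param two_sided `"abs"`: p = P(|perm| >= |obs|) (add-one estimator);
#'   `"twice_min"`: twice the smaller tail probability, capped at 1.
#' @export
perm_config <- function(n_permutations = 1000, alpha = 0.05, fdr_q = 0.05,
                        min_duration_ms = 40, seed = NULL,
                        two_sided = c("abs", "twice_min")) {
  stopifnot(n_permutations >= 1, alpha > 0, alpha < 1, fdr_q > 0, fdr_q <= 1,
            min_duration_ms %% 10 == 0)
  structure(list(n_permutations = as.integer(n_permutations), alpha = alpha,
                 fdr_q = fdr_q, min_duration_ms = min_duration_ms,
                 seed = seed, two_sided = match.arg(two_sided)),
            class = "perm_config")
}

two_sided_p <- function(perm_stats, obs, n, mode) {
  # tie-tolerant comparisons: a permuted statistic equal to the observed one
  # up to floating-point noise counts as at least as extreme (conservative)
  tol <- 1e-9 * pmax(abs(obs), .Machine$double.eps)
  R <- nrow(perm_stats)
  if (mode == "abs") {
    thr <- rep(abs(obs) - tol, each = R)
    p <- (1 + colSums(abs(perm_stats) >= thr)) / (n + 1)
  } else {
    hi <- (1 + colSums(perm_stats >= rep(obs - tol, each = R))) / (n + 1)
    lo <- (1 + colSums(perm_stats <= rep(obs + tol, each = R))) / (n + 1)
    p <- pmin(1, 2 * pmin(hi, lo))
  }
  p
}

#' Per-bin permutation test of task amplitude against baseline
#'
#' Tests, for each 10-ms bin, the null hypothesis that the mean task-related
#' percent-change amplitude matches the baseline mean. The permutation unit
#' is the trial: each trial's tested-bin value is paired with one randomly
#' selected baseline-bin value from the same trial, and a permutation
#' exchanges the two (equivalently, flips the sign of their difference).
#' This within-trial scheme respects the trial structure and yields an exact
#' test under exchangeability. The statistic is the across-trial mean
#' difference in percent-change units.
#'
#' @param task_bins trials x bins matrix of percent change in the analysis
#'   window.
#' @param baseline_bins trials x bins matrix of percent change in the
#'   baseline window (same trials).
#' @param cfg a [perm_config()].
#' @return list: `p` (per-bin two-sided p-values), `observed` (per-bin mean
#'   difference), `sign`, and `alpha_mask` (p < alpha).
#' @export
permutation_vs_baseline <- function(task_bins, baseline_bins,
                                    cfg = perm_config()) {
  task_bins <- as.matrix(task_bins); baseline_bins <- as.matrix(baseline_bins)
  nt <- nrow(task_bins)
  if (nt < 2) stop("need at least 2 trials")
  if (nrow(baseline_bins) != nt)
    stop("task and baseline must contain the same trials")
  nb <- ncol(task_bins)
  with_local_seed(cfg$seed, {
    partner <- matrix(sample.int(ncol(baseline_bins), nt * nb, replace = TRUE),
                      nt, nb)
    D <- task_bins - matrix(baseline_bins[cbind(rep(seq_len(nt), nb),
                                                as.vector(partner))], nt, nb)
    obs <- colMeans(D)
    S <- matrix(sample(c(-1, 1), cfg$n_permutations * nt, replace = TRUE),
                cfg$n_permutations, nt)
    perm_stats <- (S %*% D) / nt
    p <- two_sided_p(perm_stats, obs, cfg$n_permutations, cfg$two_sided)
    list(p = p, observed = obs, sign = sign(obs), alpha_mask = p < cfg$alpha)
  })
}

#' Per-bin permutation contrast between two task conditions
#'
#' Label-permutation test of the across-trial mean percent-change difference
#' between two conditions, per bin, with a peak summary (largest absolute
#' mean difference and its bin).
#'
#' @param series_a,series_b trials x bins percent-change matrices for the two
#'   conditions (same bin axis).
#' @param cfg a [perm_config()].
#' @param bin_times optional bin time labels (ms) for the peak summary.
#' @return list: `p`, `observed` (mean a - mean b per bin), `sign`,
#'   `alpha_mask`, and `peak` (list: difference, bin index, time).
#' @export
permutation_task_contrast <- function(series_a, series_b,
                                      cfg = perm_config(),
                                      bin_times = NULL) {
  series_a <- as.matrix(series_a); series_b <- as.matrix(series_b)
  na <- nrow(series_a); nb_ <- nrow(series_b)
  if (na < 2 || nb_ < 2) stop("each condition needs at least 2 trials")
  if (ncol(series_a) != ncol(series_b)) stop("bin axes differ")
  pooled <- rbind(series_a, series_b)
  n <- na + nb_
  obs <- colMeans(series_a) - colMeans(series_b)
  with_local_seed(cfg$seed, {
    perm_stats <- matrix(0, cfg$n_permutations, ncol(pooled))
    for (r in seq_len(cfg$n_permutations)) {
      idx <- sample.int(n, na)
      perm_stats[r, ] <- colMeans(pooled[idx, , drop = FALSE]) -
        colMeans(pooled[-idx, , drop = FALSE])
    }
    p <- two_sided_p(perm_stats, obs, cfg$n_permutations, cfg$two_sided)
    pk <- which.max(abs(obs))
    list(p = p, observed = obs, sign = sign(obs), alpha_mask = p < cfg$alpha,
         peak = list(difference = obs[pk], bin = pk,
                     time_ms = if (!is.null(bin_times)) bin_times[pk] else NA))
  })
}

#' Benjamini-Hochberg significance mask
#'
#' Step-up FDR control at level `q` across a family of p-values (in this
#' pipeline: the 80 bins of one region's analysis window, or the 364
#' region-by-window mixed-model tests).
#'
#' @param pvals numeric p-values in (0, 1].
#' @param q FDR level.
#' @return logical mask, TRUE where the hypothesis is rejected.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) return(logical(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH") <= q
}

#' Duration criterion on a per-bin significance mask
#'
#' Keeps only runs of at least `min_duration_ms / bin_ms` consecutive
#' significant bins (default: 40 ms, three high-gamma oscillatory cycles)
#' and reports the surviving intervals.
#'
#' @param mask logical per-bin significance flags on a regular grid.
#' @param min_duration_ms minimum run duration; must be a multiple of
#'   `bin_ms`.
#' @param bin_ms bin width (default 10).
#' @param bin_starts optional bin start times for interval labels.
#' @return list: `mask` (filtered), `intervals` (data.frame start_bin,
#'   end_bin, start_ms, end_ms, duration_ms).
#' @export
duration_filter <- function(mask, min_duration_ms = 40, bin_ms = 10,
                            bin_starts = NULL) {
  if (min_duration_ms %% bin_ms != 0)
    stop("min_duration_ms must be a multiple of the bin width")
  min_bins <- min_duration_ms / bin_ms
  mask <- as.logical(mask)
  out <- logical(length(mask))
  iv <- list()
  if (length(mask)) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (r$values[k] && r$lengths[k] >= min_bins) {
        out[starts[k]:ends[k]] <- TRUE
        iv[[length(iv) + 1]] <- c(starts[k], ends[k])
      }
    }
  }
  intervals <- if (length(iv)) {
    m <- do.call(rbind, iv)
    d <- data.frame(start_bin = m[, 1], end_bin = m[, 2])
    if (!is.null(bin_starts)) {
      d$start_ms <- bin_starts[d$start_bin]
      d$end_ms <- bin_starts[d$end_bin] + bin_ms
    }
    d$duration_ms <- (d$end_bin - d$start_bin + 1) * bin_ms
    d
  } else data.frame(start_bin = integer(), end_bin = integer(),
                    duration_ms = numeric())
  list(mask = out, intervals = intervals)
}

#' Full per-region bin-wise test battery
#'
#' Convenience wrapper chaining [permutation_vs_baseline()] (or a task
#' contrast), [bh_fdr()] across the window's bins, and [duration_filter()],
#' returning the per-bin result table.
#'
#' @param task_bins,baseline_bins trials x bins percent-change matrices.
#' @param cfg a [perm_config()].
#' @param bin_starts bin start times (ms relative to lock).
#' @return data.frame: bin_ms, statistic, p, fdr_significant,
#'   duration_passed, sign.
#' @export
bin_test_table <- function(task_bins, baseline_bins, cfg = perm_config(),
                           bin_starts = NULL) {
  res <- permutation_vs_baseline(task_bins, baseline_bins, cfg)
  fdr <- bh_fdr(res$p, cfg$fdr_q)
  dur <- duration_filter(fdr, cfg$min_duration_ms, bin_starts = bin_starts)
  data.frame(
    bin_ms = bin_starts %||% seq_along(res$p),
    statistic = res$observed, p = res$p, fdr_significant = fdr,
    duration_passed = dur$mask, sign = res$sign)
}
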