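# Independent oracle implementations used to cross-check the package's fast
# paths: a filter-based Gabor demodulator, brute-force Benjamini-Hochberg,
# exhaustive permutation tests, and a triple-loop edge rule.

# Demodulate by full-signal complex mixing followed by FIR convolution
# (stats::filter), then sample; independent of the slice-matrix route.
demod_oracle <- function(x, rate, freqs, kernel, centers) {
  t <- (seq_along(x) - 1) / rate
  sapply(freqs, function(f) {
    z <- x * exp(-2i * pi * f * t)
    re <- stats::filter(Re(z), kernel$taps, method = "convolution", sides = 2)
    im <- stats::filter(Im(z), kernel$taps, method = "convolution", sides = 2)
    2 * Mod(complex(real = re[centers], imaginary = im[centers]))
  })
}

# Benjamini-Hochberg step-up straight from the definition: largest k with
# p_(k) <= k * q / m; reject the k smallest p-values.
bh_oracle <- function(pvals, q) {
  m <- length(pvals)
  if (m == 0) return(logical(0))
  o <- order(pvals)
  ps <- pvals[o]
  k <- max(c(0, which(ps <= seq_len(m) * q / m)))
  out <- logical(m)
  if (k > 0) out[o[seq_len(k)]] <- TRUE
  out
}

# Exhaustive paired sign-flip p-value (two-sided, |stat| convention) for the
# differences d, including the identity assignment as the permutation test
# does through its add-one estimator.
exhaustive_signflip_p <- function(d) {
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  stats <- abs(signs %*% d) / n
  mean(stats >= abs(mean(d)) - 1e-12)
}

# Exhaustive two-group label permutation p-value for a single bin.
exhaustive_label_p <- function(a, b) {
  pooled <- c(a, b)
  idx <- utils::combn(length(pooled), length(a))
  stats <- apply(idx, 2, function(i) mean(pooled[i]) - mean(pooled[-i]))
  obs <- mean(a) - mean(b)
  mean(abs(stats) >= abs(obs) - 1e-12)
}

# Brute-force simultaneity-plus-adjacency rule: triple loop over windows and
# region pairs.
edge_oracle <- function(effects, adjacency, sig_col = "q_significant") {
  out <- list()
  for (w in sort(unique(effects$window_start))) {
    ew <- effects[effects$window_start == w, ]
    rois <- ew$roi
    for (i in seq_along(rois)) for (j in seq_along(rois)) {
      if (i >= j) next
      a <- rois[i]; b <- rois[j]
      if (!ew[[sig_col]][i] || !ew[[sig_col]][j]) next
      if (!adjacency[a, b]) next
      if (sign(ew$coefficient[i]) != sign(ew$coefficient[j])) next
      out[[length(out) + 1]] <- paste(min(a, b), max(a, b), w,
                                      sign(ew$coefficient[i]))
    }
  }
  sort(unlist(out))
}

# Compact cohort used by several tests: two effect regions, full trial
# counts, everything else default.
small_cohort_config <- function(seed = 1, ...) {
  cohort_config(
    effect_map = rbind(
      effect_spec("LOG_left", direction = -1, amplitude_pct = 16.6,
                  window = c(-500, -300)),
      effect_spec("pFG_left", direction = -1, amplitude_pct = 14.0,
                  window = c(-500, -300))),
    seed = seed, ...)
}
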