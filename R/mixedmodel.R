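#' Number of sliding windows over a span
#'
#' `floor((span - win) / step) + 1`; the standard response-locked scheme
#' (span -600..200 ms, 200-ms windows, 50-ms step) yields 13 windows, hence
#' 364 tests over 28 regions.
#'
#' @param span numeric length 2, ms.
#' @param win window length, ms.
#' @param step step, ms.
#' @export
count_windows <- function(span = c(-600, 200), win = 200, step = 50) {
  if (step <= 0) stop("step must be positive")
  len <- span[2] - span[1]
  if (win > len) stop("window longer than span")
  floor((len - win) / step) + 1
}

#' Window start times for the sliding scheme
#' @inheritParams count_windows
#' @return numeric vector of window starts (a window labeled `-600` covers
#'   -600..-400 ms).
#' @export
window_starts <- function(span = c(-600, 200), win = 200, step = 50) {
  seq(span[1], by = step, length.out = count_windows(span, win, step))
}

#' Trial-level sliding-window amplitude table
#'
#' One row per (subject, region, trial, window): the mean percent-change
#' amplitude over the window's 10-ms bins, the task indicator for the
#' requested contrast (Stroop = 1 against pooled word reading, or
#' incongruent = 1 against congruent), trial number, and the subject's
#' clinical covariates (age, sex with female = 1, lesion, antiseizure
#' medication count).
#'
#' @param roi_series named list (per region) of lists with `pct` (pooled
#'   trials x bins percent-change matrix) and `meta` (data.frame subject,
#'   task, trial_number), as produced by [cohort_highgamma()].
#' @param participants data.frame with subject, age, sex, lesion, n_asm.
#' @param bin_starts bin start times of the series' bin axis, ms.
#' @param contrast `"stroop_vs_reading"` or `"incongruent_vs_congruent"`.
#' @param span,win,step sliding-window scheme (defaults: -600..200, 200, 50).
#' @return data.frame, one row per subject x region x trial x window.
#' @export
build_window_table <- function(roi_series, participants,
                               bin_starts = seq(-600, 190, by = 10),
                               contrast = c("stroop_vs_reading",
                                            "incongruent_vs_congruent"),
                               span = c(-600, 200), win = 200, step = 50) {
  contrast <- match.arg(contrast)
  starts <- window_starts(span, win, step)
  need <- c("age", "sex", "lesion", "n_asm")
  for (f in need)
    if (any(is.na(participants[[f]])) || is.null(participants[[f]]))
      stop("missing covariate '", f, "' for subject ",
           paste(participants$subject[is.na(participants[[f]])],
                 collapse = ", "))
  out <- list()
  for (r in names(roi_series)) {
    pct <- roi_series[[r]]$pct
    meta <- roi_series[[r]]$meta
    keep <- contrast_rows(meta$task, contrast)
    pct <- pct[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
    task01 <- contrast_coding(meta$task, contrast)
    wmeans <- sapply(starts, function(w0) {
      cols <- which(bin_starts >= w0 & bin_starts < w0 + win)
      rowMeans(pct[, cols, drop = FALSE])
    })
    cov <- participants[match(meta$subject, participants$subject), need]
    for (wi in seq_along(starts)) {
      out[[length(out) + 1]] <- data.frame(
        subject = meta$subject, roi = r, trial = meta$trial_number,
        window_start = starts[wi], amplitude = wmeans[, wi], task = task01,
        trial_number = meta$trial_number, cov, row.names = NULL)
    }
  }
  do.call(rbind, out)
}

contrast_rows <- function(task, contrast) {
  if (contrast == "stroop_vs_reading")
    task %in% c("stroop", "congruent_reading", "incongruent_reading")
  else task %in% c("congruent_reading", "incongruent_reading")
}

contrast_coding <- function(task, contrast) {
  if (contrast == "stroop_vs_reading") as.numeric(task == "stroop")
  else as.numeric(task == "incongruent_reading")
}

#' Mixed-model task contrast for one region x window cell
#'
#' Fits `amplitude ~ task + trial_number + age + sex + lesion + n_asm +
#' (1 | subject)` by REML (falling back to ML if REML fails) and returns the
#' Wald test of the task coefficient with DF = n_obs - n_fixed. Covariates
#' that are constant or collinear in this cell are dropped with a warning and
#' the model refit.
#'
#' @param df rows of a [build_window_table()] for one region and window.
#' @param covariates fixed-effect covariates besides the task indicator.
#' @return one-row data.frame: roi, window_start, coefficient, se, t, df, p,
#'   ci_lo, ci_hi, sign, n_obs, dropped (comma-separated dropped covariates).
#' @export
fit_window_model <- function(df, covariates = c("trial_number", "age", "sex",
                                                "lesion", "n_asm")) {
  if (length(unique(df$subject)) < 2) stop("need at least 2 subjects")
  if (min(table(df$task)) < 2) stop("need at least 2 observations per task")
  fixed <- c("task", covariates)
  repeat {
    X <- cbind("(Intercept)" = 1, as.matrix(df[fixed]))
    qrX <- qr(X)
    if (qrX$rank == ncol(X)) break
    drop_idx <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    bad <- setdiff(colnames(X)[drop_idx], c("(Intercept)", "task"))
    if (!length(bad)) {
      # pivoting blamed the intercept or task; the real culprit is an
      # aliased covariate - a constant one if present, else the last
      const <- intersect(fixed, setdiff(fixed, "task"))
      const <- const[vapply(const, function(cv)
        length(unique(df[[cv]])) == 1, logical(1))]
      cand <- setdiff(fixed, "task")
      if (length(const)) bad <- const[1]
      else if (length(cand)) bad <- cand[length(cand)]
      else stop("task indicator itself is confounded")
    }
    warning("dropping singular covariate(s): ", paste(bad, collapse = ", "),
            call. = FALSE)
    fixed <- setdiff(fixed, bad)
  }
  dropped <- setdiff(c("task", covariates), fixed)
  form <- stats::as.formula(paste("amplitude ~",
                                  paste(fixed, collapse = " + "),
                                  "+ (1 | subject)"))
  fit <- tryCatch(
    lme4::lmer(form, data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    error = function(e)
      lme4::lmer(form, data = df, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)))
  wald_row(fit, "task", nrow(df), length(fixed) + 1,
           roi = df$roi[1], window_start = df$window_start[1],
           dropped = dropped)
}

wald_row <- function(fit, term, n_obs, n_fixed, roi = NA, window_start = NA,
                     dropped = character(0)) {
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  est <- cf[[term]]
  s <- se[[which(names(cf) == term)]]
  df_resid <- n_obs - n_fixed
  tval <- est / s
  p <- 2 * pt(-abs(tval), df_resid)
  ci <- est + c(-1, 1) * qt(0.975, df_resid) * s
  data.frame(roi = roi, window_start = window_start, coefficient = est,
             se = s, t = tval, df = df_resid, p = p, ci_lo = ci[1],
             ci_hi = ci[2], sign = sign(est), n_obs = n_obs,
             dropped = paste(dropped, collapse = ","),
             row.names = NULL)
}

#' Fit the task contrast in every region x window cell
#'
#' @param window_table a [build_window_table()].
#' @param covariates passed to [fit_window_model()].
#' @return data.frame of [fit_window_model()] rows, one per region x window.
#' @export
fit_all_windows <- function(window_table,
                            covariates = c("trial_number", "age", "sex",
                                           "lesion", "n_asm")) {
  cells <- unique(window_table[c("roi", "window_start")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    df <- window_table[window_table$roi == cells$roi[i] &
                         window_table$window_start == cells$window_start[i], ]
    fit_window_model(df, covariates)
  })
  do.call(rbind, rows)
}

#' FDR across all region x window tests
#'
#' Benjamini-Hochberg over the pooled p-values of every fitted cell (364 in
#' the standard 28-region x 13-window scheme). Significant cells keep the
#' sign of their coefficient (positive = Stroop-preferential under the
#' Stroop = 1 coding).
#'
#' @param effects a [fit_all_windows()] table.
#' @param q FDR level (default 0.05).
#' @return `effects` with columns `q_significant` and `preference`
#'   (`"stroop"` / `"reading"` for the standard contrast, NA when not
#'   significant).
#' @export
fdr_across_tests <- function(effects, q = 0.05) {
  effects$q_significant <- bh_fdr(effects$p, q)
  effects$preference <- ifelse(!effects$q_significant, NA,
                               ifelse(effects$coefficient > 0, "stroop",
                                      "reading"))
  effects
}

#' Behavioral response-time mixed model
#'
#' `rt ~ task + (1 | subject)` over the pooled trials of a cohort, with the
#' requested task coding (Stroop = 1 vs pooled word reading over all 840
#' default trials giving DF = 838, or incongruent = 1 vs congruent over the
#' 560 reading trials giving DF = 558). DF = n_obs - n_fixed (2 fixed
#' coefficients: intercept and task).
#'
#' @param events pooled event table with columns subject, task, rt, or a list
#'   of per-subject event tables plus `subjects` labels.
#' @param contrast `"stroop_vs_reading"` or `"incongruent_vs_congruent"`.
#' @param subjects subject labels when `events` is a list.
#' @return one-row data.frame: coefficient (ms), se, t, df, p, ci_lo, ci_hi,
#'   n_obs.
#' @export
fit_rt_model <- function(events, contrast = c("stroop_vs_reading",
                                              "incongruent_vs_congruent"),
                         subjects = NULL) {
  contrast <- match.arg(contrast)
  if (is.list(events) && !is.data.frame(events)) {
    subjects <- subjects %||% paste0("sub-", seq_along(events))
    events <- do.call(rbind, Map(function(ev, s)
      cbind(subject = s, ev), events, subjects))
  }
  keep <- contrast_rows(events$task, contrast)
  df <- events[keep, ]
  df$task01 <- contrast_coding(df$task, contrast)
  if (length(unique(df$task01)) < 2)
    stop("contrast needs both task levels present")
  if (length(unique(df$subject)) < 2) stop("need at least 2 subjects")
  fit <- lme4::lmer(rt ~ task01 + (1 | subject), data = df, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  out <- wald_row(fit, "task01", nrow(df), 2)
  out$roi <- NULL; out$window_start <- NULL; out$dropped <- NULL
  out
}
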