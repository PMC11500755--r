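#' ROI vocabulary
#'
#' Abbreviations of the Desikan-derived cortical regions used throughout:
#' aIFG/pIFG (anterior/posterior inferior-frontal), aITG/pITG
#' (inferior-temporal), aMFG/pMFG (middle-frontal), Cun (cuneus), IPL
#' (inferior parietal lobule), LG (lingual), LOG (lateral occipital), MTG
#' (middle-temporal), PCun (precuneus), pFG (posterior fusiform), PoCG/PreCG
#' (post/precentral), SFG (superior-frontal), SMG (supramarginal), STG
#' (superior-temporal), TP (temporal pole), each suffixed `_left` / `_right`.
#'
#' @return character vector of ROI labels.
#' @export
roi_vocabulary <- function() {
  base <- c("aIFG", "aITG", "aMFG", "pMFG", "Cun", "IPL", "LG", "LOG", "MTG",
            "PCun", "pFG", "pIFG", "pITG", "PoCG", "PreCG", "SFG", "SMG",
            "STG", "TP")
  c(paste0(base, "_left"), paste0(base, "_right"), "unassigned")
}

#' One injected task effect
#'
#' Describes a ground-truth amplitude modulation the generator injects:
#' in `roi`, the tasks on the `direction` side of `contrast` carry an extra
#' narrowband high-gamma burst calibrated so the mean percent-change amplitude
#' over `window` exceeds the other side by `amplitude_pct`.
#'
#' @param roi ROI label from [roi_vocabulary()].
#' @param contrast `"stroop_vs_reading"` (reading pools the congruent and
#'   incongruent tasks) or `"incongruent_vs_congruent"`.
#' @param direction +1 if the first-named side of the contrast is larger
#'   (e.g. Stroop-preferential), -1 for the other side.
#' @param amplitude_pct effect size in percent-change units (> 0).
#' @param window numeric length 2, ms relative to `lock` (start < end).
#' @param lock `"response"` or `"stimulus"`.
#' @export
effect_spec <- function(roi, contrast = "stroop_vs_reading", direction,
                        amplitude_pct, window, lock = "response") {
  if (!roi %in% roi_vocabulary()) stop("unknown roi: ", roi)
  contrast <- match.arg(contrast,
                        c("stroop_vs_reading", "incongruent_vs_congruent"))
  lock <- match.arg(lock, c("response", "stimulus"))
  if (!direction %in% c(-1, 1)) stop("direction must be -1 or +1")
  if (!is.finite(amplitude_pct) || amplitude_pct <= 0)
    stop("amplitude_pct must be a positive finite number")
  if (length(window) != 2 || window[1] >= window[2])
    stop("window must be (start, end) with start < end")
  data.frame(roi = roi, contrast = contrast, direction = direction,
             amplitude_pct = amplitude_pct,
             window_start = window[1], window_end = window[2], lock = lock,
             stringsAsFactors = FALSE)
}

#' Default ground-truth effect map
#'
#' The headline region/time effects of the study the generator emulates:
#' reading-preferential high-gamma in left occipito-temporal cortex (lateral
#' occipital 16.6% in -500..-300 ms, posterior fusiform 14.0% in -500..-300,
#' posterior inferior-temporal 7.7% in -400..-200, middle temporal 4.6% in
#' -200..0 ms pre-response) and Stroop-preferential high-gamma in left frontal
#' cortex (anterior middle-frontal 5.9%, posterior middle-frontal 4.0%,
#' precentral 4.3%, all in -600..-400 ms pre-response). Direction -1 =
#' reading-preferential under the Stroop-vs-reading coding.
#'
#' @return data.frame of effect specifications (one row per effect).
#' @export
default_effect_map <- function() {
  rbind(
    effect_spec("LOG_left",   direction = -1, amplitude_pct = 16.6, window = c(-500, -300)),
    effect_spec("pFG_left",   direction = -1, amplitude_pct = 14.0, window = c(-500, -300)),
    effect_spec("pITG_left",  direction = -1, amplitude_pct = 7.7,  window = c(-400, -200)),
    effect_spec("MTG_left",   direction = -1, amplitude_pct = 4.6,  window = c(-200, 0)),
    effect_spec("aMFG_left",  direction = +1, amplitude_pct = 5.9,  window = c(-600, -400)),
    effect_spec("pMFG_left",  direction = +1, amplitude_pct = 4.0,  window = c(-600, -400)),
    effect_spec("PreCG_left", direction = +1, amplitude_pct = 4.3,  window = c(-600, -400)))
}

#' Synthetic parcel centroids (mm, MNI-like)
#'
#' Spherical stand-ins for the cortical parcels; only endpoint-in-parcel
#' membership matters downstream, so spheres around plausible centroids
#' suffice. Right-hemisphere parcels mirror the left in x.
#'
#' @param radius parcel radius in mm.
#' @return data.frame with columns label, x, y, z, radius.
#' @export
default_parcels <- function(radius = 10) {
  left <- data.frame(
    label = c("LOG_left", "pFG_left", "pITG_left", "MTG_left",
              "aMFG_left", "pMFG_left", "PreCG_left", "aIFG_left"),
    x = c(-40, -40, -52, -58, -38, -42, -45, -48),
    y = c(-78, -55, -56, -40, 30, 10, -8, 28),
    z = c(0, -18, -12, -5, 28, 40, 45, 4))
  right <- left
  right$label <- sub("_left", "_right", right$label)
  right$x <- -right$x
  out <- rbind(left, right)
  out$radius <- radius
  out
}

#' Default streamline adjacency specification
#'
#' ROI pairs the synthetic streamline set connects, mirroring the tract
#' systems relevant to the injected effects: the vertical occipital fasciculus
#' (lateral occipital - posterior fusiform), inferior longitudinal fasciculus
#' (posterior fusiform - middle temporal, with a posterior inferior-temporal
#' branch), and the left frontal u-fiber triangle (anterior/posterior
#' middle-frontal and precentral gyri).
#'
#' @return two-column matrix of ROI label pairs.
#' @export
default_adjacency_spec <- function() {
  rbind(c("LOG_left", "pFG_left"),
        c("pFG_left", "MTG_left"),
        c("pFG_left", "pITG_left"),
        c("aMFG_left", "pMFG_left"),
        c("pMFG_left", "PreCG_left"),
        c("aMFG_left", "PreCG_left"))
}

#' Default exclusion regions for streamline filtering
#'
#' Spherical masks standing in for the manually excluded deep structures
#' (brainstem, bilateral thalamus and basal ganglia, ventricular CSF).
#'
#' @return data.frame with columns label, x, y, z, radius (mm).
#' @export
default_exclusion_regions <- function() {
  data.frame(
    label = c("brainstem", "thalamus_left", "thalamus_right",
              "basal_ganglia_left", "basal_ganglia_right", "csf_ventricles"),
    x = c(0, -12, 12, -25, 25, 0),
    y = c(-30, -18, -18, 0, 0, -20),
    z = c(-35, 8, 8, 0, 0, 18),
    radius = c(15, 9, 9, 12, 12, 10))
}

#' Default subject covariates
#'
#' A seven-subject clinical profile (age in years, sex with female = 1,
#' MRI-visible lesion flag, number of antiseizure medications) matching the
#' published cohort table.
#'
#' @return data.frame with one row per subject.
#' @export
default_covariates <- function() {
  data.frame(
    subject = paste0("sub-", 1:7),
    age = c(14, 10, 17, 17, 17, 17, 14),
    sex = c(1, 1, 0, 0, 1, 1, 0),
    lesion = c(0, 1, 0, 1, 0, 0, 1),
    n_asm = c(3, 2, 2, 1, 1, 2, 3))
}

#' Cohort generator configuration
#'
#' Assembles and validates every knob of the synthetic cohort: cohort size and
#' trial counts, response-time distribution (per-task means and pooled SDs,
#' decomposed into a subject random intercept and trial noise), trial timing,
#' electrode layout, noise level, the injected effect map, subject covariates,
#' and the streamline layout. Defaults encode the study conditions the
#' generator emulates: 7 subjects, 3 tasks x 40 trials, 1000 Hz sampling, RT
#' means 826/1034/1211 ms with pooled SDs 172/190/234 ms (implying a 281 ms
#' Stroop-vs-reading shift), 5000 ms stimulus display with a 2000-2500 ms
#' inter-stimulus interval, and the [default_effect_map()].
#'
#' @param n_subjects number of subjects (>= 1).
#' @param trials_per_task trials in each task block (>= 1).
#' @param tasks task labels; the reading pair plus stroop by default.
#' @param sampling_rate Hz.
#' @param rt_means named ms per task.
#' @param rt_sds named pooled SD ms per task (subject + trial variance).
#' @param rt_subject_sd SD of the per-subject RT intercept, ms.
#' @param rt_trunc lower truncation of simulated RTs, ms.
#' @param effect_map data.frame of [effect_spec()] rows (may have 0 rows).
#' @param covariates per-subject data.frame (subject, age, sex, lesion,
#'   n_asm); recycled/subset to `n_subjects`.
#' @param channels_per_roi electrode sites each subject contributes to each
#'   ROI in `rois` (3 by default, i.e. 21 sites per ROI cohort-wide,
#'   comparable to the study's 547 sites over 28 regions).
#' @param rois ROIs receiving electrodes; defaults to the effect-map ROIs.
#' @param n_flagged_per_subject extra artifact/epilepsy-flagged channels per
#'   subject, excluded by channel selection.
#' @param noise_sd RMS of the pink background noise, microvolts.
#' @param stim_duration_ms stimulus display duration.
#' @param isi_range_ms uniform inter-stimulus interval (display offset to next
#'   onset), ms.
#' @param band high-gamma band, Hz.
#' @param burst_ramp_ms raised-cosine ramp of the injected burst envelope.
#' @param streamlines_per_pair polylines per adjacent ROI pair.
#' @param qa_low_frac fraction of streamlines drawn below the QA threshold.
#' @param seed integer seed; the entire cohort is a pure function of it.
#' @return validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 7,
                          trials_per_task = 40,
                          tasks = c("congruent_reading", "incongruent_reading",
                                    "stroop"),
                          sampling_rate = 1000,
                          rt_means = c(congruent_reading = 826,
                                       incongruent_reading = 1034,
                                       stroop = 1211),
                          rt_sds = c(congruent_reading = 172,
                                     incongruent_reading = 190,
                                     stroop = 234),
                          rt_subject_sd = 100,
                          rt_trunc = 200,
                          effect_map = default_effect_map(),
                          covariates = default_covariates(),
                          channels_per_roi = 3,
                          rois = NULL,
                          n_flagged_per_subject = 1,
                          noise_sd = 25,
                          stim_duration_ms = 5000,
                          isi_range_ms = c(2000, 2500),
                          band = c(70, 110),
                          burst_ramp_ms = 20,
                          streamlines_per_pair = 25,
                          qa_low_frac = 0.2,
                          seed = 1) {
  chk <- function(cond, field, msg) if (!cond) stop("invalid cohort_config field '",
                                                    field, "': ", msg, call. = FALSE)
  chk(is.numeric(n_subjects) && n_subjects >= 1 &&
        n_subjects == round(n_subjects), "n_subjects", "must be an integer >= 1")
  chk(is.numeric(trials_per_task) && trials_per_task >= 1 &&
        trials_per_task == round(trials_per_task), "trials_per_task",
      "must be an integer >= 1")
  chk(length(tasks) >= 1 && !anyDuplicated(tasks), "tasks",
      "must be distinct labels")
  chk(all(tasks %in% names(rt_means)), "rt_means",
      "must name a mean for every task")
  chk(all(rt_means[tasks] > 0), "rt_means", "must be positive")
  chk(all(tasks %in% names(rt_sds)) && all(rt_sds[tasks] >= 0), "rt_sds",
      "must name a non-negative SD for every task")
  chk(rt_subject_sd >= 0, "rt_subject_sd", "must be >= 0")
  chk(all(rt_sds[tasks] >= rt_subject_sd | rt_sds[tasks] == 0),
      "rt_subject_sd", "cannot exceed any pooled task SD")
  chk(sampling_rate > 0, "sampling_rate", "must be positive")
  chk(is.data.frame(effect_map) &&
        all(c("roi", "contrast", "direction", "amplitude_pct", "window_start",
              "window_end", "lock") %in% names(effect_map)), "effect_map",
      "must be a data.frame of effect_spec() rows")
  if (nrow(effect_map)) {
    chk(all(effect_map$roi %in% roi_vocabulary()), "effect_map",
        "unknown ROI label")
    chk(all(effect_map$window_start < effect_map$window_end), "effect_map",
        "window start must precede end")
    chk(all(is.finite(effect_map$amplitude_pct)), "effect_map",
        "amplitude_pct must be finite")
  }
  chk(is.data.frame(covariates) &&
        all(c("age", "sex", "lesion", "n_asm") %in% names(covariates)),
      "covariates", "needs columns age, sex, lesion, n_asm")
  chk(nrow(covariates) >= n_subjects, "covariates",
      "needs at least one row per subject")
  chk(channels_per_roi >= 1, "channels_per_roi", "must be >= 1")
  chk(noise_sd > 0, "noise_sd", "must be positive")
  chk(length(isi_range_ms) == 2 && isi_range_ms[1] <= isi_range_ms[2] &&
        all(isi_range_ms >= 0), "isi_range_ms", "must be a non-negative range")
  chk(length(band) == 2 && band[1] < band[2], "band", "must be (low, high)")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed), "seed",
      "must be a single number")
  rois <- rois %||% unique(effect_map$roi)
  chk(length(rois) >= 1, "rois",
      "no ROIs: provide rois or a non-empty effect_map")
  chk(all(rois %in% roi_vocabulary()), "rois", "unknown ROI label")

  structure(list(
    n_subjects = as.integer(n_subjects),
    trials_per_task = as.integer(trials_per_task),
    tasks = tasks, sampling_rate = sampling_rate,
    rt_means = rt_means, rt_sds = rt_sds, rt_subject_sd = rt_subject_sd,
    rt_trunc = rt_trunc,
    effect_map = effect_map,
    covariates = covariates[seq_len(n_subjects), , drop = FALSE],
    channels_per_roi = as.integer(channels_per_roi), rois = rois,
    n_flagged_per_subject = as.integer(n_flagged_per_subject),
    noise_sd = noise_sd, stim_duration_ms = stim_duration_ms,
    isi_range_ms = isi_range_ms, band = band, burst_ramp_ms = burst_ramp_ms,
    streamlines_per_pair = as.integer(streamlines_per_pair),
    qa_low_frac = qa_low_frac, seed = seed), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  shift <- x$rt_means["stroop"] -
    mean(x$rt_means[setdiff(x$tasks, "stroop")])
  cat(sprintf(
    paste0("Synthetic iEEG cohort config: %d subjects x %d tasks x %d trials @ %g Hz\n",
           "  RT means: %s ms (Stroop-vs-reading shift %.0f ms)\n",
           "  %d injected effects in %d ROIs; %d sites/ROI/subject; seed %s\n"),
    x$n_subjects, length(x$tasks), x$trials_per_task, x$sampling_rate,
    paste(round(x$rt_means[x$tasks]), collapse = "/"),
    if (length(shift)) shift else NA,
    nrow(x$effect_map), length(x$rois), x$channels_per_roi,
    format(x$seed)))
  invisible(x)
}
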