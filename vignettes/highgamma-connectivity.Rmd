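---
title: "Methods: event-related high-gamma analysis and streamline-gated connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-related high-gamma analysis and streamline-gated connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and procedures implemented by `hgconn`,
the choices made where the method left room, and what the synthetic cohort
does and does not establish about real intracranial EEG.

## The analysis chain

The pipeline estimates when and where the amplitude of cortical high-gamma
activity (70-110 Hz) differs between automatic word reading and Stroop color
naming, and projects those differences onto white-matter connectivity:

1. **Channel selection and referencing.** Channels flagged for artifact,
   seizure-onset zone, interictal spikes, or an MRI lesion are excluded
   (`select_channels()`). The remaining channels are re-referenced to their
   common average (`common_average_reference()`). The reference is computed
   from included channels only by default: a reference built over all
   channels would feed epileptic or artifactual signal back into every clean
   channel. A mode computing the reference across all channels is available
   (`mode = "all"`) for comparison with pipelines that do so.
2. **Complex demodulation** (`design_demod_kernel()`,
   `complex_demodulate()`). Each channel is multiplied by a complex
   exponential at carrier frequencies every 5 Hz and low-pass filtered with
   a Gaussian FIR, which makes the transform a Gabor transform. The kernel
   is parameterized by the FWHM of its temporal *power* envelope, 31.6 ms by
   default; the Gabor time-bandwidth identity then fixes the spectral power
   FWHM at `2*log(2)/pi / 0.0316 s` (about 14 Hz). Amplitude (proportional
   to the square root of power) is scaled so a unit sinusoid reads 1 - the
   convention cancels in percent change. Output is sampled every 10 ms; bins
   whose kernel support overruns the recording are `NA`, never zero-padded,
   so baseline statistics cannot be diluted by edge effects. The FIR is
   truncated at four standard deviations of the amplitude Gaussian
   (tail mass < 1e-3).
3. **Percent change** (`band_amplitude()`, `percent_change()`). Band
   amplitude is the mean over the nine 5-Hz bins from 70 to 110 Hz. Each
   trial and channel is normalized as `100 * (a - b) / b` against `b`, the
   mean amplitude 1800-2200 ms after that trial's response onset - a quiet
   stretch that lies between the response and the next stimulus.
4. **Region series** (`roi_aggregate()`, `cohort_highgamma()`). Channel
   percent-change epochs are averaged within region *within subject* first,
   then trials are pooled across subjects, so electrode-rich subjects cannot
   dominate a region. Regions with fewer than 5 sites cohort-wide are
   dropped. Analysis windows are 80 bins of 10 ms: -200..600 ms around
   stimulus onset or -600..200 ms around response onset; bins are half-open
   `[t, t + 10)` counted from the lock.
5. **Permutation statistics** (`permutation_vs_baseline()`,
   `permutation_task_contrast()`, `bh_fdr()`, `duration_filter()`). Each
   bin's mean percent change is tested against baseline with 1000
   permutations at a two-sided 5% level, corrected by Benjamini-Hochberg
   across the window's 80 bins, and accepted only if significance persists
   at least 40 ms (four consecutive bins, three high-gamma cycles).
6. **Sliding-window mixed models** (`build_window_table()`,
   `fit_window_model()`, `fit_rt_model()`). Mean percent change in 200-ms
   windows stepping 50 ms over -600..200 ms (13 windows) is modeled per
   region as `amplitude ~ task + trial_number + age + sex + lesion + n_asm +
   (1 | subject)` by REML, with Stroop coded 1 against pooled congruent and
   incongruent reading, female coded 1, and the antiseizure-medication count
   as a clinical covariate. Benjamini-Hochberg runs across all region-by-
   window cells jointly (364 in a 28-region scheme). The behavioral model
   `rt ~ task + (1 | subject)` uses the same machinery.
7. **Connectivity atlas** (`filter_streamlines()`, `endpoint_adjacency()`,
   `task_preferential_edges()`, `export_atlas()`). Template streamlines are
   kept if QA >= 0.05, maximum turning angle <= 70 degrees, length within
   20-250 mm, and no vertex inside an exclusion mask (brainstem, basal
   ganglia, thalamus, CSF; supplied as input masks since the original
   exclusion was expert manual work). Two regions are adjacent if a
   surviving streamline ends within 3 mm of both parcels. An edge is
   emitted for a window when two adjacent regions both carry an
   FDR-significant task effect *of the same sign in that same window* -
   "simultaneously" means the same 200-ms window index, not mere interval
   overlap, because the edge rule is keyed to the mixed-model windows.
   An uncorrected-significance gate is available via `sig_col` for
   sensitivity analyses.

## Statistical decisions

**Permutation unit.** The method prescribes a permutation test of bin
amplitude against the baseline mean but not the exchange unit. We pair each
trial's tested-bin value with one randomly drawn baseline-bin value from the
same trial and flip the pair with probability 1/2 - a within-trial paired
scheme that respects trial structure and is exact under exchangeability of
stationary noise. Label permutation across trials remains available for the
between-task contrast, where it is the natural scheme.

**Two-sided p-values.** `p = (1 + #{|perm| >= |obs|}) / (n + 1)` (add-one
estimator, so p is never zero and the test remains valid under Monte-Carlo
sampling). A large shift therefore saturates at `1/(n+1)`. The alternative
`2 * min(tail p)` convention is available (`two_sided = "twice_min"`).

**Degrees of freedom.** Wald t statistics use `DF = n_obs - n_fixed`, the
convention that reproduces the published behavioral DF exactly (840 trials,
2 fixed coefficients, DF 838; 560 trials, DF 558). With hundreds of trials
per fit the difference from Satterthwaite approximations is immaterial.

**Random effects.** "Patient and intercept as random factors" is read as a
per-patient random intercept; random slopes and per-trial random effects are
out of scope. REML is used with a maximum-likelihood fallback if REML fails.
Covariates that are constant or collinear in a cell (inevitable with
subject-level covariates and few subjects) are dropped with a warning and
the model refit.

## The synthetic cohort

`simulate_cohort()` emulates the study conditions: 7 subjects, three tasks
of 40 trials (5000-ms stimulus display, inter-stimulus interval uniform in
2000-2500 ms), 1000-Hz recordings, response times with task means
826/1034/1211 ms - implying a 281-ms Stroop-vs-reading shift - decomposed
into a 100-ms subject intercept SD plus trial noise chosen to match the
published pooled SDs (172/190/234 ms), truncated at 200 ms. Subject
covariates reproduce the published cohort profile. Each subject contributes
3 electrode sites to each of the seven effect regions (21 sites per region
cohort-wide, comparable to the study's 547 sites over 28 regions) plus one
flagged channel that channel selection must remove.

**Background signal** is 1/f ("pink") noise at 25 uV RMS - the standard
spectral model for iEEG - generated by a pole-zero cascade with a measured
-1 power-law slope over 2-200 Hz.

**Injected effects.** The default effect map encodes the seven headline
task effects (lateral occipital 16.6% and posterior fusiform 14.0% in
-500..-300 ms, posterior inferior-temporal 7.7% in -400..-200 ms, middle
temporal 4.6% in -200..0 ms, all reading-preferential; anterior/posterior
middle-frontal 5.9%/4.0% and precentral 4.3% in -600..-400 ms,
Stroop-preferential). An effect is an amplitude-modulated narrowband noise
burst added to the preferred tasks' trials. Because burst and background
are independent, their amplitudes add in quadrature; the generator solves
`mean_b sqrt(A0^2 + (s * a_u(b))^2) / A0 - 1 = g` for the burst scale `s`,
where `A0` is the demodulated band floor of the background and `a_u(b)` the
measured per-bin response profile of a unit burst, so that the *window-mean*
percent change recovered by the measurement chain equals the configured
effect. The envelope is flat with 20-ms raised-cosine ramps: a full
raised-cosine envelope would make the per-bin peak and the window mean
diverge by about a third, leaving no single calibration target; the flat
top keeps both close while still avoiding ringing on the 10-ms grid.
Decreases are represented as increases on the other side of the contrast,
which is equivalent for every contrast-based statistic in the pipeline.

**Reference-proof injection.** Bursts are injected zero-sum across the
included channels: the burst is added to its channel (scaled by
`n/(n-1)`) and the exact counterweight is spread over the other included
channels, so the common average of the injected component is identically
zero and re-referencing passes it through unchanged. The calibration floor
is accordingly the post-reference background floor (`sqrt(1 - 1/n)` of the
raw floor), with a small correction for the variance fed back by sibling
channels of the same region. Without this, simultaneous bursts leak through
the common average and bias recovered effects by tens of percent when few
channels are included.

**Ground truth** (RT parameters, effect map, channel map, adjacency, and
the expected edge list) travels alongside the data for recovery scoring,
and no analysis function reads it. Truth edges are defined at windows fully
contained in both regions' effect windows; windows merely overlapping an
effect count as "supported" - emitted edges there are genuine partial-window
detections, not false positives - and only edges outside the support set
count against the false-edge rate.

**What the generator does not emulate:** evoked (phase-locked) potentials,
line noise, movement or epileptic artifacts (exclusion flags are inputs, not
detected), electrode spatial correlation beyond the shared reference,
non-stationary baselines, and any biophysical forward model. Passing
recovery tests therefore shows the *estimators* are unbiased and calibrated
under the assumed signal model, not that the pipeline is robust to every
pathology of clinical recordings.

## Problem sizes

The validation suite runs the permutation-size study at 2000 null datasets
of 40 trials; behavioral recovery over 50 seeded cohorts; amplitude-effect
coverage over 50 seeded cohorts focused on the lateral occipital effect
(6 included channels over 2 regions per subject); and end-to-end atlas
recovery over 4 full default cohorts. The `analysis/` scripts use one
default cohort (seed 42). These sizes give Monte-Carlo standard errors
comfortably inside the tolerances asserted (e.g. about 0.3 percentage
points for the permutation size) while keeping a full run on one CPU in
minutes.

## Known limitations

- The permutation size can run marginally above nominal because baseline
  bins are centered by their own trial mean while task bins are not; the
  asymmetry is second-order (the validation suite measures the realized
  size), but an exactly exchangeable variant would exclude the partner bin
  from the baseline mean.
- Percent change is a ratio against a noisy baseline mean (40 correlated
  bins), inflating recovered effects by roughly its squared coefficient of
  variation (about +2% relative).
- With 7 subjects, subject-level covariates (age, sex, lesion, medication)
  are barely identifiable; they are retained because the method specifies
  them, and the rank-guard drops them when a cell cannot support them.
- Parcels are spheres and adjacency is endpoint-based with a 3-mm
  tolerance; centroids are synthetic, so anatomical tract names attached to
  generated streamlines are labels, not anatomy.
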