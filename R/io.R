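# Readers and writers for the BIDS-iEEG-style sidecar dialect: events,
# channels, participants, streamlines as TSV, recordings as flat float64
# binary with a JSON sidecar.

#' @rdname cohort_io
#' @export
write_events_tsv <- function(events, path, stim_duration_ms = 5000) {
  d <- data.frame(onset = events$stimulus_onset / 1000,
                  duration = stim_duration_ms / 1000,
                  trial_type = events$task,
                  response_time = events$rt / 1000)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_events_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  ev <- data.frame(task = d$trial_type,
                   stimulus_onset = round(d$onset * 1000),
                   rt = round(d$response_time * 1000))
  ev$response_onset <- ev$stimulus_onset + ev$rt
  ev$trial_id <- seq_len(nrow(ev))
  ev$trial_number <- stats::ave(ev$trial_id, ev$task, FUN = seq_along)
  ev[c("trial_id", "task", "trial_number", "stimulus_onset",
       "response_onset", "rt")]
}

#' @rdname cohort_io
#' @export
write_channels_tsv <- function(channels, path) {
  flags <- c("artifact", "soz", "spikes", "lesion")
  desc <- apply(channels[flags], 1, function(r) {
    on <- flags[as.logical(r)]
    if (length(on)) paste(on, collapse = "+") else "n/a"
  })
  d <- data.frame(name = channels$channel_id, roi = channels$roi,
                  status = ifelse(select_channels(channels), "good", "bad"),
                  status_description = desc)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_channels_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  ch <- data.frame(channel_id = d$name, roi = d$roi,
                   stringsAsFactors = FALSE)
  for (f in c("artifact", "soz", "spikes", "lesion"))
    ch[[f]] <- grepl(f, d$status_description, fixed = TRUE)
  ch$include <- select_channels(ch)
  ch
}

#' @rdname cohort_io
#' @export
write_participants_tsv <- function(participants, path) {
  d <- data.frame(participant_id = participants$subject,
                  age = participants$age,
                  sex = ifelse(participants$sex == 1, "F", "M"),
                  lesion = ifelse(participants$lesion == 1, "yes", "no"),
                  n_asm = participants$n_asm)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_participants_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(sex = "character"))
  data.frame(subject = d$participant_id, age = d$age,
             sex = as.numeric(d$sex == "F"),
             lesion = as.numeric(d$lesion == "yes"), n_asm = d$n_asm)
}

#' @rdname cohort_io
#' @export
write_streamlines_tsv <- function(set, path) {
  d <- as.data.frame(set)
  for (v in c("x", "y", "z")) d[[v]] <- round(d[[v]], 3)  # 1-um precision
  d$qa <- round(d$qa, 6)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_streamlines_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  class(d) <- c("streamline_set", "data.frame")
  d
}

#' @rdname cohort_io
#' @export
write_recording_bin <- function(recording, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(recording$samples), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(rate = recording$rate, n_samples = nrow(recording$samples),
         channel_ids = recording$channel_ids, t0 = recording$t0,
         dtype = "float64", order = "column-major"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_recording_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", meta$n_samples * length(meta$channel_ids),
               size = 8, endian = "little")
  structure(list(samples = matrix(v, meta$n_samples),
                 rate = meta$rate, channel_ids = meta$channel_ids,
                 t0 = meta$t0), class = "ieeg_recording")
}

#' Cohort input/output
#'
#' BIDS-iEEG-style sidecar files: per-subject `events.tsv` (onset, duration,
#' trial_type, response_time; seconds), `channels.tsv` (name, roi, status,
#' status_description), cohort-level `participants.tsv` (age, sex, lesion,
#' antiseizure medication count) and `streamlines.tsv` (long polyline format
#' with per-streamline QA), and optional flat float64 recordings with JSON
#' sidecars.
#'
#' @param cohort an `ieeg_cohort`.
#' @param dir output directory.
#' @param signals also write the (large) voltage recordings.
#' @param events,channels,participants,set,recording the respective tables.
#' @param path file path.
#' @param stim_duration_ms display duration written to the events file.
#' @name cohort_io
#' @export
write_cohort_bids <- function(cohort, dir, signals = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_participants_tsv(cohort$participants,
                         file.path(dir, "participants.tsv"))
  write_streamlines_tsv(cohort$streamlines,
                        file.path(dir, "streamlines.tsv"))
  for (s in seq_along(cohort$events)) {
    sub <- cohort$participants$subject[s]
    sd <- file.path(dir, sub)
    dir.create(sd, showWarnings = FALSE)
    write_events_tsv(cohort$events[[s]], file.path(sd, "events.tsv"),
                     cohort$config$stim_duration_ms %||% 5000)
    write_channels_tsv(cohort$channels[[s]], file.path(sd, "channels.tsv"))
    if (signals && !is.null(cohort$recordings[[s]]))
      write_recording_bin(cohort$recordings[[s]],
                          file.path(sd, "ieeg.float64"))
  }
  invisible(dir)
}
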