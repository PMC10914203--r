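# CSV readers and writers for waveforms, annotations and results.
# Waveform CSV schema: time_s, ppg. Annotation CSV schema: track, start_s,
# duration_s, label, with track in {arousal, resp_event, desaturation, stage}.

#' Write a PPG record to CSV
#'
#' @param record A [ppg_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ppg_csv <- function(record, path) {
  stopifnot(inherits(record, "ppg_record"))
  t <- record$start_s + (seq_along(record$samples) - 1) / record$fs
  utils::write.csv(data.frame(time_s = t, ppg = record$samples), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a PPG record from CSV
#'
#' Expects columns `time_s` and `ppg` on a uniform time grid.
#'
#' @param path Input file path.
#' @param subject_id Subject identifier to attach.
#' @return A [ppg_record()].
#' @export
read_ppg_csv <- function(path, subject_id = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "ppg") %in% names(df))) {
    stop("malformed PPG CSV ", path, ": need columns time_s, ppg")
  }
  dt <- diff(df$time_s)
  if (length(dt) == 0L || any(abs(dt - dt[1]) > 1e-6)) {
    stop("PPG CSV ", path, " is not uniformly sampled")
  }
  ppg_record(df$ppg, 1 / dt[1],
             subject_id %||% sub("\\.csv$", "", basename(path)),
             start_s = df$time_s[1])
}

#' Write an annotation set to CSV
#'
#' One row per event with `track`, `start_s`, `duration_s`, `label` (scored
#' cause, event type or sleep stage; stage rows have duration 30).
#'
#' @param ann An [annotation_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  rows <- rbind(
    if (nrow(ann$arousals)) data.frame(
      track = "arousal", start_s = ann$arousals$start_s,
      duration_s = ann$arousals$duration_s, label = ann$arousals$scored_cause),
    if (nrow(ann$resp_events)) data.frame(
      track = "resp_event", start_s = ann$resp_events$start_s,
      duration_s = ann$resp_events$duration_s, label = ann$resp_events$type),
    if (nrow(ann$desaturations)) data.frame(
      track = "desaturation", start_s = ann$desaturations$start_s,
      duration_s = ann$desaturations$duration_s, label = "desat3"),
    if (nrow(ann$stage_epochs)) data.frame(
      track = "stage", start_s = ann$stage_epochs$epoch_start_s,
      duration_s = 30, label = ann$stage_epochs$stage)
  )
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read an annotation set from CSV
#'
#' @param path Input file path (schema as in [write_annotations_csv()]).
#' @param subject_id Subject identifier to attach.
#' @return An [annotation_set()].
#' @export
read_annotations_csv <- function(path, subject_id = NULL) {
  df <- utils::read.csv(path)
  need <- c("track", "start_s", "duration_s", "label")
  if (!all(need %in% names(df))) {
    stop("malformed annotation CSV ", path, ": need columns ",
         paste(need, collapse = ", "))
  }
  bad <- which(!df$track %in% c("arousal", "resp_event", "desaturation", "stage"))
  if (length(bad)) {
    stop("malformed annotation CSV ", path, ": unknown track '",
         df$track[bad[1]], "' in row ", bad[1])
  }
  pick <- function(tr) df[df$track == tr, , drop = FALSE]
  ar <- pick("arousal"); re <- pick("resp_event")
  de <- pick("desaturation"); st <- pick("stage")
  annotation_set(
    arousals = if (nrow(ar)) data.frame(start_s = ar$start_s,
                                        duration_s = ar$duration_s,
                                        scored_cause = ar$label) else NULL,
    resp_events = if (nrow(re)) data.frame(start_s = re$start_s,
                                           duration_s = re$duration_s,
                                           type = re$label) else NULL,
    desaturations = if (nrow(de)) data.frame(start_s = de$start_s,
                                             duration_s = de$duration_s) else NULL,
    stage_epochs = if (nrow(st)) data.frame(epoch_start_s = st$start_s,
                                            stage = st$label) else NULL,
    subject_id = subject_id %||% sub("\\.csv$", "", basename(path))
  )
}
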