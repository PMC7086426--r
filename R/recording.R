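#' Construct an EEG recording
#'
#' A recording is a channels-by-samples amplitude matrix (microvolts) with a
#' sampling rate, ordered channel labels, a subject identifier and a class
#' label (`healthy`, `tbi` or `unknown`).
#'
#' @param signal Numeric matrix, channels in rows, samples in columns,
#'   amplitudes in microvolts.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_labels Character vector, one label per row of `signal`.
#' @param subject_id Subject identifier string.
#' @param class_label One of `"healthy"`, `"tbi"`, `"unknown"`.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(signal, fs, channel_labels,
                      subject_id = "unknown", class_label = "unknown") {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("signal must be numeric", call. = FALSE)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a positive scalar", call. = FALSE)
  }
  if (ncol(signal) < 1L) stop("recording needs at least one sample", call. = FALSE)
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(signal)) {
    stop("format error: ", length(channel_labels), " labels for ",
         nrow(signal), " signal rows", call. = FALSE)
  }
  class_label <- match.arg(class_label, c("healthy", "tbi", "unknown"))
  rownames(signal) <- channel_labels
  structure(
    list(signal = signal, fs = fs, channel_labels = channel_labels,
         subject_id = as.character(subject_id), class_label = class_label),
    class = "eeg_recording")
}

#' @export
#' @method print eeg_recording
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "EEG recording '%s' (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$class_label, nrow(x$signal), ncol(x$signal), x$fs,
    ncol(x$signal) / x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$signal) / rec$fs

#' Discard the initial portion of a recording
#'
#' Drops the first `seconds` of every channel. The pipeline discards the
#' first 60 s of each resting-state recording because subjects are typically
#' not yet calm and the early signal is artifact-prone.
#'
#' @param rec An `eeg_recording`.
#' @param seconds Duration to discard (>= 0); the recording must be strictly
#'   longer than this.
#' @return The shortened recording.
#' @export
discard_initial <- function(rec, seconds = 60) {
  stopifnot(inherits(rec, "eeg_recording"), seconds >= 0)
  if (seconds == 0) return(rec)
  n_drop <- round(seconds * rec$fs)
  if (n_drop >= ncol(rec$signal)) {
    stop(sprintf(
      "insufficient data: recording is %.2f s, cannot discard %.2f s",
      recording_duration(rec), seconds), call. = FALSE)
  }
  rec$signal <- rec$signal[, -seq_len(n_drop), drop = FALSE]
  rec
}

#' Reject one-second windows exceeding an amplitude threshold
#'
#' Deterministic surrogate for manual artifact inspection: any one-second
#' window in which some channel exceeds `threshold` microvolts in absolute
#' value is dropped, and the surviving windows are concatenated. The report
#' lists the dropped window indices with the peak absolute amplitude seen.
#'
#' @param rec An `eeg_recording`.
#' @param threshold Positive amplitude threshold in microvolts (default
#'   100; `Inf` disables rejection).
#' @return A list with elements `recording` (windows that survived,
#'   re-concatenated) and `report` (data.frame with columns `window` and
#'   `peak_amplitude` for dropped windows).
#' @export
reject_artifacts <- function(rec, threshold = 100) {
  stopifnot(inherits(rec, "eeg_recording"), threshold > 0)
  win <- round(rec$fs)
  n_win <- floor(ncol(rec$signal) / win)
  dropped <- integer(0)
  peaks <- numeric(0)
  keep_cols <- logical(ncol(rec$signal))
  for (w in seq_len(n_win)) {
    cols <- ((w - 1L) * win + 1L):(w * win)
    peak <- max(abs(rec$signal[, cols]))
    if (peak > threshold) {
      dropped <- c(dropped, w)
      peaks <- c(peaks, peak)
    } else {
      keep_cols[cols] <- TRUE
    }
  }
  # trailing partial window is kept untouched
  if (n_win * win < ncol(rec$signal)) {
    keep_cols[(n_win * win + 1L):ncol(rec$signal)] <- TRUE
  }
  out <- rec
  out$signal <- rec$signal[, keep_cols, drop = FALSE]
  list(recording = out,
       report = data.frame(window = dropped, peak_amplitude = peaks))
}

#' Cut a recording into fixed-length segments
#'
#' Divides the recording into consecutive non-overlapping windows of
#' `window_seconds` and returns each as a channels-by-samples matrix: entry
#' `[i, t]` is the amplitude of channel `i` at the `t`-th sample of the
#' window. With the study configuration (63 channels, 1000 Hz, 1 s windows)
#' each segment is a 63 x 1000 matrix and 60 s of signal yield 60 segments.
#' A trailing partial window is discarded.
#'
#' @param rec An `eeg_recording`.
#' @param window_seconds Window length in seconds (default 1).
#' @param max_segments Cap on the number of segments returned (default
#'   `Inf`).
#' @return List of `eeg_segment` objects, each with fields `matrix`,
#'   `subject_id`, `index` and `class_label`.
#' @export
segment_recording <- function(rec, window_seconds = 1, max_segments = Inf) {
  stopifnot(inherits(rec, "eeg_recording"), window_seconds > 0)
  win <- round(window_seconds * rec$fs)
  n_seg <- floor(ncol(rec$signal) / win)
  if (n_seg < 1L) {
    stop(sprintf(
      "insufficient data: %.2f s recording shorter than one %.2f s window",
      recording_duration(rec), window_seconds), call. = FALSE)
  }
  n_seg <- min(n_seg, max_segments)
  lapply(seq_len(n_seg), function(k) {
    cols <- ((k - 1L) * win + 1L):(k * win)
    structure(
      list(matrix = rec$signal[, cols, drop = FALSE],
           subject_id = rec$subject_id,
           index = k,
           class_label = rec$class_label),
      class = "eeg_segment")
  })
}

#' @export
#' @method print eeg_segment
print.eeg_segment <- function(x, ...) {
  cat(sprintf("EEG segment %d of '%s' (%s): %d x %d\n", x$index,
              x$subject_id, x$class_label, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

# ---- input / output --------------------------------------------------------

#' Load an EEG recording from disk
#'
#' Supports European Data Format (EDF, 16-bit) and a plain-text matrix
#' format: a tab-delimited numeric matrix with channels as rows plus a
#' `<path>.meta` sidecar of `key: value` lines carrying `labels`
#' (comma-separated), `fs`, `subject_id` and `class_label`. Amplitudes are
#' microvolts; EDF physical-dimension scaling is honoured.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"edf"` or `"matrix"`.
#' @return An `eeg_recording`.
#' @export
load_recording <- function(path, format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  if (format == "edf") return(read_edf(path))
  read_matrix_recording(path)
}

#' Write an EEG recording to disk
#'
#' Inverse of [load_recording()]; `format = "edf"` writes 16-bit EDF (with
#' quantization bounded by the per-channel physical range), `"matrix"`
#' writes the tab-delimited matrix plus its `.meta` sidecar.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @param format `"edf"` or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("edf", "matrix")) {
  format <- match.arg(format)
  if (format == "edf") write_edf(rec, path) else write_matrix_recording(rec, path)
  invisible(path)
}

read_matrix_recording <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) {
    stop("format error: missing sidecar ", meta_path, call. = FALSE)
  }
  meta <- read_kv(meta_path)
  for (k in c("labels", "fs")) {
    if (is.null(meta[[k]])) {
      stop("format error: sidecar lacks key '", k, "'", call. = FALSE)
    }
  }
  labels <- trimws(strsplit(meta$labels, ",")[[1]])
  sig <- as.matrix(data.table::fread(path, header = FALSE, sep = "\t"))
  dimnames(sig) <- NULL
  if (nrow(sig) != length(labels)) {
    stop("format error: ", length(labels), " labels but ", nrow(sig),
         " matrix rows in ", path, call. = FALSE)
  }
  recording(sig, fs = as.numeric(meta$fs), channel_labels = labels,
            subject_id = meta$subject_id %||% "unknown",
            class_label = meta$class_label %||% "unknown")
}

write_matrix_recording <- function(rec, path) {
  data.table::fwrite(data.table::as.data.table(rec$signal), path,
                     sep = "\t", col.names = FALSE)
  writeLines(c(paste0("labels: ", paste(rec$channel_labels, collapse = ",")),
               paste0("fs: ", format(rec$fs, digits = 15)),
               paste0("subject_id: ", rec$subject_id),
               paste0("class_label: ", rec$class_label)),
             paste0(path, ".meta"))
  invisible(path)
}

read_kv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  keys <- sub(":.*$", "", lines)
  vals <- trimws(sub("^[^:]*:", "", lines))
  stats::setNames(as.list(vals), trimws(keys))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
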