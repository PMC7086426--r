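#' Channel labels of the 64-channel WaveGuard cap
#'
#' Returns the 64 electrode names of the ANT WaveGuard 10-10 cap in its
#' default channel order. This is the montage the pipeline assumes: 64
#' recorded sites of which `CPz` is treated as an electrooculography channel
#' and excluded before analysis, leaving 63 usable channels.
#'
#' @return Character vector of 64 channel labels.
#' @export
waveguard_labels <- function() {
  c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "M1", "T7", "C3", "Cz",
    "C4", "T8", "M2", "CP5", "CP1", "CP2", "CP6", "P7",
    "P3", "Pz", "P4", "P8", "POz", "O1", "Oz", "O2",
    "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
    "FC3", "FCz", "FC4", "C5", "C1", "C2", "C6", "CP3",
    "CPz", "CP4", "P5", "P1", "P2", "P6", "PO5", "PO3",
    "PO4", "PO6", "FT7", "FT8", "TP7", "TP8", "PO7", "PO8")
}

#' Define a montage
#'
#' A montage is the full set of recorded channel labels plus the subset that
#' is excluded before analysis. The default reproduces the study montage:
#' the 64 WaveGuard sites with `CPz` excluded (it serves as the EOG channel),
#' retaining 63 channels.
#'
#' @param all_labels Character vector of recorded channel labels.
#' @param excluded Character vector of labels to drop (must be a subset of
#'   `all_labels`); duplicates are ignored.
#' @param reference Free-text description of the reference scheme.
#' @return An object of class `eeg_montage`.
#' @export
montage <- function(all_labels = waveguard_labels(),
                    excluded = "CPz",
                    reference = "linked earlobes") {
  all_labels <- as.character(all_labels)
  excluded <- unique(as.character(excluded))
  if (anyDuplicated(all_labels)) {
    stop("montage labels must be unique", call. = FALSE)
  }
  if (!all(excluded %in% all_labels)) {
    stop("excluded labels not present in montage: ",
         paste(setdiff(excluded, all_labels), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(all_labels = all_labels, excluded_labels = excluded,
         reference_description = reference),
    class = "eeg_montage")
}

#' @export
#' @method print eeg_montage
print.eeg_montage <- function(x, ...) {
  cat(sprintf("EEG montage: %d channels, %d excluded (%s), %d retained\n",
              length(x$all_labels), length(x$excluded_labels),
              paste(x$excluded_labels, collapse = ", "),
              length(x$all_labels) - length(x$excluded_labels)))
  invisible(x)
}

#' Number of channels a montage retains
#' @param m An `eeg_montage`.
#' @return Integer count of retained channels.
#' @export
montage_retained <- function(m) {
  length(m$all_labels) - length(m$excluded_labels)
}

#' Drop excluded channels from a recording
#'
#' Removes the montage's excluded channels (by label) from a recording while
#' preserving the relative order of the remaining channels, i.e. the cap's
#' default arrangement. With the study montage this turns a 64-channel
#' recording into the 63 analysis channels.
#'
#' @param rec An `eeg_recording`.
#' @param m An `eeg_montage`. Every excluded label must be present in `rec`.
#' @return The recording without the excluded channels.
#' @export
apply_montage <- function(rec, m = montage()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(m, "eeg_montage"))
  excl <- unique(m$excluded_labels)
  if (!all(excl %in% rec$channel_labels)) {
    stop("montage error: excluded label(s) absent from recording: ",
         paste(setdiff(excl, rec$channel_labels), collapse = ", "),
         call. = FALSE)
  }
  if (length(excl) == 0L) return(rec)
  keep <- !(rec$channel_labels %in% excl)
  recording(signal = rec$signal[keep, , drop = FALSE],
            fs = rec$fs,
            channel_labels = rec$channel_labels[keep],
            subject_id = rec$subject_id,
            class_label = rec$class_label)
}
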