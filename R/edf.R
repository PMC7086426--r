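# Minimal European Data Format (EDF) reader/writer.
#
# Fixed-layout ASCII header (256 bytes + 256 per signal) followed by 16-bit
# little-endian samples, record-major with per-signal blocks. One-second data
# records are written; amplitudes are microvolts and the per-channel
# physical/digital scaling of the format is honoured, so a round trip is
# exact up to the 16-bit quantization step of the channel's physical range.

edf_str <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width = 8) {
  for (d in 7:1) {
    s <- formatC(signif(x, d), format = "g", digits = d, width = 1)
    if (nchar(s) <= width) return(formatC(s, width = width, flag = "-"))
  }
  stop("cannot format ", x, " in ", width, " EDF header bytes", call. = FALSE)
}

#' Write a recording as EDF
#'
#' @param rec An `eeg_recording` with integer sampling rate.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate",
                            call. = FALSE)
  ns <- nrow(rec$signal)
  n_rec <- floor(ncol(rec$signal) / fs)
  if (n_rec < 1L) stop("recording shorter than one EDF data record", call. = FALSE)
  if (n_rec * fs < ncol(rec$signal)) {
    warning("EDF writer truncating trailing partial second")
  }

  pmin <- apply(rec$signal, 1, min)
  pmax <- apply(rec$signal, 1, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(edf_str("0", 8))
  wr(edf_str(rec$subject_id, 80))
  wr(edf_str(paste0("class=", rec$class_label), 80))
  wr(edf_str("01.01.26", 8))
  wr(edf_str("00.00.00", 8))
  wr(edf_str(256 * (ns + 1), 8))
  wr(edf_str("", 44))
  wr(edf_str(n_rec, 8))
  wr(edf_str("1", 8))
  wr(edf_str(ns, 4))
  wr(paste0(vapply(rec$channel_labels, edf_str, "", width = 16), collapse = ""))
  wr(strrep(edf_str("", 80), ns))                    # transducer
  wr(strrep(edf_str("uV", 8), ns))                   # physical dimension
  wr(paste0(vapply(pmin, edf_num, ""), collapse = ""))
  wr(paste0(vapply(pmax, edf_num, ""), collapse = ""))
  wr(strrep(edf_str("-32768", 8), ns))
  wr(strrep(edf_str("32767", 8), ns))
  wr(strrep(edf_str("", 80), ns))                    # prefiltering
  wr(strrep(edf_str(fs, 8), ns))
  wr(strrep(edf_str("", 32), ns))

  # physical -> digital, per channel
  scale <- (32767 - (-32768)) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((rec$signal[ch, cols] - pmin[ch]) * scale[ch] - 32768)
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path Path to a 16-bit EDF file.
#' @return An `eeg_recording` in microvolts (assuming uV physical units).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rdn <- function(n) as.numeric(trimws(rd(n)))
  version <- trimws(rd(8))
  if (version != "0") stop("not an EDF file: ", path, call. = FALSE)
  subject_id <- trimws(rd(80))
  rec_field <- trimws(rd(80))
  rd(8); rd(8)                                       # start date/time
  rdn(8)                                             # header bytes
  rd(44)
  n_rec <- rdn(8)
  rec_dur <- rdn(8)
  ns <- as.integer(rdn(4))
  per_sig <- function(width, fn = trimws) {
    vapply(seq_len(ns), function(i) fn(rd(width)), "")
  }
  labels <- per_sig(16)
  per_sig(80)                                        # transducer
  per_sig(8)                                         # physical dimension
  pmin <- as.numeric(per_sig(8))
  pmax <- as.numeric(per_sig(8))
  dmin <- as.numeric(per_sig(8))
  dmax <- as.numeric(per_sig(8))
  per_sig(80)                                        # prefiltering
  nr <- as.integer(per_sig(8))
  per_sig(32)
  if (length(unique(nr)) != 1L) {
    stop("EDF with per-signal sampling rates not supported", call. = FALSE)
  }
  fs <- nr[1] / rec_dur
  sig <- matrix(0, nrow = ns, ncol = n_rec * nr[1])
  gain <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nr[1], size = 2, signed = TRUE,
                     endian = "little")
      cols <- ((r - 1L) * nr[1] + 1L):(r * nr[1])
      sig[ch, cols] <- (dig - dmin[ch]) * gain[ch] + pmin[ch]
    }
  }
  class_label <- "unknown"
  if (grepl("^class=", rec_field)) {
    cl <- sub("^class=", "", rec_field)
    if (cl %in% c("healthy", "tbi")) class_label <- cl
  }
  recording(sig, fs = fs, channel_labels = labels,
            subject_id = if (nzchar(subject_id)) subject_id else "unknown",
            class_label = class_label)
}
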