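test_that("recording constructor enforces its invariants", {
  sig <- matrix(rnorm(12), 3, 4)
  rec <- recording(sig, fs = 4, channel_labels = c("a", "b", "c"))
  expect_s3_class(rec, "eeg_recording")
  expect_equal(recording_duration(rec), 1)
  expect_error(recording(sig, 4, c("a", "b")), "format error")
  expect_error(recording(sig, -1, c("a", "b", "c")), "fs")
})

test_that("montage exclusion drops CPz and preserves channel order", {
  spec <- cohort_spec(n_per_class = 1, n_channels = 64, fs = 100,
                      duration_s = 2, seed = 1)
  rec <- generate_subject(spec, "healthy", 1)
  expect_equal(length(rec$channel_labels), 64)

  out <- apply_montage(rec, montage())
  expect_equal(nrow(out$signal), 63)
  expect_false("CPz" %in% out$channel_labels)
  expect_identical(out$channel_labels,
                   setdiff(rec$channel_labels, "CPz"))

  # empty exclusion is the identity
  same <- apply_montage(rec, montage(rec$channel_labels, character(0)))
  expect_identical(same$signal, rec$signal)

  # a twice-listed exclusion removes the channel once
  twice <- apply_montage(rec, montage(rec$channel_labels, c("CPz", "CPz")))
  expect_equal(nrow(twice$signal), 63)

  # second application with empty exclusions is idempotent
  again <- apply_montage(out, montage(out$channel_labels, character(0)))
  expect_identical(again$signal, out$signal)

  expect_error(apply_montage(out, montage()), "montage error")
})

test_that("discard_initial removes exactly the leading samples", {
  rec <- recording(matrix(seq_len(200), 2, 100, byrow = TRUE), fs = 10,
                   channel_labels = c("a", "b"))
  out <- discard_initial(rec, 4)
  expect_equal(ncol(out$signal), 60)
  expect_equal(out$signal[1, 1], rec$signal[1, 41])
  expect_identical(discard_initial(rec, 0), rec)
  expect_error(discard_initial(rec, 10), "insufficient data")
  expect_error(discard_initial(rec, 11), "insufficient data")
})

test_that("amplitude-threshold rejection drops exactly the spiked window", {
  spec <- cohort_spec(n_per_class = 1, n_channels = 8, fs = 50,
                      duration_s = 10, seed = 2)
  rec <- generate_subject(spec, "healthy", 1)
  clean <- reject_artifacts(rec, threshold = 500)
  expect_equal(nrow(clean$report), 0)
  expect_identical(clean$recording$signal, rec$signal)

  # 1000 uV spike at t = 5 s lands in the sixth one-second window
  spiked <- rec
  spiked$signal[3, 5 * 50 + 10] <- 1000
  out <- reject_artifacts(spiked, threshold = 500)
  expect_equal(out$report$window, 6)
  expect_equal(ncol(out$recording$signal), ncol(rec$signal) - 50)

  expect_identical(reject_artifacts(spiked, Inf)$recording$signal,
                   spiked$signal)
})

test_that("segmentation yields matrices that tile the recording", {
  spec <- cohort_spec(n_per_class = 1, n_channels = 8, fs = 40,
                      duration_s = 5.9, seed = 3)
  rec <- generate_subject(spec, "tbi", 1)
  segs <- segment_recording(rec, 1)
  expect_length(segs, 5)          # trailing 0.9 s discarded
  expect_equal(dim(segs[[1]]$matrix), c(8, 40))
  expect_equal(vapply(segs, function(s) s$index, 0L), 1:5)
  expect_true(all(vapply(segs, function(s) s$class_label, "") == "tbi"))

  # concatenating the segments reproduces the first floor(duration) seconds
  expect_identical(do.call(cbind, lapply(segs, function(s) s$matrix)),
                   rec$signal[, 1:200])

  expect_length(segment_recording(rec, 1, max_segments = 3), 3)
  one <- recording(matrix(rnorm(40), 1, 40), 40, "a")
  expect_length(segment_recording(one, 1), 1)
  short <- recording(matrix(rnorm(20), 1, 20), 40, "a")
  expect_error(segment_recording(short, 1), "insufficient data")
})

test_that("the study pipeline arithmetic gives 60 segments of 63 x 1000", {
  # reduced-rate stand-in for the full geometry: same channel count and
  # second structure, smaller fs (the full-size case is covered by the
  # acceptance suite)
  spec <- cohort_spec(n_per_class = 1, n_channels = 64, fs = 50,
                      duration_s = 130, seed = 5)
  rec <- generate_subject(spec, "healthy", 1)
  segs <- segment_recording(discard_initial(apply_montage(rec, montage()), 60),
                            1, max_segments = 60)
  expect_length(segs, 60)
  expect_equal(dim(segs[[1]]$matrix), c(63, 50))
})

test_that("matrix interchange format round-trips and validates", {
  rec <- generate_subject(cohort_spec(n_per_class = 1, n_channels = 6,
                                      fs = 80, duration_s = 2, seed = 6),
                          "tbi", 1)
  path <- tempfile(fileext = ".tsv")
  write_recording(rec, path, "matrix")
  back <- load_recording(path)
  expect_equal(back$signal, rec$signal, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$class_label, "tbi")

  # label/row mismatch is a format error
  meta <- readLines(paste0(path, ".meta"))
  meta[1] <- "labels: a,b,c"
  writeLines(meta, paste0(path, ".meta"))
  expect_error(load_recording(path), "format error")
  expect_error(load_recording(tempfile()), "cannot read")
})

test_that("EDF round-trip is exact up to 16-bit quantization", {
  rec <- generate_subject(cohort_spec(n_per_class = 1, n_channels = 8,
                                      fs = 100, duration_s = 3, seed = 7),
                          "tbi", 1)
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_equal(back$fs, 100)
  expect_equal(back$subject_id, rec$subject_id)
  expect_equal(back$class_label, "tbi")
  step <- max(apply(rec$signal, 1, function(x) diff(range(x)))) / 65535
  expect_lt(max(abs(back$signal - rec$signal)), 2 * step)
})

test_that("an independent EDF reader agrees with the writer", {
  # cross-check the byte layout against python-mne
  rec <- generate_subject(cohort_spec(n_per_class = 1, n_channels = 5,
                                      fs = 64, duration_s = 2, seed = 8),
                          "healthy", 1)
  path <- tempfile(fileext = ".edf")
  csv <- tempfile(fileext = ".csv")
  write_edf(rec, path)
  code <- sprintf(paste0(
    "import mne, numpy as np; ",
    "raw = mne.io.read_raw_edf('%s', verbose='ERROR'); ",
    "np.savetxt('%s', raw.get_data() * 1e6, delimiter=',')"), path, csv)
  status <- suppressWarnings(system2("python", c("-c", shQuote(code)),
                                     stdout = FALSE, stderr = FALSE))
  expect_identical(status, 0L)
  ext <- as.matrix(utils::read.csv(csv, header = FALSE))
  step <- max(apply(rec$signal, 1, function(x) diff(range(x)))) / 65535
  expect_lt(max(abs(ext - unname(rec$signal))), 2 * step)
})
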