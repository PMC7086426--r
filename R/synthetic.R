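# Seeded synthetic EEG cohorts: 1/f^beta background plus band-limited
# oscillations with per-subject and per-channel lognormal amplitude factors,
# neighbor-mixed for spatial correlation. The TBI class attenuates the alpha
# amplitude and boosts the theta amplitude, the direction of the spectral
# biomarkers the detection problem assumes.

#' Specify a synthetic two-class EEG cohort
#'
#' Defaults reproduce the study acquisition geometry: 15 subjects per
#' class, 64 channels (CPz included, excluded downstream), 1000 Hz, 130 s
#' per subject (60 s discard + 60 s analysis + margin).
#' `alpha_attenuation = theta_gain = 1` defines the null cohort; smaller
#' `alpha_attenuation` and larger `theta_gain` increase the class
#' separation (power scales with amplitude squared).
#'
#' @param n_per_class Subjects per class.
#' @param n_channels Channel count; reduced montages always retain Fpz,
#'   AF7, AF8 and CPz.
#' @param fs Sampling rate in Hz.
#' @param duration_s Recording duration in seconds.
#' @param alpha_attenuation Multiplier in (0, 1] on the TBI alpha
#'   amplitude.
#' @param theta_gain Multiplier >= 1 on the TBI theta amplitude.
#' @param subject_variability Coefficient of variation of the per-subject
#'   lognormal band-amplitude factors (default 0.2).
#' @param noise_exponent Spectral slope beta of the 1/f^beta background
#'   (default 1).
#' @param background_rms Background RMS amplitude in microvolts.
#' @param band_amplitudes Named RMS amplitudes (uV) of the delta, theta,
#'   alpha and beta oscillation components.
#' @param seed Integer master seed; every subject's stream derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = 15, n_channels = 64, fs = 1000,
                        duration_s = 130, alpha_attenuation = 1,
                        theta_gain = 1, subject_variability = 0.2,
                        noise_exponent = 1, background_rms = 15,
                        band_amplitudes = c(delta = 8, theta = 6,
                                            alpha = 10, beta = 3),
                        seed = 1) {
  stopifnot(n_per_class >= 1, n_channels >= 4, n_channels <= 64, fs > 0,
            duration_s > 0, alpha_attenuation > 0, alpha_attenuation <= 1,
            theta_gain >= 1, subject_variability >= 0, background_rms >= 0,
            all(c("delta", "theta", "alpha", "beta") %in%
                  names(band_amplitudes)))
  structure(
    list(n_per_class = as.integer(n_per_class),
         n_channels = as.integer(n_channels), fs = fs,
         duration_s = duration_s, alpha_attenuation = alpha_attenuation,
         theta_gain = theta_gain, subject_variability = subject_variability,
         noise_exponent = noise_exponent, background_rms = background_rms,
         band_amplitudes = band_amplitudes, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' @export
#' @method print cohort_spec
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    paste0("Synthetic cohort spec: %d+%d subjects, %d channels @ %g Hz, %g s, ",
           "alpha x%.2f / theta x%.2f (TBI), seed %d\n"),
    x$n_per_class, x$n_per_class, x$n_channels, x$fs, x$duration_s,
    x$alpha_attenuation, x$theta_gain, x$seed))
  invisible(x)
}

montage_subset <- function(n_channels) {
  all <- waveguard_labels()
  if (n_channels >= length(all)) return(all)
  required <- c("Fpz", "AF7", "AF8", "CPz")
  extra <- setdiff(all, required)[seq_len(n_channels - length(required))]
  all[all %in% c(required, extra)]
}

colored_noise <- function(n, fs, shaper) {
  # white Gaussian noise spectrally shaped by shaper(freq) and scaled to
  # unit RMS
  x <- stats::rnorm(n)
  freq <- c(0, seq_len(n - 1)) * fs / n
  freq <- pmin(freq, fs - freq)            # fold to two-sided frequencies
  a <- shaper(freq)
  y <- Re(stats::fft(stats::fft(x) * a, inverse = TRUE) / n)
  s <- stats::sd(y)
  if (s < 1e-12) return(numeric(n))
  y / s
}

band_shaper <- function(low, high, roll = 1) {
  force(low); force(high); force(roll)
  function(f) {
    up <- pmin(pmax((f - (low - roll)) / roll, 0), 1)
    down <- pmin(pmax(((high + roll) - f) / roll, 0), 1)
    sin(up * pi / 2) * sin(down * pi / 2)
  }
}

slope_shaper <- function(beta, f_floor = 0.5) {
  force(beta); force(f_floor)
  function(f) pmax(f, f_floor)^(-beta / 2)
}

subject_seed <- function(spec, class, subject_index) {
  cls_num <- if (class == "tbi") 2L else 1L
  as.integer((as.numeric(spec$seed) * 100003 + cls_num * 49999 +
                subject_index * 7919) %% 2147483647)
}

#' Generate one synthetic subject
#'
#' Per channel: a 1/f^beta background plus delta/theta/alpha/beta
#' band-limited oscillations, with lognormal per-subject (CV
#' `subject_variability`) and per-channel (CV 0.1) amplitude factors. The
#' TBI class multiplies the alpha amplitude by `alpha_attenuation` and the
#' theta amplitude by `theta_gain`. Neighboring channels (in cap order) are
#' mixed for spatial correlation. Deterministic given
#' `(spec$seed, class, subject_index)`.
#'
#' @param spec A [cohort_spec()].
#' @param class `"healthy"` or `"tbi"`.
#' @param subject_index Positive integer within the class.
#' @return An `eeg_recording`.
#' @export
generate_subject <- function(spec, class = c("healthy", "tbi"),
                             subject_index = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  class <- match.arg(class)
  set.seed(subject_seed(spec, class, subject_index))
  labels <- montage_subset(spec$n_channels)
  n_ch <- length(labels)
  n <- round(spec$duration_s * spec$fs)
  bands <- band_definitions()
  osc_names <- c("delta", "theta", "alpha", "beta")

  cv <- spec$subject_variability
  sdlog <- sqrt(log(1 + cv^2))
  subj_fac <- stats::setNames(
    stats::rlnorm(length(osc_names) + 1, meanlog = -sdlog^2 / 2, sdlog = sdlog),
    c(osc_names, "background"))
  ch_sdlog <- sqrt(log(1 + 0.1^2))

  amp <- spec$band_amplitudes[osc_names]
  if (class == "tbi") {
    amp[["alpha"]] <- amp[["alpha"]] * spec$alpha_attenuation
    amp[["theta"]] <- amp[["theta"]] * spec$theta_gain
  }

  bg_sh <- slope_shaper(spec$noise_exponent)
  band_sh <- lapply(osc_names, function(b) {
    rng <- bands[bands$name == b, ]
    band_shaper(rng$low_hz, rng$high_hz)
  })
  names(band_sh) <- osc_names

  sig <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    ch_fac <- stats::rlnorm(length(osc_names) + 1,
                            meanlog = -ch_sdlog^2 / 2, sdlog = ch_sdlog)
    x <- spec$background_rms * subj_fac[["background"]] * ch_fac[1] *
      colored_noise(n, spec$fs, bg_sh)
    for (bi in seq_along(osc_names)) {
      b <- osc_names[bi]
      if (amp[[b]] > 0) {
        x <- x + amp[[b]] * subj_fac[[b]] * ch_fac[bi + 1] *
          colored_noise(n, spec$fs, band_sh[[b]])
      }
    }
    sig[ch, ] <- x
  }

  # spatial correlation: mix each channel with its cap-order neighbors,
  # preserving the per-channel RMS
  if (n_ch >= 3) {
    pre_sd <- apply(sig, 1, stats::sd)
    mixed <- sig
    mixed[2:(n_ch - 1), ] <- sig[2:(n_ch - 1), ] +
      0.4 * sig[1:(n_ch - 2), ] + 0.4 * sig[3:n_ch, ]
    mixed[1, ] <- sig[1, ] + 0.4 * sig[2, ]
    mixed[n_ch, ] <- sig[n_ch, ] + 0.4 * sig[n_ch - 1, ]
    post_sd <- apply(mixed, 1, stats::sd)
    sig <- mixed * (pre_sd / pmax(post_sd, 1e-12))
  }

  recording(sig, fs = spec$fs, channel_labels = labels,
            subject_id = sprintf("%s_%02d", class, subject_index),
            class_label = class)
}

#' Generate a full two-class cohort
#'
#' @param spec A [cohort_spec()].
#' @return A list with `recordings` (length `2 * n_per_class`) and
#'   `manifest` (data.frame of `subject_id`, `class_label`, `seed`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- expand.grid(subject_index = seq_len(spec$n_per_class),
                      class = c("healthy", "tbi"),
                      stringsAsFactors = FALSE)
  recordings <- lapply(seq_len(nrow(grid)), function(i) {
    generate_subject(spec, grid$class[i], grid$subject_index[i])
  })
  manifest <- data.frame(
    subject_id = vapply(recordings, function(r) r$subject_id, ""),
    class_label = vapply(recordings, function(r) r$class_label, ""),
    seed = vapply(seq_len(nrow(grid)), function(i)
      subject_seed(spec, grid$class[i], grid$subject_index[i]), 0L),
    stringsAsFactors = FALSE)
  list(recordings = recordings, manifest = manifest)
}

#' Write / read a cohort directory
#'
#' One file per subject (EDF or the matrix interchange format) plus a
#' tab-delimited `manifest.tsv`.
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param dir Directory (created if missing).
#' @param format `"edf"` or `"matrix"`.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   cohort list.
#' @export
write_cohort <- function(cohort, dir, format = c("edf", "matrix")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "edf") ".edf" else ".tsv"
  files <- vapply(cohort$recordings, function(rec) {
    path <- file.path(dir, paste0(rec$subject_id, ext))
    write_recording(rec, path, format)
    basename(path)
  }, "")
  manifest <- cohort$manifest
  manifest$file <- files
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  recordings <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- load_recording(file.path(dir, manifest$file[i]))
    rec$subject_id <- manifest$subject_id[i]
    rec$class_label <- manifest$class_label[i]
    rec
  })
  list(recordings = recordings, manifest = manifest)
}
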