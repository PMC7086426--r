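# Spectral band power, orthogonalized envelope connectivity, and MRMR
# feature selection used by the feature-engineered comparison pipelines.

#' Clinical frequency band definitions
#'
#' Conventional clinical EEG bands: delta 0.5-4, theta 4-8, alpha 8-13,
#' beta 13-30 (sub-bands beta1 13-18, beta2 18-24, beta3 24-30) and gamma
#' 30-70 Hz (the amplifier passband tops out at 70 Hz). Band power is taken
#' over `[low, high)`.
#'
#' @return data.frame with columns `name`, `low_hz`, `high_hz`.
#' @export
band_definitions <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "beta1", "beta2", "beta3",
             "gamma"),
    low_hz = c(0.5, 4, 8, 13, 13, 18, 24, 30),
    high_hz = c(4, 8, 13, 30, 18, 24, 30, 70),
    stringsAsFactors = FALSE)
}

band_range <- function(band) {
  if (is.character(band)) {
    defs <- band_definitions()
    row <- defs[defs$name == band, ]
    if (nrow(row) != 1) stop("unknown band: ", band, call. = FALSE)
    c(row$low_hz, row$high_hz)
  } else {
    stopifnot(length(band) == 2, band[1] >= 0, band[2] > band[1])
    as.numeric(band)
  }
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: Hann-windowed segments of `nperseg`
#' samples with 50% overlap, density scaling (power per Hz), one-sided.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length (default `min(length(x), fs)` rounded).
#' @return List with `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
welch_psd <- function(x, fs, nperseg = NULL) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(n, round(fs))
  nperseg <- min(as.integer(nperseg), n)
  stopifnot(nperseg >= 8)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(win^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * u * fs)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nperseg %% 2L == 0L) dbl[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1L) * fs / nperseg, psd = psd * dbl)
}

#' Band power of one or more channels
#'
#' Integrated Welch power spectral density over `[low, high)` Hz, per
#' channel, in uV^2.
#'
#' @param x Numeric vector (one channel) or channels-by-samples matrix.
#' @param fs Sampling rate in Hz.
#' @param band Band name (see [band_definitions()]) or `c(low, high)` in Hz.
#' @param channels Optional row subset (indices or labels) when `x` is a
#'   matrix.
#' @param nperseg Welch segment length passed to [welch_psd()].
#' @return Numeric vector of band power per selected channel.
#' @export
band_power <- function(x, fs, band, channels = NULL, nperseg = NULL) {
  rng <- band_range(band)
  if (rng[1] >= fs / 2) {
    stop(sprintf("frequency error: band starts at %g Hz but Nyquist is %g Hz",
                 rng[1], fs / 2), call. = FALSE)
  }
  if (is.matrix(x)) {
    if (!is.null(channels)) x <- x[channels, , drop = FALSE]
    return(apply(x, 1, band_power, fs = fs, band = rng, nperseg = nperseg))
  }
  w <- welch_psd(x, fs, nperseg)
  sel <- w$freq >= rng[1] & w$freq < rng[2]
  df <- w$freq[2] - w$freq[1]
  sum(w$psd[sel]) * df
}

#' Zero-phase band filter
#'
#' Forward-backward Butterworth filtering (order 4). A `low <= 0` bound
#' gives a low-pass, a `high >= Nyquist` bound a high-pass.
#'
#' @param x Numeric vector or channels-by-samples matrix.
#' @param fs Sampling rate in Hz.
#' @param low,high Passband edges in Hz.
#' @param order Butterworth order (default 4).
#' @return Filtered signal, same shape as `x`.
#' @export
filter_band <- function(x, fs, low, high, order = 4) {
  nyq <- fs / 2
  if (low >= nyq) stop("frequency error: low edge at/above Nyquist", call. = FALSE)
  high_capped <- min(high, nyq * 0.999)
  if (low <= 0 && high >= nyq) return(x)
  bf <- if (low <= 0) {
    signal::butter(order, high_capped / nyq, type = "low")
  } else if (high >= nyq) {
    signal::butter(order, low / nyq, type = "high")
  } else {
    signal::butter(order %/% 2, c(low, high_capped) / nyq, type = "pass")
  }
  if (is.matrix(x)) {
    t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Notch filter for mains interference
#'
#' Zero-phase second-order Butterworth band-stop of width `width` Hz around
#' `freq` (default 50 Hz mains). Signals sampled too slowly to contain the
#' mains frequency are returned unchanged.
#'
#' @param x Numeric vector or matrix.
#' @param fs Sampling rate in Hz.
#' @param freq Notch centre frequency in Hz.
#' @param width Full stop-band width in Hz.
#' @return Filtered signal.
#' @export
notch_filter <- function(x, fs, freq = 50, width = 2) {
  nyq <- fs / 2
  if (freq + width / 2 >= nyq) return(x)
  bf <- signal::butter(2, c(freq - width / 2, freq + width / 2) / nyq,
                       type = "stop")
  if (is.matrix(x)) t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  else signal::filtfilt(bf, x)
}

#' Amplitude envelope via the analytic signal
#'
#' Modulus of the FFT-based analytic signal (positive frequencies doubled,
#' negative zeroed).
#'
#' @param x Numeric vector.
#' @return Nonnegative envelope of the same length.
#' @export
amplitude_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Orthogonalized amplitude-envelope connectivity
#'
#' Band-limited connectivity that discounts zero-lag volume conduction:
#' both channels are band-filtered, one is orthogonalized against the other
#' by removing its zero-lag parallel (regression) component, amplitude
#' envelopes are taken via the analytic signal, log-transformed, and
#' correlated. The two orthogonalization directions are averaged. Shared
#' instantaneous activity therefore contributes nothing; the value lies in
#' `[-1, 1]`.
#'
#' @param x,y Numeric vectors of equal length (two channels).
#' @param fs Sampling rate in Hz.
#' @param band Band name or `c(low, high)` Hz.
#' @return Correlation of log envelopes after orthogonalization.
#' @export
envelope_connectivity <- function(x, y, fs, band) {
  stopifnot(length(x) == length(y))
  rng <- band_range(band)
  xb <- filter_band(x, fs, rng[1], rng[2])
  yb <- filter_band(y, fs, rng[1], rng[2])
  one_way <- function(a, b) {
    # component of b parallel to a at zero lag removed
    b_orth <- b - a * (sum(a * b) / sum(a * a))
    ea <- log(pmax(amplitude_envelope(a), 1e-12))
    eb <- log(pmax(amplitude_envelope(b_orth), 1e-12))
    if (stats::sd(ea) < 1e-10 || stats::sd(eb) < 1e-10) {
      stop("undefined correlation: constant envelope", call. = FALSE)
    }
    stats::cor(ea, eb)
  }
  (one_way(xb, yb) + one_way(yb, xb)) / 2
}

# ---- mutual information and MRMR ------------------------------------------

discretize_ef <- function(x, bins = 4) {
  # equal-frequency binning; constant features collapse to one bin
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               type = 7))
  if (length(qs) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = qs, include.lowest = TRUE))
}

mutual_information <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Greedy minimum-redundancy maximum-relevance feature selection
#'
#' Mutual-information MRMR on equal-frequency 4-bin discretized features:
#' the first pick maximizes relevance (MI with the class); each further
#' pick maximizes relevance minus mean redundancy (mean MI with the already
#' selected features). Ties break toward the lower feature index, so the
#' ranking is deterministic. Constant features have zero relevance and are
#' never preferred over informative ones.
#'
#' @param x Numeric feature matrix, observations in rows.
#' @param y Class labels (factor or character).
#' @param n_keep Number of features to select.
#' @param bins Discretization bins (default 4).
#' @return Integer vector of `n_keep` selected column indices, in selection
#'   order.
#' @export
mrmr_select <- function(x, y, n_keep, bins = 4) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= n_keep, length(unique(y)) >= 2)
  disc <- apply(x, 2, discretize_ef, bins = bins)
  y <- as.factor(y)
  relevance <- apply(disc, 2, mutual_information, y = y)
  p <- ncol(x)
  selected <- integer(0)
  red_sum <- numeric(p)
  for (step in seq_len(n_keep)) {
    score <- if (length(selected) == 0) relevance
             else relevance - red_sum / length(selected)
    score[selected] <- -Inf
    pick <- unname(which(score >= max(score) - 1e-12))[1]  # tie -> lowest index
    selected <- c(selected, pick)
    if (step < n_keep) {
      for (j in seq_len(p)) {
        if (!(j %in% selected)) {
          red_sum[j] <- red_sum[j] + mutual_information(disc[, j], disc[, pick])
        }
      }
    }
  }
  selected
}
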