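#' @title Zero-phase FIR filtering
#' @description Filtering uses windowed-sinc (Hamming) linear-phase FIR
#'   designs. Because the impulse response is symmetric, a single pass with
#'   exact group-delay compensation is zero-phase; the signal is extended by
#'   reflection at both ends so the compensation never runs off the data.
#'   The transition band is about 1 Hz wide at the 1 Hz edge, which places
#'   the half-amplitude point of the high-pass exactly at 1 Hz.
#' @name filtering
NULL

# Symmetric-FIR zero-phase filtering of each row of `data`.
fir_zero_phase <- function(data, h) {
  d <- (length(h) - 1L) %/% 2L
  n <- ncol(data)
  apply_one <- function(x) {
    # reflect (without repeating the edge sample) by d each side
    left <- x[pmin(d + 1L, n):2L]
    right <- x[(n - 1L):pmax(n - d, 1L)]
    xp <- c(left, x, right)
    L <- length(xp) + length(h) - 1L
    nf <- stats::nextn(L, 2)
    y <- Re(stats::fft(stats::fft(c(xp, numeric(nf - length(xp)))) *
                         stats::fft(c(h, numeric(nf - length(h)))),
                       inverse = TRUE)) / nf
    # full convolution index of output sample t (1-based, within xp): t + d;
    # xp leads x by d, so y index = (t + d) + d
    y[(2L * d + 1L):(2L * d + n)]
  }
  t(apply(data, 1L, apply_one))
}

# Hamming-windowed sinc low-pass with exactly unit DC gain.
windowed_sinc_lowpass <- function(fs, fc, ord) {
  n <- seq(-ord / 2, ord / 2)
  x <- 2 * fc * n / fs
  h <- (2 * fc / fs) * ifelse(n == 0, 1, sin(pi * x) / (pi * x))
  w <- 0.54 + 0.46 * cos(2 * pi * n / ord)    # Hamming over [-ord/2, ord/2]
  h <- h * w
  h / sum(h)
}

# High-pass by spectral inversion (exact zero at DC); band-pass as the
# difference of two unit-DC low-passes.
fir_design <- function(fs, type = c("high", "pass"), edges,
                       transition_hz = 1) {
  type <- match.arg(type)
  ord <- ceiling(3.3 * fs / transition_hz)
  if (ord %% 2 == 1L) ord <- ord + 1L   # even order -> odd length, type I
  if (type == "high") {
    h <- -windowed_sinc_lowpass(fs, edges[1], ord)
    h[ord / 2 + 1L] <- h[ord / 2 + 1L] + 1
  } else {
    h <- windowed_sinc_lowpass(fs, edges[2], ord) -
      windowed_sinc_lowpass(fs, edges[1], ord)
  }
  h
}

check_filter_length <- function(rec, h) {
  if (n_samples(rec) < 3L * length(h))
    stop(sprintf(paste("recording too short for the filter: %d samples <",
                       "3 x filter length (%d); at %g Hz provide at least",
                       "%.1f s of data"),
                 n_samples(rec), length(h), rec$sample_rate,
                 3 * length(h) / rec$sample_rate))
}

#' High-pass filter at 1 Hz (zero-phase)
#'
#' Removes non-stationary drift and conditions the data for line-noise
#' regression and ICA, which both perform best on 1-2 Hz high-passed EEG.
#'
#' @param rec an `eeg_recording` with `sample_rate > 2`.
#' @param cutoff_hz high-pass edge (default 1 Hz; half-amplitude point).
#' @return the filtered recording, history appended.
#' @export
highpass_filter <- function(rec, cutoff_hz = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$sample_rate <= 2) stop("sampling rate must exceed 2 Hz")
  h <- fir_design(rec$sample_rate, "high", cutoff_hz)
  check_filter_length(rec, h)
  rec <- replace_data(rec, fir_zero_phase(rec$data, h))
  add_history(rec, sprintf("highpass:%gHz", cutoff_hz))
}

#' Band-pass 1-249 Hz for high-rate files, high-pass otherwise
#'
#' Files sampled at 500 Hz or above get a 1-249 Hz zero-phase band-pass so
#' the signal handed to ICA is band-limited; lower-rate files get the plain
#' 1 Hz high-pass.
#'
#' @param rec an `eeg_recording`.
#' @return the filtered recording; history records which branch ran.
#' @export
bandpass_if_high_rate <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$sample_rate >= 500) {
    upper <- min(249, rec$sample_rate / 2 - 1)
    h <- fir_design(rec$sample_rate, "pass", c(1, upper))
    check_filter_length(rec, h)
    rec <- replace_data(rec, fir_zero_phase(rec$data, h))
    rec <- add_history(rec, sprintf("bandpass:1-%gHz", upper))
  } else {
    rec <- highpass_filter(rec)
  }
  rec
}
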