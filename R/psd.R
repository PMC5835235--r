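#' Welch power spectral density
#'
#' Averaged modified periodograms with Hamming windows and 50% overlap.
#' Returned power is a one-sided density in (input unit)^2 / Hz.
#'
#' @param x numeric vector, or channels-x-samples matrix (one PSD per row).
#' @param fs sampling rate in Hz.
#' @param window_sec segment length in seconds (default 2).
#' @return list with `freq` (Hz) and `power` (vector, or channels x freq
#'   matrix for matrix input).
#' @export
welch_psd <- function(x, fs, window_sec = 2) {
  if (is.matrix(x)) {
    out <- apply(x, 1L, function(ch) welch_psd(ch, fs, window_sec)$power)
    f <- welch_psd(x[1L, ], fs, window_sec)$freq
    return(list(freq = f, power = t(out)))
  }
  n <- length(x)
  nper <- min(n, max(8L, round(window_sec * fs)))
  step <- max(1L, floor(nper / 2))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))
  u <- sum(w^2)
  nf <- floor(nper / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)] * w
    X <- stats::fft(seg)[seq_len(nf)]
    acc <- acc + Mod(X)^2
  }
  p <- acc / (length(starts) * u * fs)
  # one-sided: double everything but DC (and Nyquist when nper even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nper %% 2 == 0) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * fs / nper, power = p * dbl)
}

#' Per-channel average log power over a band
#'
#' The summary statistic used for bad-channel detection: each channel's
#' Welch PSD is reduced to the mean log10 power over the band (default
#' 1-125 Hz, clipped to Nyquist - 1 with a warning when the sampling rate
#' is too low).
#'
#' @param rec an `eeg_recording` (at least 2 s long).
#' @param band numeric length-2, band edges in Hz.
#' @param floor_log floor applied to log10 power before averaging, guarding
#'   all-zero (flat) channels (default -12).
#' @return named numeric vector, one value per channel.
#' @export
avg_log_power <- function(rec, band = c(1, 125), floor_log = -12) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_samples(rec) < 2 * rec$sample_rate)
    stop("avg_log_power needs at least 2 s of data")
  nyq <- rec$sample_rate / 2
  if (band[2] > nyq) {
    warning(sprintf("band upper edge %g Hz clipped to Nyquist-1 = %g Hz",
                    band[2], nyq - 1))
    band[2] <- nyq - 1
  }
  psd <- welch_psd(rec$data, rec$sample_rate)
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  vals <- rowMeans(pmax(log10(pmax(psd$power[, sel, drop = FALSE], 0)),
                        floor_log))
  stats::setNames(vals, rec$channel_ids)
}

#' Export the per-channel power spectrum to CSV
#'
#' Writes a frequency-by-channel table of Welch PSD values, the file-based
#' stand-in for on-screen spectrum inspection in semi-automated review.
#'
#' @param rec an `eeg_recording`.
#' @param path output CSV path.
#' @param fmax highest frequency to export (default Nyquist).
#' @return invisibly, `path`.
#' @export
export_psd <- function(rec, path, fmax = NULL) {
  psd <- welch_psd(rec$data, rec$sample_rate)
  sel <- if (is.null(fmax)) rep(TRUE, length(psd$freq)) else psd$freq <= fmax
  df <- data.frame(freq_hz = psd$freq[sel],
                   t(psd$power[, sel, drop = FALSE]))
  names(df)[-1] <- rec$channel_ids
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
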