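#' @title Wavelet-enhanced ICA (W-ICA)
#' @description Before component rejection, every ICA component time series
#'   is cleaned by stationary (undecimated) wavelet thresholding: large
#'   coefficients that survive a robust universal threshold are taken as
#'   the artifact stream, reconstructed, and subtracted, so whole components
#'   are never removed at this stage. The Coiflet order-5 filter bank is
#'   used, with the decomposition depth chosen so the detail bands span
#'   roughly 8-125 Hz; the sub-8 Hz approximation band is thresholded with
#'   the same global threshold, which is what lets high-amplitude
#'   low-frequency transients (blinks, discontinuities) enter the artifact
#'   stream.
#' @name wica
NULL

# Coiflet order-5 analysis low-pass filter (30 taps, orthonormal:
# sum = sqrt(2)). Standard published filter bank.
coif5_dec_lo <- c(
  -9.604010112767894e-08, -1.6237995172048338e-07, 2.0612203985788783e-06,
  3.7007277113394796e-06, -2.1270221672515614e-05, -4.12198619242655e-05,
  1.4035632812373243e-04, 3.018579416682448e-04, -6.375589261258812e-04,
  -1.6616273039298788e-03, 2.4315754425382886e-03, 6.761520220620417e-03,
  -9.159507338676163e-03, -1.9758391600965465e-02, 3.2674799467057355e-02,
  4.1287530472117834e-02, -1.0556315130733723e-01, -6.203775157498196e-02,
  4.379823066591634e-01, 7.742936228603274e-01, 4.2157126673075435e-01,
  -5.2046670253554764e-02, -9.192158806008609e-02, 2.8169744270532353e-02,
  2.3408322118927783e-02, -1.0131584846900276e-02, -4.15931262757864e-03,
  2.1782943778456947e-03, 3.585777411617577e-04, -2.12081862067494e-04)

# quadrature-mirror high-pass from the low-pass
qmf_highpass <- function(lo) rev(lo) * (-1)^(seq_along(lo) - 1)

# DFTs of the level-l a-trous filters (upsampled by 2^(l-1)), length m.
atrous_filter_ffts <- function(lo, levels, m) {
  hi <- qmf_highpass(lo)
  lapply(seq_len(levels), function(l) {
    up <- 2^(l - 1)
    pos <- 1L + (seq_along(lo) - 1L) * up
    if (max(pos) > m)
      stop("signal too short for ", levels, " stationary wavelet levels")
    hl <- numeric(m); hl[pos] <- lo
    gl <- numeric(m); gl[pos] <- hi
    list(H = stats::fft(hl), G = stats::fft(gl))
  })
}

#' Stationary wavelet transform (Coiflet-5 a trous)
#'
#' Undecimated, shift-invariant decomposition into `levels` detail bands
#' plus an approximation, computed by circular convolution with upsampled
#' filters. The signal is symmetrically padded to the next multiple of
#' `2^levels`; [iswt_coif5()] inverts the transform exactly.
#'
#' @param x numeric vector.
#' @param levels decomposition depth (>= 1).
#' @return list with `details` (list of length `levels`, finest first),
#'   `approx`, `n` (original length), all at padded length.
#' @export
swt_coif5 <- function(x, levels) {
  stopifnot(levels >= 1)
  n <- length(x)
  m <- as.integer(ceiling(n / 2^levels) * 2^levels)
  pad <- m - n
  if (pad >= n) stop("signal too short for ", levels, " wavelet levels")
  xp <- if (pad > 0) c(x, x[n:(n - pad + 1L)]) else x
  filts <- atrous_filter_ffts(coif5_dec_lo, levels, m)
  a_hat <- stats::fft(xp)
  details <- vector("list", levels)
  for (l in seq_len(levels)) {
    details[[l]] <- Re(stats::fft(a_hat * filts[[l]]$G, inverse = TRUE)) / m
    a_hat <- a_hat * filts[[l]]$H
  }
  list(details = details, approx = Re(stats::fft(a_hat, inverse = TRUE)) / m,
       n = n)
}

#' Inverse stationary wavelet transform
#'
#' @param sw a list as returned by [swt_coif5()] (details may have been
#'   modified; set `approx` to zeros to reconstruct detail content only).
#' @return numeric vector of length `sw$n`.
#' @export
iswt_coif5 <- function(sw) {
  levels <- length(sw$details)
  m <- length(sw$approx)
  filts <- atrous_filter_ffts(coif5_dec_lo, levels, m)
  a_hat <- stats::fft(sw$approx)
  for (l in rev(seq_len(levels))) {
    d_hat <- stats::fft(sw$details[[l]])
    a_hat <- (Conj(filts[[l]]$H) * a_hat + Conj(filts[[l]]$G) * d_hat) / 2
  }
  Re(stats::fft(a_hat, inverse = TRUE))[seq_len(sw$n)] / m
}

#' Robust universal threshold
#'
#' The Donoho-Johnstone universal threshold with a robust noise-scale
#' estimate: `T = (median(|D|) / 0.6745) * sqrt(2 * log(N))`, where `D` are
#' detail coefficients and `N` is the signal length. For Gaussian noise,
#' `median(|D|)/0.6745` estimates its standard deviation.
#'
#' @param D numeric vector of detail coefficients (nonempty).
#' @param N signal length (>= 2).
#' @return the threshold (0 when `D` is all zeros).
#' @export
universal_threshold <- function(D, N) {
  stopifnot(length(D) >= 1, N >= 2)
  (stats::median(abs(D)) / 0.6745) * sqrt(2 * log(N))
}

#' Soft thresholding
#'
#' @param c numeric coefficients.
#' @param T threshold (>= 0).
#' @return `sign(c) * pmax(abs(c) - T, 0)`.
#' @export
soft_threshold <- function(c, T) {
  stopifnot(T >= 0)
  sign(c) * pmax(abs(c) - T, 0)
}

# default depth: deepest detail band's lower edge ~ 8 Hz
wica_default_depth <- function(fs) max(1L, as.integer(round(log2(fs / 16))))

#' Wavelet-enhanced ICA artifact subtraction
#'
#' Runs extended Infomax ICA, wavelet-thresholds every component, takes the
#' content surviving the threshold as the artifact time series, remixes it
#' to channel space and subtracts it. Nothing is removed outright: the
#' cleaned and artifact recordings sum back to the input sample-exactly.
#'
#' @param rec a filtered, line-cleaned `eeg_recording` with bad channels
#'   already removed.
#' @param seed ICA seed.
#' @param depth stationary-wavelet depth (default `round(log2(fs/16))`, so
#'   the detail bands span about 8-125 Hz).
#' @param threshold override the automatic global threshold (e.g. `Inf`
#'   for a no-op, `0` to take the entire centered signal as artifact).
#' @param per_component compute one threshold per component instead of one
#'   global threshold from all components' finest-level coefficients
#'   (default `FALSE`).
#' @param dec optionally, a precomputed `eeg_decomposition` of `rec`.
#' @return list with `cleaned` and `artifact` (`eeg_recording`s), the
#'   `decomposition`, and `threshold` used.
#' @export
wica_clean <- function(rec, seed, depth = NULL, threshold = NULL,
                       per_component = FALSE, dec = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(depth)) depth <- wica_default_depth(rec$sample_rate)
  if (is.null(dec)) dec <- run_extended_infomax(rec, seed)
  S <- dec$sources
  r <- nrow(S); N <- ncol(S)
  sws <- lapply(seq_len(r), function(i) swt_coif5(S[i, ], depth))
  if (is.null(threshold)) {
    if (per_component) {
      thr <- vapply(sws, function(sw) universal_threshold(sw$details[[1L]], N),
                    numeric(1))
    } else {
      d1 <- unlist(lapply(sws, function(sw) sw$details[[1L]]))
      thr <- rep(universal_threshold(d1, N), r)
    }
  } else thr <- rep(threshold, length.out = r)
  art_src <- matrix(0, r, N)
  for (i in seq_len(r)) {
    # every band is soft-thresholded, approximation included: the content
    # surviving the threshold in any band is artifact, so T = Inf leaves
    # the input untouched and T = 0 takes all of it as artifact
    sw <- sws[[i]]
    sw$details <- lapply(sw$details, soft_threshold, T = thr[i])
    sw$approx <- soft_threshold(sw$approx, thr[i])
    art_src[i, ] <- iswt_coif5(sw)
  }
  art_ch <- dec$mixing %*% art_src
  artifact <- rec
  artifact$data <- art_ch
  rownames(artifact$data) <- rec$channel_ids
  artifact <- add_history(artifact, "wica:artifact")
  cleaned <- replace_data(rec, rec$data - art_ch)
  cleaned <- add_history(cleaned, sprintf("wica:depth%d", depth))
  list(cleaned = cleaned, artifact = artifact, decomposition = dec,
       threshold = thr)
}
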