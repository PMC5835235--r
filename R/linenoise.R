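#' @title Multitaper sinusoid-regression line-noise removal
#' @description Electrical line noise (50/60 Hz) is removed by fitting a
#'   deterministic sinusoid per sliding window with multitaper regression
#'   rather than notch filtering, which would also remove genuine EEG power
#'   at neighbouring frequencies. In each 4-s window (1-s step) the exact
#'   line frequency is located within +/- 2 Hz of the user-specified target
#'   by maximizing the Thomson F-statistic on a fine frequency grid; if the
#'   sinusoid regression coefficient is significant at p < 0.01 the fitted
#'   sinusoid is reconstructed and subtracted. Overlapping window
#'   contributions are blended with steep sigmoidal weights (tau = 100)
#'   across the 3-s overlap.
#' @name line_noise
NULL

#' Line-noise removal configuration
#'
#' @param target_freq line frequency to remove, Hz (60 in the Americas,
#'   50 elsewhere).
#' @param scan_halfwidth half-width of the frequency scan around the target
#'   (Hz, default 2).
#' @param window_len sliding-window length in seconds (default 4).
#' @param step window step in seconds (default 1).
#' @param smoothing_tau steepness of the sigmoidal overlap-blending weights
#'   (dimensionless, default 100; larger is closer to a hard hand-over at
#'   the overlap midpoint).
#' @param p_threshold significance level for the sinusoid regression
#'   coefficient (default 0.01).
#' @param harmonics frequencies to process (default just `target_freq`;
#'   each entry is scanned and regressed independently).
#' @param scan_resolution frequency-grid spacing of the scan, Hz
#'   (default 0.05).
#' @param nw multitaper time-bandwidth product (default 4, giving a 2 Hz
#'   taper bandwidth over the 4-s window); `2*nw - 1` Slepian tapers are
#'   used.
#' @return list of class `line_noise_config`.
#' @export
line_noise_config <- function(target_freq = 60, scan_halfwidth = 2,
                              window_len = 4, step = 1,
                              smoothing_tau = 100, p_threshold = 0.01,
                              harmonics = NULL, scan_resolution = 0.05,
                              nw = 4) {
  stopifnot(step > 0, step <= window_len, p_threshold > 0, p_threshold < 1,
            scan_halfwidth > 0)
  structure(list(target_freq = target_freq, scan_halfwidth = scan_halfwidth,
                 window_len = window_len, step = step,
                 smoothing_tau = smoothing_tau, p_threshold = p_threshold,
                 harmonics = if (is.null(harmonics)) target_freq else harmonics,
                 scan_resolution = scan_resolution, nw = nw),
            class = "line_noise_config")
}

# ---- Slepian tapers ------------------------------------------------------
# Discrete prolate spheroidal sequences via the standard symmetric
# tridiagonal eigenproblem; cached per (n, nw, k) for the session.
.taper_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .taper_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  i <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  diag_off <- (seq_len(n - 1) * (n - seq_len(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diag_main
  A[cbind(seq_len(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, seq_len(n - 1))] <- diag_off
  eg <- eigen(A, symmetric = TRUE)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  # unit energy; fix sign so symmetric tapers have positive mean and
  # antisymmetric tapers start positive
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    s <- sum(v[, j])
    if (abs(s) > 1e-8) { if (s < 0) v[, j] <- -v[, j] }
    else if (v[1, j] < 0) v[, j] <- -v[, j]
  }
  .taper_cache[[key]] <- v
  v
}

# Thomson F-test for a deterministic sinusoid at each frequency of `grid`
# in windowed data `x` (length n). `ph` is the precomputed nf x n matrix of
# complex exponentials exp(-2i pi f t / fs). Returns list(amp, F, p).
mt_sinusoid_scan <- function(x, grid, tapers, ph) {
  k <- ncol(tapers)
  tx <- tapers * x                       # n x k tapered copies
  J <- ph %*% tx                         # nf x k eigencoefficients
  U0 <- colSums(tapers)                  # taper DC values
  su2 <- sum(U0^2)
  mu <- as.vector(J %*% U0) / su2        # complex amplitude estimate
  resid <- Mod(J - outer(mu, U0))^2
  Fstat <- (k - 1) * Mod(mu)^2 * su2 / pmax(rowSums(resid), 1e-300)
  p <- stats::pf(Fstat, 2, 2 * (k - 1), lower.tail = FALSE)
  list(freq = grid, amp = mu, F = Fstat, p = p)
}

#' Remove line noise by multitaper sinusoid regression
#'
#' @param rec an `eeg_recording` (at least one window long).
#' @param cfg a [line_noise_config()].
#' @return the cleaned recording, history appended.
#' @export
remove_line_noise <- function(rec, cfg = line_noise_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate
  nyq <- fs / 2
  for (f0 in cfg$harmonics) {
    if (f0 >= nyq - cfg$scan_halfwidth)
      stop(sprintf("target frequency %g Hz is too close to Nyquist %g Hz",
                   f0, nyq))
  }
  nwin <- round(cfg$window_len * fs)
  nstep <- round(cfg$step * fs)
  n <- n_samples(rec)
  if (nwin > n)
    stop(sprintf("recording (%d samples) shorter than one %g-s window",
                 n, cfg$window_len))
  tapers <- dpss_tapers(nwin, cfg$nw)
  starts <- seq(1L, n - nwin + 1L, by = nstep)
  if (starts[length(starts)] + nwin - 1L < n)      # cover the tail
    starts <- c(starts, n - nwin + 1L)
  overlap <- max(nwin - nstep, 1L)
  wprof <- window_weight_profile(nwin, overlap, cfg$smoothing_tau)
  # the first/last windows have no neighbour across their outer edge, so
  # they keep full weight there instead of ramping to zero
  wprof_first <- window_weight_profile(nwin, overlap, cfg$smoothing_tau,
                                       ramp_up = FALSE)
  wprof_last <- window_weight_profile(nwin, overlap, cfg$smoothing_tau,
                                      ramp_down = FALSE)
  profile_for <- function(s) {
    if (length(starts) == 1L) rep(1, nwin)
    else if (s == starts[1L]) wprof_first
    else if (s == starts[length(starts)]) wprof_last
    else wprof
  }
  data <- rec$data
  tsec <- (seq_len(nwin) - 1) / fs
  for (f0 in cfg$harmonics) {
    grid <- seq(f0 - cfg$scan_halfwidth, f0 + cfg$scan_halfwidth,
                by = cfg$scan_resolution)
    grid <- grid[grid > 0 & grid < nyq]
    ph <- exp(-2i * pi * outer(grid, seq_len(nwin) - 1) / fs)
    for (ci in seq_len(nrow(data))) {
      x <- data[ci, ]
      # stage 1: scan each window for the exact line frequency
      found <- numeric(0)
      for (s in starts) {
        scan <- mt_sinusoid_scan(x[s:(s + nwin - 1L)], grid, tapers, ph)
        best <- which(scan$F == max(scan$F))
        if (length(best) > 1L)           # tie-break to nearest target
          best <- best[which.min(abs(grid[best] - f0))]
        if (scan$p[best] < cfg$p_threshold) found <- c(found, grid[best])
      }
      if (!length(found)) next           # no significant line on this channel
      # stage 2: one consensus frequency per channel keeps the fitted
      # sinusoid phase-coherent across windows (per-window scan jitter
      # would otherwise leave sidebands around the line)
      fstar <- stats::median(found)
      ph1 <- exp(-2i * pi * fstar * (seq_len(nwin) - 1) / fs)
      fit_acc <- numeric(n)
      w_acc <- numeric(n)
      for (s in starts) {
        idx <- s:(s + nwin - 1L)
        scan <- mt_sinusoid_scan(x[idx], fstar, tapers, rbind(ph1))
        if (scan$p[1] < cfg$p_threshold) {
          fit <- 2 * Re(scan$amp[1] * exp(2i * pi * fstar * tsec))
          wp <- profile_for(s)
          fit_acc[idx] <- fit_acc[idx] + wp * fit
          w_acc[idx] <- w_acc[idx] + wp
        }
      }
      nz <- w_acc > 1e-12
      x[nz] <- x[nz] - fit_acc[nz] / w_acc[nz]
      data[ci, ] <- x
    }
  }
  rec <- replace_data(rec, data)
  add_history(rec, sprintf("linenoise:%s",
                           paste(cfg$harmonics, collapse = "+")))
}

# Sigmoidal weight profile over one window: ramps up across the leading
# overlap and down across the trailing overlap; tau sets the steepness.
window_weight_profile <- function(nwin, overlap, tau, ramp_up = TRUE,
                                  ramp_down = TRUE) {
  sig <- function(u) 1 / (1 + exp(-tau * (u - 0.5)))
  t <- seq_len(nwin) - 1
  up <- if (ramp_up) sig(pmin(t / overlap, 1)) else rep(1, nwin)
  down <- if (ramp_down) sig(pmin((nwin - 1 - t) / overlap, 1))
          else rep(1, nwin)
  w <- up * down
  w / max(w)
}
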