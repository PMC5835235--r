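#' @title Component artifact features
#' @description Each ICA component is summarized by six features spanning
#'   temporal (local skewness), spectral (alpha power, 1/f fit slope and fit
#'   error) and spatial (scalp-map range, current-density norm) information,
#'   the feature set used by automated artifact classifiers trained on
#'   manual component labels. Spatial features read the component's scalp
#'   map from the mixing-matrix rows of the 19 10-20 anchor channels.
#' @name component_features
NULL

sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 < 1e-24) return(0)   # zero-variance windows have no shape
  mean((x - m)^3) / m2^1.5
}

#' Mean local skewness of a component time series
#'
#' Mean over consecutive 15-s windows of the absolute sample skewness;
#' sensitive to sparse high-amplitude transients such as blinks or
#' electrode pops. A trailing partial window of at least 5 s is included,
#' shorter remainders are dropped.
#'
#' @param source numeric component time series.
#' @param fs sampling rate in Hz.
#' @param window_sec window length (default 15 s).
#' @param min_tail_sec minimum trailing-window length (default 5 s).
#' @return scalar feature value (>= 0).
#' @export
mean_local_skewness <- function(source, fs, window_sec = 15,
                                min_tail_sec = 5) {
  n <- length(source)
  w <- round(window_sec * fs)
  if (n < w) {
    if (n < min_tail_sec * fs) stop("component shorter than one window")
    return(abs(sample_skewness(source)))
  }
  starts <- seq(1L, n - w + 1L, by = w)
  vals <- vapply(starts, function(s) abs(sample_skewness(source[s:(s + w - 1L)])),
                 numeric(1))
  tail_start <- starts[length(starts)] + w
  if (n - tail_start + 1L >= min_tail_sec * fs)
    vals <- c(vals, abs(sample_skewness(source[tail_start:n])))
  mean(vals)
}

#' Average log alpha-band power of a component
#'
#' Mean log10 Welch PSD over 8-13 Hz. Brain components typically carry
#' robust alpha power; artifact components do not.
#'
#' @param source numeric component time series.
#' @param fs sampling rate in Hz (> 26).
#' @param floor_log log10 floor (default -12).
#' @return scalar feature value.
#' @export
log_alpha_power <- function(source, fs, floor_log = -12) {
  if (fs <= 26) stop("sampling rate too low for the alpha band")
  psd <- welch_psd(source, fs)
  sel <- psd$freq >= 8 & psd$freq <= 13
  mean(pmax(log10(pmax(psd$power[sel], 0)), floor_log))
}

#' Fit of the 1/f spectral prototype
#'
#' Samples the component's log10 PSD at six frequencies spanning the
#' spectrum (default 2, 5, 8, 13, 30, 75 Hz) and fits
#' `log10 P = a - lambda * log10 f`. `lambda` measures how closely the
#' spectrum follows the prototypical 1/f shape of cerebral components
#' (muscle activity yields small or negative lambda); `fit_error` is the
#' mean squared residual of the fitted line against the observed
#' log-spectrum restricted to 8-15 Hz, the alpha-to-beta transition.
#'
#' @param source numeric component time series.
#' @param fs sampling rate in Hz; below 160 Hz the highest sample frequency
#'   is clipped to Nyquist - 5.
#' @param sample_freqs the six sampled frequencies (configurable).
#' @param floor_log log10 floor (default -12).
#' @return list with `lambda` and `fit_error`.
#' @export
fit_one_over_f <- function(source, fs,
                           sample_freqs = c(2, 5, 8, 13, 30, 75),
                           floor_log = -12) {
  nyq <- fs / 2
  sample_freqs <- pmin(sample_freqs, nyq - 5)
  sample_freqs <- sort(unique(sample_freqs))
  psd <- welch_psd(source, fs)
  logp <- pmax(log10(pmax(psd$power, 0)), floor_log)
  at <- vapply(sample_freqs,
               function(f) logp[which.min(abs(psd$freq - f))], numeric(1))
  fit <- stats::lm.fit(cbind(1, -log10(sample_freqs)), at)
  a <- fit$coefficients[1]; lambda <- fit$coefficients[2]
  band <- psd$freq >= 8 & psd$freq <= 15 & psd$freq > 0
  pred <- a - lambda * log10(psd$freq[band])
  list(lambda = unname(lambda),
       fit_error = mean((logp[band] - pred)^2))
}

#' Log range of a scalp map
#'
#' The log difference between the largest and smallest activation of the
#' unit-norm scalp map. Focal artifact maps (single-electrode spikes, eye
#' patterns) have large ranges; smooth cerebral maps have small ones.
#'
#' @param scalp_map numeric vector of per-channel activations (finite).
#' @param floor_range range floor guarding degenerate maps (default 1e-12).
#' @return scalar feature value.
#' @export
range_within_pattern <- function(scalp_map, floor_range = 1e-12) {
  if (!all(is.finite(scalp_map))) stop("scalp map has non-finite entries")
  v <- scalp_map / sqrt(sum(scalp_map^2))
  log(max(max(v) - min(v), floor_range))
}

# ---- Single-sphere head model -------------------------------------------

# Surface potential on a unit sphere (sigma = 1) from a dipole at position
# `p` (|p| < 1) with moment `mom`, evaluated at unit-vector electrode rows
# `elec`: Legendre series of the analytic homogeneous-sphere solution.
sphere_dipole_potential <- function(elec, p, mom, nmax = 50) {
  b <- sqrt(sum(p^2))
  if (b < 1e-9) return(numeric(nrow(elec)))
  ph <- p / b
  cosg <- pmin(pmax(elec %*% ph, -1), 1)
  # tangential unit vector at each electrode (in the p-electrode plane)
  tang <- elec - outer(as.vector(cosg), ph)
  tn <- sqrt(rowSums(tang^2))
  tang[tn > 1e-9, ] <- tang[tn > 1e-9, , drop = FALSE] / tn[tn > 1e-9]
  tang[tn <= 1e-9, ] <- 0
  m_r <- sum(mom * ph)
  m_t <- as.vector(tang %*% mom)
  x <- as.vector(cosg)
  sing <- sqrt(pmax(0, 1 - x^2))
  v <- numeric(nrow(elec))
  pm1 <- rep(1, length(x)); pn <- x          # P_0, P_1
  dpm1 <- rep(0, length(x)); dpn <- rep(1, length(x))  # P'_0, P'_1
  for (n in seq_len(nmax)) {
    p1n <- -sing * dpn                        # associated P_n^1
    v <- v + b^(n - 1) * ((2 * n + 1) / n) * (n * m_r * pn - m_t * p1n)
    # recurrences for P_{n+1} and its derivative
    pnext <- ((2 * n + 1) * x * pn - n * pm1) / (n + 1)
    dnext <- ((2 * n + 1) * (pn + x * dpn) - n * dpm1) / (n + 1)
    pm1 <- pn; pn <- pnext
    dpm1 <- dpn; dpn <- dnext
  }
  v / (4 * pi)
}

# deterministic Fibonacci lattice on the full sphere
sphere_lattice <- function(n, radius = 1) {
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  az <- 2 * pi * i / golden
  r <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(x = r * cos(az), y = r * sin(az), z = z)
}

#' Build a single-sphere head model for the 10-20 anchor channels
#'
#' A minimal distributed source space: `n_dipoles` grid sites on a shell of
#' radius `shell` inside the unit sphere, three orthogonal orientations
#' each, with the analytic homogeneous-sphere leadfield evaluated at the
#' montage's 10-20 electrode positions and average-referenced.
#'
#' @param montage an `eeg_montage` (10-20 anchor positions are used).
#' @param n_dipoles grid size (default 200).
#' @param shell grid radius (default 0.8).
#' @param alpha_scale regularization: `alpha = alpha_scale *
#'   trace(L L^T) / n_channels` (default 1e-4).
#' @return list of class `eeg_head_model`: `leadfield` (channels x
#'   3*n_dipoles), `channels`, `grid`, `alpha`.
#' @export
build_head_model <- function(montage, n_dipoles = 200, shell = 0.8,
                             alpha_scale = 1e-4) {
  labels <- names(montage$ten_twenty)
  ids <- ten_twenty_ids(montage)
  elec <- montage$positions[ids, , drop = FALSE]
  grid <- sphere_lattice(n_dipoles, shell)
  L <- matrix(0, nrow(elec), 3L * n_dipoles)
  for (d in seq_len(n_dipoles)) {
    for (o in 1:3) {
      mom <- c(0, 0, 0); mom[o] <- 1
      L[, 3L * (d - 1L) + o] <- sphere_dipole_potential(elec, grid[d, ], mom)
    }
  }
  L <- sweep(L, 2L, colMeans(L))        # average reference
  alpha <- alpha_scale * sum(L * L) / nrow(elec)
  structure(list(leadfield = L, channels = labels, channel_ids = ids,
                 grid = grid, alpha = alpha),
            class = "eeg_head_model")
}

#' Current density norm of a scalp map
#'
#' Log norm of the minimum-norm distributed source estimate explaining the
#' (unit-norm, average-referenced) scalp map:
#' `j = L^T (L L^T + alpha I)^-1 v`. Dipolar, brain-like maps are explained
#' by small source currents; non-dipolar artifact maps need overly complex
#' source models and return large values.
#'
#' @param scalp_map numeric vector over the head model's channels.
#' @param head an `eeg_head_model` from [build_head_model()].
#' @return scalar feature value (`log ||j||`).
#' @export
current_density_norm <- function(scalp_map, head) {
  stopifnot(inherits(head, "eeg_head_model"))
  if (length(scalp_map) != nrow(head$leadfield))
    stop("scalp map length does not match the head model's channels")
  nrm <- sqrt(sum(scalp_map^2))
  if (nrm < 1e-12) stop("degenerate (all-zero) scalp map")
  v <- scalp_map / nrm
  v <- v - mean(v)                      # match the leadfield's reference
  if (sum(v^2) < 1e-18) return(log(1e-12))  # constant map: no field at all
  L <- head$leadfield
  M <- tcrossprod(L) + diag(head$alpha, nrow(L))
  j <- crossprod(L, solve(M, v))
  log(sqrt(sum(j^2)))
}
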