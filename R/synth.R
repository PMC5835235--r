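#' @title Seeded synthetic EEG with ground truth
#' @description Every stage of the pipeline is testable without external
#'   data through a generator that emits recordings as an exact sum of a
#'   clean signal (1/f background plus dipolar narrowband neural sources)
#'   and labeled artifacts: frontal biphasic blinks, temporal EMG bursts,
#'   line noise, slow drift, and dead or noisy channels. The ground-truth
#'   object returns the clean matrix, per-artifact masks and channel
#'   footprints, and the planted bad channels, all sample-exact; all
#'   randomness flows from a single seed.
#' @name synthetic_eeg
NULL

#' Specification for a synthetic recording
#'
#' Defaults emulate a developmental resting-state acquisition: moderate-
#' density montage, 250 Hz, heavily blink- and EMG-contaminated, with line
#' noise on every channel. Amplitudes are in microvolts.
#'
#' @param n_channels number of channels (default 39: the 19 10-20 anchors
#'   plus 20 additional lattice sites of the 128-channel layout).
#' @param fs sampling rate in Hz (default 250).
#' @param duration_sec recording length in seconds (default 120).
#' @param montage an `eeg_montage`; default `sphere128`.
#' @param channels labels to include; default the 19 mapped 10-20 ids plus
#'   the first additional lattice sites up to `n_channels`.
#' @param background list: `exponent` of the 1/f background (default 1) and
#'   `amplitude` (RMS microvolts per channel, default 10).
#' @param sensor_noise_uv RMS of the white amplifier/sensor noise floor
#'   added to every channel (default 4; high-impedance developmental
#'   recordings sit at the upper end of typical sensor noise).
#' @param n_neural number of dipolar narrowband neural sources (default 4,
#'   one of them a 10 Hz alpha source).
#' @param blink_rate blinks per minute (default 10; 0 disables).
#' @param blink_amp_uv peak blink amplitude (default 150).
#' @param emg_rate EMG bursts per minute (default 6; 0 disables).
#' @param emg_amp_uv EMG burst RMS amplitude (default 30).
#' @param line_freq line-noise frequency (default 60; NA disables).
#' @param line_amp_uv line-noise amplitude (default 20).
#' @param drift_amp_uv slow (< 0.5 Hz) drift RMS amplitude (default 50;
#'   0 disables).
#' @param flat_channels labels to render flat/dead (default none).
#' @param noisy_channels labels to contaminate with broadband noise
#'   (default none).
#' @param noisy_amp_uv RMS of the added broadband noise (default 100).
#' @param seed integer seed driving all randomness.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_channels = 39, fs = 250, duration_sec = 120,
                       montage = load_montage("sphere128"),
                       channels = NULL,
                       background = list(exponent = 1, amplitude = 10),
                       sensor_noise_uv = 4,
                       n_neural = 4,
                       blink_rate = 10, blink_amp_uv = 150,
                       emg_rate = 6, emg_amp_uv = 30,
                       line_freq = 60, line_amp_uv = 20,
                       drift_amp_uv = 50,
                       flat_channels = character(),
                       noisy_channels = character(),
                       noisy_amp_uv = 100,
                       seed = 1) {
  if (is.null(channels)) {
    anchors <- ten_twenty_ids(montage)
    extra <- setdiff(rownames(montage$positions), anchors)
    if (n_channels < length(anchors))
      stop("n_channels must cover at least the 19 10-20 anchors")
    channels <- c(anchors, extra[seq_len(n_channels - length(anchors))])
  }
  structure(list(n_channels = length(channels), fs = fs,
                 duration_sec = duration_sec, montage = montage,
                 channels = channels, background = background,
                 sensor_noise_uv = sensor_noise_uv,
                 n_neural = n_neural,
                 blink_rate = blink_rate, blink_amp_uv = blink_amp_uv,
                 emg_rate = emg_rate, emg_amp_uv = emg_amp_uv,
                 line_freq = line_freq, line_amp_uv = line_amp_uv,
                 drift_amp_uv = drift_amp_uv,
                 flat_channels = flat_channels,
                 noisy_channels = noisy_channels,
                 noisy_amp_uv = noisy_amp_uv, seed = seed),
            class = "synth_spec")
}

# colored noise with power spectrum ~ 1/f^exponent, unit RMS
colored_noise <- function(n, fs, exponent) {
  nf <- n %/% 2 + 1L
  f <- (seq_len(nf) - 1L) * fs / n
  gain <- c(0, 1 / f[-1]^(exponent / 2))
  re <- stats::rnorm(nf); im <- stats::rnorm(nf)
  spec <- complex(real = re, imaginary = im) * gain
  spec[1] <- 0
  full <- c(spec, Conj(rev(spec[2:(n - nf + 1L)])))
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}

# band-limited noise, unit RMS
band_noise <- function(n, fs, lo, hi) {
  nf <- n %/% 2 + 1L
  f <- (seq_len(nf) - 1L) * fs / n
  gain <- as.numeric(f >= lo & f <= hi)
  re <- stats::rnorm(nf); im <- stats::rnorm(nf)
  spec <- complex(real = re, imaginary = im) * gain
  full <- c(spec, Conj(rev(spec[2:(n - nf + 1L)])))
  x <- Re(stats::fft(full, inverse = TRUE))
  s <- stats::sd(x)
  if (s < 1e-12) return(numeric(n))
  x / s
}

# biphasic blink template: positive lobe then smaller negative rebound
blink_template <- function(n) {
  t <- seq(0, 1, length.out = n)
  lobe1 <- sin(pi * pmin(t / 0.6, 1))^2
  lobe2 <- -0.3 * sin(pi * pmax((t - 0.6) / 0.4, 0))^2
  lobe1 + lobe2
}

# spatial footprint decaying with scalp distance from a reference direction
footprint_from <- function(montage, channels, direction, sharpness = 6) {
  pos <- montage$positions[channels, , drop = FALSE]
  d <- as.vector(pos %*% (direction / sqrt(sum(direction^2))))
  w <- exp(sharpness * (d - 1))
  w / max(w)
}

#' Generate a synthetic recording with ground truth
#'
#' @param spec a [synth_spec()].
#' @return list with `recording` (an `eeg_recording`) and `truth`: `clean`
#'   matrix, `artifacts` (named list of channels x samples matrices that
#'   sum with `clean` to the emitted data exactly), `masks` (per-artifact
#'   logical sample masks), `footprints` (per-artifact channel weights),
#'   and `bad_channels`.
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  fs <- spec$fs
  n <- as.integer(round(spec$duration_sec * fs))
  chans <- spec$channels
  C <- length(chans)
  montage <- spec$montage
  pos <- montage$positions[chans, , drop = FALSE]

  # clean background: independent 1/f noise plus the sensor-noise floor.
  # Per-channel gain jitter (+/-10%) emulates electrode gain/impedance
  # heterogeneity; without it channel powers are unrealistically identical.
  gain <- stats::runif(C, 0.9, 1.1)
  clean <- t(vapply(seq_len(C), function(i)
    gain[i] * (spec$background$amplitude *
                 colored_noise(n, fs, spec$background$exponent) +
               spec$sensor_noise_uv * stats::rnorm(n)),
    numeric(n)))
  # dipolar narrowband neural sources
  if (spec$n_neural > 0) {
    head_grid <- sphere_lattice(64, 0.8)
    for (k in seq_len(spec$n_neural)) {
      f0 <- if (k == 1) 10 else stats::runif(1, 4, 25)
      bw <- stats::runif(1, 1, 3)
      src <- band_noise(n, fs, f0 - bw / 2, f0 + bw / 2)
      dip <- head_grid[sample.int(64, 1), ]
      mom <- stats::rnorm(3); mom <- mom / sqrt(sum(mom^2))
      map <- sphere_dipole_potential(pos, dip, mom)
      map <- map / max(abs(map))
      amp <- stats::runif(1, 3, 8)
      clean <- clean + amp * outer(map, src)
    }
  }
  rownames(clean) <- chans

  artifacts <- list()
  masks <- list()
  footprints <- list()
  zero <- function() matrix(0, C, n, dimnames = list(chans, NULL))

  if (spec$blink_rate > 0) {
    art <- zero(); mask <- logical(n)
    fp <- footprint_from(montage, chans, c(0, 1, 0.35))
    n_blinks <- max(1L, stats::rpois(1, spec$blink_rate * spec$duration_sec / 60))
    for (b in seq_len(n_blinks)) {
      len <- as.integer(round(stats::runif(1, 0.3, 1) * fs))
      start <- sample.int(max(1L, n - len), 1)
      amp <- spec$blink_amp_uv * stats::runif(1, 0.8, 1.2)
      idx <- start:(start + len - 1L)
      art[, idx] <- art[, idx] + amp * outer(fp, blink_template(len))
      mask[idx] <- TRUE
    }
    artifacts$blink <- art; masks$blink <- mask; footprints$blink <- fp
  }
  if (spec$emg_rate > 0) {
    art <- zero(); mask <- logical(n)
    side <- if (stats::runif(1) < 0.5) c(-1, 0, 0.2) else c(1, 0, 0.2)
    fp <- footprint_from(montage, chans, side, sharpness = 8)
    n_bursts <- max(1L, stats::rpois(1, spec$emg_rate * spec$duration_sec / 60))
    for (b in seq_len(n_bursts)) {
      len <- as.integer(round(stats::runif(1, 0.5, 2) * fs))
      start <- sample.int(max(1L, n - len), 1)
      idx <- start:(start + len - 1L)
      env <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = len))
      burst <- band_noise(len, fs, 20, min(100, fs / 2 - 5)) * env
      amp <- spec$emg_amp_uv * stats::runif(1, 0.8, 1.2)
      art[, idx] <- art[, idx] + amp * outer(fp, burst)
      mask[idx] <- TRUE
    }
    artifacts$emg <- art; masks$emg <- mask; footprints$emg <- fp
  }
  if (!is.na(spec$line_freq) && spec$line_amp_uv > 0) {
    t <- (seq_len(n) - 1) / fs
    phase <- stats::runif(1, 0, 2 * pi)
    gains <- stats::runif(C, 0.8, 1.2)
    art <- spec$line_amp_uv * outer(gains, sin(2 * pi * spec$line_freq * t + phase))
    rownames(art) <- chans
    artifacts$line <- art; masks$line <- rep(TRUE, n)
    footprints$line <- stats::setNames(gains, chans)
  }
  if (spec$drift_amp_uv > 0) {
    art <- t(vapply(seq_len(C), function(i)
      spec$drift_amp_uv * band_noise(n, fs, 0.01, 0.5), numeric(n)))
    rownames(art) <- chans
    artifacts$drift <- art; masks$drift <- rep(TRUE, n)
    footprints$drift <- stats::setNames(rep(1, C), chans)
  }
  for (ch in spec$flat_channels) {
    # the dead channel's artifact cancels everything else on it exactly,
    # so the emitted data there is identically zero
    art <- zero()
    art[ch, ] <- -clean[ch, ]
    for (nm in names(artifacts)) art[ch, ] <- art[ch, ] - artifacts[[nm]][ch, ]
    artifacts[[paste0("flat_", ch)]] <- art
    masks[[paste0("flat_", ch)]] <- rep(TRUE, n)
  }
  for (ch in spec$noisy_channels) {
    art <- zero()
    art[ch, ] <- spec$noisy_amp_uv * stats::rnorm(n)
    artifacts[[paste0("noisy_", ch)]] <- art
    masks[[paste0("noisy_", ch)]] <- rep(TRUE, n)
  }

  data <- clean
  for (a in artifacts) data <- data + a
  rec <- new_recording(data, fs, channel_ids = chans, montage = montage,
                       input_kind = "rest",
                       history = sprintf("synth:seed%d", spec$seed))
  list(recording = rec,
       truth = list(clean = clean, artifacts = artifacts, masks = masks,
                    footprints = footprints,
                    bad_channels = c(spec$flat_channels, spec$noisy_channels)))
}

#' Generate a labeled component corpus for classifier calibration
#'
#' Emits component time series and 10-20 scalp maps for six classes:
#' neural alpha (1/f + 10 Hz peak, dipolar occipital map), neural broadband
#' (1/f, dipolar map), blink (sparse biphasic transients, frontal focal
#' map), EMG (high-frequency bursts, temporal focal map), line (pure
#' sinusoid, spatially irregular map) and discontinuity (step/pop series,
#' single-electrode map). The two neural classes are labeled non-artifact.
#'
#' @param seed integer seed.
#' @param n_per_class components per class.
#' @param montage montage providing the 10-20 anchor positions (default
#'   `standard1020`).
#' @param fs sampling rate (default 250).
#' @param duration_sec component length (default 60).
#' @return list with `sources` (list of time series), `maps` (list of
#'   19-channel maps), `class` (character), `artifact` (logical).
#' @export
generate_labeled_components <- function(seed, n_per_class = 2,
                                        montage = load_montage("standard1020"),
                                        fs = 250, duration_sec = 60) {
  set.seed(seed)
  n <- as.integer(round(duration_sec * fs))
  ids <- ten_twenty_ids(montage)
  pos <- montage$positions[ids, , drop = FALSE]
  nchan <- length(ids)
  t_idx <- seq_len(n)

  dipolar_map <- function(direction = NULL) {
    dip <- 0.8 * if (is.null(direction)) {
      v <- stats::rnorm(3); v[3] <- abs(v[3]); v / sqrt(sum(v^2))
    } else direction / sqrt(sum(direction^2))
    mom <- stats::rnorm(3); mom <- mom / sqrt(sum(mom^2))
    map <- sphere_dipole_potential(pos, dip, mom)
    if (max(abs(map)) < 1e-9) map <- map + stats::rnorm(nchan, sd = 1e-3)
    map / sqrt(sum(map^2))
  }
  focal_map <- function(direction, sharpness = 10) {
    w <- footprint_from(montage, ids, direction, sharpness)
    w / sqrt(sum(w^2))
  }

  gen_one <- function(cls) {
    switch(cls,
      neural_alpha = list(
        src = colored_noise(n, fs, 1) + 1.5 * band_noise(n, fs, 9, 11),
        map = dipolar_map(c(0, -0.8, 0.4))),
      neural_broadband = list(
        src = colored_noise(n, fs, 1),
        map = dipolar_map()),
      blink = {
        src <- 0.2 * colored_noise(n, fs, 1)
        k <- max(2L, stats::rpois(1, duration_sec / 6))
        for (b in seq_len(k)) {
          len <- as.integer(round(stats::runif(1, 0.3, 1) * fs))
          start <- sample.int(n - len, 1)
          src[start:(start + len - 1L)] <-
            src[start:(start + len - 1L)] +
            stats::runif(1, 8, 15) * blink_template(len)
        }
        list(src = src, map = focal_map(c(stats::runif(1, -0.3, 0.3), 1, 0.35)))
      },
      emg = {
        env <- pmax(band_noise(n, fs, 0.1, 2), 0)
        src <- 0.15 * colored_noise(n, fs, 1) +
          band_noise(n, fs, 20, min(100, fs / 2 - 5)) * (0.5 + env)
        side <- if (stats::runif(1) < 0.5) -1 else 1
        list(src = src, map = focal_map(c(side, stats::runif(1, -0.3, 0.3), 0.2),
                                        sharpness = 12))
      },
      line = list(
        src = sqrt(2) * sin(2 * pi * ifelse(fs >= 130, 60, 50) * t_idx / fs +
                              stats::runif(1, 0, 2 * pi)) +
          0.05 * stats::rnorm(n),
        map = { v <- abs(stats::rnorm(nchan)) + 0.2; v / sqrt(sum(v^2)) }),
      discontinuity = {
        src <- 0.3 * colored_noise(n, fs, 1)
        k <- max(2L, stats::rpois(1, duration_sec / 10))
        for (b in seq_len(k)) {
          start <- sample.int(n - 1L, 1)
          src[start:n] <- src[start:n] + stats::runif(1, -10, 10)
        }
        m <- numeric(nchan)
        m[sample.int(nchan, 1)] <- 1
        list(src = src, map = m + stats::rnorm(nchan, sd = 0.05))
      })
  }

  classes <- c("neural_alpha", "neural_broadband", "blink", "emg", "line",
               "discontinuity")
  out <- list(sources = list(), maps = list(), class = character(),
              artifact = logical())
  for (cls in classes) for (r in seq_len(n_per_class)) {
    g <- gen_one(cls)
    out$sources <- c(out$sources, list(g$src))
    out$maps <- c(out$maps, list(g$map))
    out$class <- c(out$class, cls)
    out$artifact <- c(out$artifact,
                      !cls %in% c("neural_alpha", "neural_broadband"))
  }
  out
}
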