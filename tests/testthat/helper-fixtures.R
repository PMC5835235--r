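# Shared fixtures and independent oracles for the test suite.

# colored noise with P(f) ~ 1/f^expo, unit RMS, deterministic under the
# ambient RNG state (independent of the package's internal generator)
pink_noise <- function(n, fs, expo = 1) {
  nf <- n %/% 2 + 1L
  f <- (seq_len(nf) - 1L) * fs / n
  g <- c(0, 1 / f[-1]^(expo / 2))
  sp <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * g
  x <- Re(stats::fft(c(sp, Conj(rev(sp[2:(n - nf + 1L)]))), inverse = TRUE))
  x / stats::sd(x)
}

# amplitude of the FFT bin nearest frequency f
fft_amp <- function(x, f, fs) {
  n <- length(x)
  2 * Mod(stats::fft(x))[round(f * n / fs) + 1L] / n
}

# Amari separation index of the product (estimated unmixing) x (true
# mixing); 0 for a perfect permutation-scaled identity
amari_index <- function(P) {
  P <- abs(P)
  K <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1L, max)) - 1)
  c2 <- sum(colSums(t(t(P) / apply(P, 2L, max))) - 1)
  (r + c2) / (2 * K * (K - 1))
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

# white-noise recording with exchangeable channels
white_recording <- function(C, n, fs = 250, sd = 3, labels = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(C))
  new_recording(matrix(stats::rnorm(C * n, sd = sd), C, n,
                       dimnames = list(labels, NULL)), fs)
}

# a half-sine-squared blink train on the given samples-per-blink layout
blink_train <- function(n, fs, starts, dur_s = 1) {
  len <- round(dur_s * fs)
  x <- numeric(n)
  for (s in starts) {
    idx <- s:min(s + len - 1L, n)
    x[idx] <- x[idx] + sin(pi * seq(0, 1, length.out = length(idx)))^2
  }
  x
}

# One full pipeline run (19 channels, 50 s, planted flat anchor channel,
# segment rejection), computed once per session and shared across test
# files; the two ICA passes dominate its cost.
.fixture_cache <- new.env(parent = emptyenv())
cached_pipeline_run <- function() {
  if (!is.null(.fixture_cache$pipe)) return(.fixture_cache$pipe)
  m128 <- load_montage("sphere128")
  flat_id <- unname(m128$ten_twenty[["T5"]])
  sp <- synth_spec(n_channels = 19, duration_sec = 50, seed = 95,
                   flat_channels = flat_id)
  g <- generate_recording(sp)
  cfg <- pipeline_config(segment_mode = "reject", seed = 4,
                         output_dir = file.path(tempdir(), "pipe_out"))
  .fixture_cache$pipe <- list(res = process_recording(g$recording, cfg,
                                                      "synth95"),
                              g = g, cfg = cfg, flat_id = flat_id)
  .fixture_cache$pipe
}
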