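test_that("high-pass removes DC and preserves the passband", {
  rec <- new_recording(matrix(10, 2, 5000), 250)
  hf <- highpass_filter(rec)
  expect_lt(mean(abs(hf$data)), 0.01)

  t <- (0:4999) / 250
  sig <- sin(2 * pi * 0.1 * t) + sin(2 * pi * 10 * t)
  f <- highpass_filter(new_recording(matrix(sig, 1, 5000), 250))
  g10 <- fft_amp(f$data[1, ], 10, 250) / fft_amp(sig, 10, 250)
  g01 <- fft_amp(f$data[1, ], 0.1, 250) / fft_amp(sig, 0.1, 250)
  expect_gt(g10, 0.95); expect_lt(g10, 1.05)
  expect_lt(20 * log10(g01), -20)
})

test_that("the designed response at the 1 Hz cutoff is half gain", {
  t <- (0:4999) / 250
  s1 <- sin(2 * pi * 1 * t)
  f <- highpass_filter(new_recording(matrix(s1, 1, 5000), 250))
  g <- fft_amp(f$data[1, ], 1, 250) / fft_amp(s1, 1, 250)
  expect_gt(g, 0.35); expect_lt(g, 0.65)
})

test_that("filtering is zero-phase", {
  set.seed(2)
  bb <- as.vector(stats::filter(rnorm(6000), rep(0.2, 5), sides = 2))
  bb[is.na(bb)] <- 0
  f <- highpass_filter(new_recording(matrix(bb, 1, 6000), 250))
  cc <- stats::ccf(as.vector(f$data), bb, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("band-pass branch engages only at >= 500 Hz", {
  # a tone above the 249 Hz edge needs a rate that can represent it
  tk <- (0:14999) / 1000
  tone300 <- sin(2 * pi * 300 * tk)
  f <- bandpass_if_high_rate(new_recording(matrix(tone300, 1, 15000), 1000))
  expect_lt(20 * log10(fft_amp(f$data[1, ], 300, 1000) /
                         fft_amp(tone300, 300, 1000)), -20)
  expect_match(f$history[length(f$history)], "bandpass")

  set.seed(3)
  x <- rnorm(6000)
  r250 <- new_recording(matrix(x, 1, 6000), 250)
  expect_equal(bandpass_if_high_rate(r250)$data, highpass_filter(r250)$data)

  t1k <- (0:14999) / 1000
  tone100 <- sin(2 * pi * 100 * t1k)
  f1k <- bandpass_if_high_rate(new_recording(matrix(tone100, 1, 15000), 1000))
  g <- fft_amp(f1k$data[1, ], 100, 1000) / fft_amp(tone100, 100, 1000)
  expect_gt(g, 0.95); expect_lt(g, 1.05)
})

test_that("too-short recordings are refused with a duration hint", {
  expect_error(highpass_filter(new_recording(matrix(0, 1, 100), 250)),
               "at least")
})

test_that("line-noise regression removes a planted 60 Hz tone", {
  set.seed(30)
  fs <- 250; n <- 60 * fs
  x <- 10 * pink_noise(n, fs) + 20 * sin(2 * pi * 60 * (0:(n - 1)) / fs + 0.7)
  out <- remove_line_noise(new_recording(matrix(x, 1, n), fs))
  p0 <- welch_psd(x, fs); p1 <- welch_psd(out$data[1, ], fs)
  at <- function(p, f) p$power[which.min(abs(p$freq - f))]
  floor_db <- 10 * log10(mean(p1$power[p1$freq >= 55 & p1$freq <= 65 &
                                         abs(p1$freq - 60) > 2]))
  expect_lt(10 * log10(at(p1, 60)), floor_db + 3)
  bp <- function(p, lo, hi) sum(p$power[p$freq >= lo & p$freq <= hi])
  expect_lt(abs(bp(p1, 54, 56) / bp(p0, 54, 56) - 1), 0.10)
  expect_lt(abs(bp(p1, 64, 66) / bp(p0, 64, 66) - 1), 0.10)
  # signal preservation: total 1-45 Hz power must not grow by > 1%
  expect_lt(bp(p1, 1, 45) / bp(p0, 1, 45), 1.01)
})

test_that("a signal without line noise passes through untouched", {
  set.seed(31)
  fs <- 250; n <- 40 * fs
  x <- 10 * pink_noise(n, fs)
  X <- stats::fft(x)
  f <- c(0:(n / 2), -((n / 2 - 1):1)) * fs / n
  X[abs(f) > 40] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  out <- remove_line_noise(new_recording(matrix(x, 1, n), fs))
  expect_lt(rmse(out$data[1, ], x) / stats::sd(x), 1e-6)
})

test_that("the frequency scan locks onto an off-target line at 60.4 Hz", {
  set.seed(32)
  fs <- 250; n <- 60 * fs
  x <- 10 * pink_noise(n, fs) + 20 * sin(2 * pi * 60.4 * (0:(n - 1)) / fs)
  out <- remove_line_noise(new_recording(matrix(x, 1, n), fs),
                           line_noise_config(60))
  p1 <- welch_psd(out$data[1, ], fs)
  at604 <- p1$power[which.min(abs(p1$freq - 60.4))]
  floor60 <- mean(p1$power[p1$freq >= 55 & p1$freq <= 65 &
                             abs(p1$freq - 60.4) > 2])
  expect_lt(10 * log10(at604), 10 * log10(floor60) + 3)
})

test_that("spectral preprocessing is deterministic", {
  set.seed(33)
  fs <- 250; n <- 20 * fs
  x <- matrix(10 * pink_noise(n, fs) + 5 * sin(2 * pi * 60 * (0:(n - 1)) / fs),
              1, n)
  rec <- new_recording(x, fs)
  a <- remove_line_noise(highpass_filter(rec))
  b <- remove_line_noise(highpass_filter(rec))
  expect_identical(a$data, b$data)
})

test_that("line-noise configuration is validated", {
  rec <- new_recording(matrix(rnorm(250), 1, 250), 250)
  expect_error(remove_line_noise(rec, line_noise_config(60)), "window")
  rec2 <- new_recording(matrix(rnorm(5000), 1, 5000), 250)
  expect_error(remove_line_noise(rec2, line_noise_config(124.5)), "Nyquist")
})
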