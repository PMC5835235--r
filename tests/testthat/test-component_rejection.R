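head19 <- build_head_model(load_montage("standard1020"))

test_that("mean local skewness separates spiky from symmetric series", {
  set.seed(70)
  fs <- 250
  g <- rnorm(15000)
  expect_lt(mean_local_skewness(g, fs), 0.1)

  spiky <- 2 * rnorm(15000)
  for (s in seq(1000, 14000, by = round(15 * fs)))
    spiky[s:(s + 20)] <- spiky[s:(s + 20)] + 200
  expect_gt(mean_local_skewness(spiky, fs), 1)

  expect_equal(mean_local_skewness(rep(4, 15000), fs), 0)
})

test_that("log alpha power orders and scales correctly", {
  fs <- 250; t <- (0:14999) / fs
  s10 <- sin(2 * pi * 10 * t)
  s30 <- sin(2 * pi * 30 * t)
  expect_gt(log_alpha_power(s10, fs), log_alpha_power(s30, fs))

  set.seed(71)
  w <- rnorm(15000)
  expect_equal(log_alpha_power(10 * w, fs) - log_alpha_power(w, fs), 2,
               tolerance = 1e-9)

  # a narrowband alpha source fills the whole 8-13 Hz band, so its mean
  # log band power towers over the 20-40 Hz floor
  alpha_nb <- eegclean:::band_noise(15000, fs, 8, 13) + 0.01 * w
  psd <- welch_psd(alpha_nb, fs)
  beta <- mean(log10(psd$power[psd$freq >= 20 & psd$freq <= 40]))
  expect_gt(log_alpha_power(alpha_nb, fs) - beta, 2)
})

test_that("the 1/f fit recovers the spectral exponent", {
  set.seed(72)
  fs <- 250; n <- 30000
  f1 <- fit_one_over_f(pink_noise(n, fs), fs)
  expect_equal(f1$lambda, 1.0, tolerance = 0.05)
  expect_lt(f1$fit_error, 0.01)

  expect_lt(abs(fit_one_over_f(rnorm(n), fs)$lambda), 0.1)

  # EMG-like: power rising above 20 Hz
  nf <- n / 2 + 1
  fr <- (0:(nf - 1)) * fs / n
  g <- ifelse(fr < 20, 0.3, 1) * c(0, sqrt(fr[-1]) / sqrt(max(fr)))
  sp <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * g
  emg <- Re(stats::fft(c(sp, Conj(rev(sp[2:(n - nf + 1)]))), inverse = TRUE))
  expect_lt(fit_one_over_f(emg / sd(emg), fs)$lambda, 0.3)
})

test_that("scalp-map range ranks focality", {
  focal <- c(1, rep(0, 18))
  uniform <- rep(1, 19)
  expect_gt(range_within_pattern(focal), range_within_pattern(uniform))
  expect_equal(range_within_pattern(uniform), log(1e-12))

  m <- load_montage("standard1020")
  dip <- eegclean:::sphere_dipole_potential(m$positions,
                                            0.4 * c(0, 0.5, 0.85), c(0, 1, 0))
  spikemap <- rep(0.05, 19); spikemap[7] <- 1
  expect_gt(range_within_pattern(spikemap), range_within_pattern(dip))
  expect_error(range_within_pattern(c(1, NA, rep(0, 17))), "finite")
})

test_that("current density norm separates dipolar from scrambled maps", {
  m <- load_montage("standard1020")
  dipmap <- eegclean:::sphere_dipole_potential(
    m$positions, 0.8 * c(0, -0.4, 0.55) / sqrt(sum(c(0, -0.4, 0.55)^2)),
    c(0, 1, 0.3))
  set.seed(73)
  worse <- 0
  for (r in 1:20) {
    perm <- sample(dipmap)
    if (current_density_norm(perm, head19) >
        current_density_norm(dipmap, head19)) worse <- worse + 1
  }
  expect_gte(worse, 19)

  expect_equal(current_density_norm(dipmap * 10, head19),
               current_density_norm(dipmap, head19), tolerance = 1e-9)
  expect_error(current_density_norm(rep(0, 19), head19), "degenerate")
})

test_that("the zero classifier sits exactly on the boundary", {
  clf0 <- new_classifier(rep(0, 6), 0, rep(0, 6), rep(1, 6))
  feats <- matrix(rnorm(30), 5, 6,
                  dimnames = list(NULL, eegclean:::feature_names))
  p <- classifier_probability(clf0, feats)
  expect_equal(p, rep(0.5, 5))
  expect_false(any(p > 0.5))   # strict inequality: none rejected
})

test_that("shipped weights separate planted blink from alpha components", {
  clf <- load_classifier_weights()
  lc <- generate_labeled_components(seed = 74, n_per_class = 2)
  feats <- t(mapply(function(s, m) component_features(s, m, 250, head19),
                    lc$sources, lc$maps))
  p <- classifier_probability(clf, feats)
  expect_true(all(p[lc$class == "blink"] > 0.5))
  expect_true(all(p[lc$class == "neural_alpha"] < 0.5))
})

test_that("classification demands enough 10-20 anchors", {
  set.seed(75)
  m <- load_montage("standard1020")
  labs <- rownames(m$positions)[1:13]   # 6 anchors missing
  X <- matrix(rnorm(13 * 3000), 13, 3000)
  d <- suppressWarnings(run_extended_infomax(X, seed = 1))
  d$channel_ids <- labs
  expect_error(classify_components(d, m, 250), "anchor")
})

test_that("percent variance kept matches constructed component drops", {
  set.seed(76)
  pre <- matrix(rnorm(600), 6, 100)
  expect_identical(percent_variance_kept(pre, pre), 100)
  expect_equal(percent_variance_kept(pre, matrix(0, 6, 100)), 0,
               tolerance = 1)

  # orthogonal mixing; one component carries ~30% of the variance
  n <- 20000
  S <- matrix(rnorm(6 * n), 6, n)
  S <- S / apply(S, 1, sd)
  S <- S * sqrt(c(0.3, rep(0.7 / 5, 5)) * 6)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  dec <- structure(list(mixing = Q, sources = S,
                        unmixing = t(Q), sphering = diag(6),
                        channel_means = rep(0, 6),
                        channel_ids = paste0("c", 1:6), seed = 1L,
                        converged = TRUE, n_iter = 0L),
                   class = "eeg_decomposition")
  pre2 <- Q %*% S
  post2 <- project_without_components(dec, 1L)
  expect_equal(percent_variance_kept(pre2, post2), 70, tolerance = 2)

  # monotone nonincreasing in the dropped set
  pvk <- vapply(1:5, function(k)
    percent_variance_kept(pre2, project_without_components(dec, 1:k)),
    numeric(1))
  expect_true(all(diff(pvk) <= 1e-9))
})

test_that("features are invariant to component sign flips", {
  set.seed(77)
  fs <- 250
  src <- pink_noise(20000, fs)
  map <- rnorm(19)
  a <- component_features(src, map, fs, head19)
  b <- component_features(-src, -map, fs, head19)
  expect_equal(a, b, tolerance = 1e-9)
})
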