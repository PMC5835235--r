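test_that("avg_log_power reflects relative channel power exactly", {
  set.seed(40)
  x <- rnorm(2000)
  rec <- new_recording(rbind(a = x, b = x, c = 10 * x), 250)
  v <- avg_log_power(rec)
  expect_equal(v[["a"]], v[["b"]])
  expect_equal(v[["c"]] - v[["a"]], 2.0, tolerance = 1e-9)

  flat <- new_recording(rbind(a = x, z = rep(0, 2000)), 250)
  vf <- avg_log_power(flat)
  expect_equal(vf[["z"]], -12)   # guarded floor, not -Inf

  expect_error(avg_log_power(new_recording(matrix(x[1:100], 1), 250)), "2 s")
  low_rate <- new_recording(rbind(a = x, b = x), 100)
  expect_warning(avg_log_power(low_rate), "Nyquist")
})

test_that("joint-probability flags exactly the planted outliers", {
  set.seed(41)
  hits <- 0
  for (r in 1:100) {
    v <- stats::setNames(c(rnorm(30), 8), paste0("c", 1:31))
    if (identical(joint_probability_outliers(v), "c31")) hits <- hits + 1
  }
  expect_gte(hits, 99)

  set.seed(42)
  v2 <- stats::setNames(c(rnorm(30), 8, -8), paste0("c", 1:32))
  expect_setequal(joint_probability_outliers(v2), c("c31", "c32"))

  expect_length(joint_probability_outliers(
    stats::setNames(rep(1, 30), paste0("c", 1:30))), 0)

  # below 8 channels a plain value z-score is used; with so few values the
  # largest attainable |z| is (n-1)/sqrt(n) < 3, so nothing can be flagged
  expect_warning(
    f <- joint_probability_outliers(stats::setNames(c(0, 0.1, -0.1, 9), 1:4)),
    "fewer than 8")
  expect_length(f, 0)
})

test_that("bad-channel detection runs two passes and unions the results", {
  # two-population fixture: one extreme channel masks a moderate one in the
  # first pass; the second pass (on survivors) must catch the moderate one
  set.seed(43)
  n <- 1500
  amps <- c(rep(1, 36) * exp(rnorm(36, sd = 0.02)), 40, 1.8)
  labels <- c(paste0("g", 1:36), "extreme", "moderate")
  dat <- t(vapply(amps, function(a) a * rnorm(n), numeric(n)))
  rownames(dat) <- labels
  rec <- new_recording(dat, 250, channel_ids = labels)
  res <- detect_bad_channels(rec)
  expect_true("extreme" %in% res$pass1_ids)
  expect_true("moderate" %in% res$bad_ids)
  expect_setequal(res$bad_ids, union(res$pass1_ids, res$pass2_ids))
  expect_true(all(c("extreme", "moderate") %in% res$bad_ids))
  # determinism
  expect_identical(detect_bad_channels(rec)$bad_ids, res$bad_ids)
})

test_that("flat and extreme-noise channels are caught in synthetic EEG", {
  sp <- synth_spec(seed = 44, duration_sec = 60, blink_rate = 0,
                   emg_rate = 0, drift_amp_uv = 0,
                   flat_channels = "E3", noisy_channels = "E9")
  g <- generate_recording(sp)
  rec <- remove_line_noise(highpass_filter(g$recording))
  res <- detect_bad_channels(rec)
  expect_true(all(c("E3", "E9") %in% res$bad_ids))
})

test_that("over-half-bad yields a warning, not an error", {
  # at z_cut = 3 Chebyshev caps the flaggable fraction well below one half,
  # so the guard is exercised with a permissive cutoff
  set.seed(45)
  n <- 1000
  amps <- exp(seq(0, 4, length.out = 10))
  dat <- t(vapply(amps, function(a) a * rnorm(n), numeric(n)))
  rec <- new_recording(dat, 250)
  w <- capture_warnings(detect_bad_channels(rec, z_cut = 0.3))
  expect_true(any(grepl("half", w)))
})

test_that("spherical splines reproduce low-order harmonic fields exactly", {
  m <- load_montage("sphere128")
  P <- m$positions
  set.seed(46)
  co <- rnorm(63)
  field <- eegclean:::real_spherical_harmonics(P, 7) %*% co + 2
  hold <- c(5, 60, 100)
  rec <- new_recording(matrix(rep(field, 3), ncol = 3), 250,
                       channel_ids = rownames(P), montage = m)
  out <- interpolate_bad_channels(rec, rownames(P)[hold], m,
                                  full_order = rownames(P))
  expect_lt(max(abs(out$data[hold, ] - matrix(rep(field[hold], 3), ncol = 3))),
            1e-6)

  # constant field -> the constant, everywhere
  recc <- new_recording(matrix(3.3, 128, 2), 250,
                        channel_ids = rownames(P), montage = m)
  outc <- interpolate_bad_channels(recc, rownames(P)[hold], m)
  expect_lt(max(abs(outc$data - 3.3)), 1e-6)
})

test_that("leave-one-out error on a dipolar field stays below 10%", {
  m <- load_montage("sphere128")
  anchors <- unname(m$ten_twenty)
  ids39 <- c(anchors, setdiff(rownames(m$positions), anchors)[1:20])
  P39 <- m$positions[ids39, ]
  dip <- eegclean:::sphere_dipole_potential(P39, 0.4 * c(0, 0.55, 0.83),
                                            c(0, 0, 1))
  err <- vapply(seq_along(ids39), function(i) {
    rec <- new_recording(matrix(dip, ncol = 1), 250, channel_ids = ids39,
                         montage = m)
    out <- interpolate_bad_channels(rec, ids39[i], m, full_order = ids39)
    abs(out$data[ids39[i], 1] - dip[i])
  }, numeric(1))
  expect_lt(sqrt(mean(err^2)) / diff(range(dip)), 0.10)
})

test_that("interpolation restores order and validates its inputs", {
  m <- load_montage("standard1020")
  labs <- rownames(m$positions)
  rec <- new_recording(matrix(rnorm(19 * 50), 19, 50), 250,
                       channel_ids = labs, montage = m)
  expect_identical(interpolate_bad_channels(rec, character()), rec)
  dropped <- drop_channels(rec, "Fz")
  out <- interpolate_bad_channels(dropped, "Fz", m, full_order = labs)
  expect_identical(out$channel_ids, labs)
  expect_error(interpolate_bad_channels(drop_channels(rec, labs[1:16]),
                                        labs[1:16], m), "4 good")
})

test_that("re-referencing conserves and centres as specified", {
  set.seed(47)
  rec <- white_recording(6, 500)
  avg <- rereference(rec, "average")
  expect_lt(max(abs(colSums(avg$data))), 1e-9)

  one <- rereference(rec, "channels", channels = "ch3")
  expect_equal(max(abs(one$data["ch3", ])), 0)

  twice <- rereference(avg, "average")
  expect_equal(twice$data, avg$data, tolerance = 1e-12)

  shifted <- rec
  shifted$data <- rec$data + 42
  expect_equal(rereference(shifted, "average")$data, avg$data,
               tolerance = 1e-9)

  expect_error(rereference(rec, "channels", channels = character()), "empty")
  expect_error(rereference(rec, "channels", channels = "nope"), "nope")
})
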