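test_that("recording construction enforces its invariants", {
  d <- matrix(rnorm(20), 2, 10)
  rec <- new_recording(d, 250)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(n_channels(rec), 2)
  expect_equal(n_samples(rec), 10)

  d2 <- d; d2[1, 3] <- NaN
  expect_error(new_recording(d2, 250), "NaN")
  expect_error(new_recording(d, 0), "positive")
  expect_error(new_recording(d, 250, channel_ids = c("a", "a")), "duplicate")
  expect_error(new_recording(d, 250,
                             events = data.frame(label = "x", sample = 10L)),
               "\\[0, n_samples\\)")
})

test_that("ica_sample_budget reproduces the worked examples", {
  b <- ica_sample_budget(128, sample_rate = 500)
  expect_identical(b$n_samples_required, 491520L)
  expect_equal(b$seconds_required, 983.04)

  b40 <- ica_sample_budget(40, 75000)
  expect_identical(b40$n_samples_required, 48000L)
  expect_true(b40$sufficient)

  b1 <- ica_sample_budget(1, 30)
  expect_identical(b1$n_samples_required, 30L)
  expect_true(b1$sufficient)

  expect_error(ica_sample_budget(0), "positive")
})

test_that("ica_sample_budget is exact integer arithmetic for C in 1..256", {
  for (C in 1:256) {
    # independent brute force: repeated addition, no multiplication
    req <- 0L
    for (i in 1:30) req <- req + sum(rep.int(C, C))
    expect_identical(ica_sample_budget(C)$n_samples_required, req)
  }
})

test_that("native format round-trips bit-exactly with metadata", {
  set.seed(1)
  rec <- new_recording(matrix(rnorm(30), 3, 10), 250,
                       channel_ids = c("a", "b", "c"),
                       events = data.frame(label = "stim", sample = 4L),
                       input_kind = "event", history = "origin")
  path <- file.path(tempdir(), "rt_native")
  write_recording(rec, path, "native")
  r2 <- read_recording(paste0(path, ".dat"), "native")
  expect_identical(r2$data, rec$data)
  expect_identical(r2$channel_ids, rec$channel_ids)
  expect_equal(r2$sample_rate, 250)
  expect_equal(r2$events$sample, 4L)
  expect_identical(r2$input_kind, "event")
  expect_true("origin" %in% r2$history)
})

test_that("EDF round-trip error stays within one quantization step", {
  t <- (0:14999) / 250
  rec <- new_recording(rbind(a = 100 * sin(2 * pi * 7 * t),
                             b = 50 * sin(2 * pi * 13 * t + 1)), 250)
  path <- file.path(tempdir(), "rt.edf")
  write_recording(rec, path, "edf")
  r2 <- read_recording(path, "edf")
  expect_equal(dim(r2$data), dim(rec$data))
  lsb <- 2 * 3276.7 / 65534
  expect_lt(max(abs(r2$data - rec$data)), lsb)
})

test_that("EDF handles large layouts and non-integer-second lengths", {
  rec <- new_recording(matrix(rnorm(128 * 15000), 128, 15000), 250)
  path <- file.path(tempdir(), "big.edf")
  write_recording(rec, path, "edf")
  expect_equal(dim(read_recording(path, "edf")$data), c(128, 15000))

  odd <- new_recording(matrix(rnorm(2 * 1100), 2, 1100), 250)
  path2 <- file.path(tempdir(), "odd.edf")
  write_recording(odd, path2, "edf")
  expect_equal(ncol(read_recording(path2, "edf")$data), 1100)
})

test_that("unreadable files raise I/O errors naming the file", {
  p <- file.path(tempdir(), "trunc.edf")
  writeBin(raw(100), p)
  expect_error(read_recording(p, "edf"), "trunc.edf")
  expect_error(read_recording(file.path(tempdir(), "absent.dat"), "native"),
               "absent")
  rec <- new_recording(matrix(0, 1, 10), 250)
  suppressWarnings(
    expect_error(write_recording(rec, "/nonexistent_dir_x/y", "native"),
                 "cannot open"))
})

test_that("builtin montages carry positions and a complete 10-20 map", {
  m <- load_montage("sphere128")
  expect_equal(nrow(m$positions), 128)
  expect_length(m$ten_twenty, 19)
  expect_false(anyDuplicated(m$ten_twenty) > 0)
  expect_equal(max(abs(sqrt(rowSums(m$positions^2)) - 1)), 0, tolerance = 1e-6)

  m19 <- load_montage("standard1020")
  expect_equal(nrow(m19$positions), 19)
})

test_that("montage files are normalized and validated", {
  p <- file.path(tempdir(), "mont.txt")
  lines <- c(sprintf("%s %f %f %f", ten_twenty_labels(),
                     c(0, rep(0.1, 18)), c(0, rep(0.2, 18)) + (1:19) / 40,
                     rep(1, 19)))
  lines[1] <- "Fp1 0 0 2"
  writeLines(lines, p)
  m <- load_montage(p)
  expect_equal(unname(m$positions["Fp1", ]), c(0, 0, 1))

  writeLines(lines[-14], p)   # drop the Pz line
  expect_error(load_montage(p), "Pz")
})

test_that("channel subset selection keeps order and enforces the anchors", {
  m <- load_montage("sphere128")
  anchors <- unname(m$ten_twenty)
  extra <- setdiff(rownames(m$positions), anchors)[1:20]
  rec <- new_recording(matrix(rnorm(128 * 100), 128, 100), 250,
                       channel_ids = rownames(m$positions), montage = m)
  sub <- select_channel_subset(rec, c(anchors, extra))
  expect_equal(n_channels(sub), 39)
  expect_identical(sub$channel_ids, c(anchors, extra))

  again <- select_channel_subset(sub, c(anchors, extra))
  expect_identical(again$data, sub$data)

  all_ch <- select_channel_subset(rec, rec$channel_ids)
  expect_identical(all_ch$data, rec$data)

  expect_error(select_channel_subset(rec, setdiff(c(anchors, extra),
                                                  m$ten_twenty[["Fz"]])),
               m$ten_twenty[["Fz"]])
  expect_error(select_channel_subset(rec, c(anchors, "NOPE")), "NOPE")
})
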