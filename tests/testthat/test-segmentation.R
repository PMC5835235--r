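mont19 <- load_montage("standard1020")

test_that("resting segmentation counts whole windows from the start", {
  rec <- white_recording(5, 2500)
  expect_length(segment_rest(rec, 2)$starts, 5)

  rec2 <- white_recording(5, 40999)   # 163.996 s at 250 Hz
  expect_length(segment_rest(rec2, 2)$starts, 81)

  expect_warning(s0 <- segment_rest(white_recording(2, 100), 10), "0 segments")
  expect_length(s0$starts, 0)
})

test_that("event segmentation respects bounds and permits overlap", {
  rec <- new_recording(matrix(rnorm(2 * 2500), 2, 2500), 250,
                       events = data.frame(label = rep("s", 4),
                                           sample = c(10L, 500L, 600L, 2400L)),
                       input_kind = "event")
  expect_warning(segs <- segment_events(rec, "s", c(-1, 1)), "skipped")
  # events at 10 (pre-bound) and 2400 (post-bound) are dropped; the two
  # overlapping windows around 500 and 600 are both kept
  expect_length(segs$starts, 2)
  expect_equal(segs$starts, c(500L - 250L, 600L - 250L))

  expect_error(segment_events(white_recording(2, 100), "s", c(0, 1)),
               "event-kind")
})

test_that("amplitude and joint-probability criteria flag planted segments", {
  set.seed(80)
  dat <- matrix(rnorm(19 * 7500) * 3, 19, 7500,
                dimnames = list(ten_twenty_labels(), NULL))
  dat[4, 1300:1320] <- 100                  # inside segment 3
  rec <- new_recording(dat, 250, montage = mont19)
  segs <- reject_segments(segment_rest(rec, 2))
  expect_true(segs$rejected[3])
  expect_true("amplitude" %in% segs$reasons[[3]])
  expect_equal(n_retained_segments(segs) + sum(segs$rejected),
               length(segs$starts))
})

test_that("sub-threshold EMG is caught by joint probability alone", {
  set.seed(81)
  dat <- matrix(rnorm(19 * 7500) * 3, 19, 7500,
                dimnames = list(ten_twenty_labels(), NULL))
  burst <- 30 * sin(2 * pi * 80 * (0:499) / 250)
  dat[7, 2001:2500] <- pmax(pmin(dat[7, 2001:2500] + burst, 39), -39)
  rec <- new_recording(dat, 250, montage = mont19)
  segs <- reject_segments(segment_rest(rec, 2))
  expect_true(segs$rejected[5])
  expect_true(any(c("jointprob_single", "jointprob_group") %in%
                    segs$reasons[[5]]))
  expect_false("amplitude" %in% segs$reasons[[5]])
})

test_that("infinite thresholds flag nothing", {
  set.seed(82)
  rec <- new_recording(matrix(rnorm(19 * 5000) * 5, 19, 5000,
                              dimnames = list(ten_twenty_labels(), NULL)),
                       250, montage = mont19)
  segs <- reject_segments(segment_rest(rec, 2), amp_lo = -Inf, amp_hi = Inf,
                          z_cut = Inf)
  expect_false(any(segs$rejected))
})

test_that("identical segments are never flagged by joint probability", {
  block <- matrix(rnorm(19 * 500), 19, 500,
                  dimnames = list(ten_twenty_labels(), NULL))
  dat <- do.call(cbind, replicate(10, block, simplify = FALSE))
  rec <- new_recording(dat, 250, montage = mont19)
  segs <- reject_segments(segment_rest(rec, 2), amp_lo = -Inf, amp_hi = Inf)
  expect_false(any(segs$rejected))
})

test_that("ROI mode ignores artifact outside the ROI", {
  set.seed(83)
  roi <- ten_twenty_labels()[1:6]
  block <- matrix(rnorm(19 * 500), 19, 500)
  dat <- do.call(cbind, replicate(10, block, simplify = FALSE))
  rownames(dat) <- ten_twenty_labels()
  dat["O2", 2100:2200] <- 500               # massive artifact outside ROI
  rec <- new_recording(dat, 250, montage = mont19)
  segs <- reject_segments(segment_rest(rec, 2), roi = roi)
  expect_false(any(segs$rejected))
  expect_error(reject_segments(segment_rest(rec, 2), roi = c("O2", "nope")),
               "nope")
})

test_that("within-segment interpolation repairs only the bad segment", {
  set.seed(84)
  dat <- matrix(rnorm(19 * 7500) * 3, 19, 7500,
                dimnames = list(ten_twenty_labels(), NULL))
  orig <- dat
  dat[5, 1001:1500] <- dat[5, 1001:1500] * 10   # segment 3 only
  rec <- new_recording(dat, 250, montage = mont19)
  segs <- interpolate_within_segments(segment_rest(rec, 2))
  bad_label <- ten_twenty_labels()[5]
  expect_true(bad_label %in% segs$interpolated[[3]])
  # other segments keep the channel untouched
  untouched <- setdiff(seq_along(segs$starts),
                       which(vapply(segs$interpolated,
                                    function(l) bad_label %in% l, logical(1))))
  for (i in untouched[1:3])
    expect_equal(segs$recording$data[5, segs$starts[i] + 1:500],
                 orig[5, segs$starts[i] + 1:500])
})

test_that("within-segment interpolation rarely fires on clean data", {
  # under the any-of-four-criteria |z| > 3 rule across 19 channels, the
  # best-case (i.i.d. Gaussian) per-segment flag probability is ~8%; the
  # test bounds the implementation at 10% per clean segment
  fired_segments <- 0; total <- 0
  for (s in 1:20) {
    set.seed(800 + s)
    dat <- matrix(rnorm(19 * 4000) * 3, 19, 4000,
                  dimnames = list(ten_twenty_labels(), NULL))
    segs <- interpolate_within_segments(
      segment_rest(new_recording(dat, 250, montage = mont19), 2))
    fired_segments <- fired_segments + sum(lengths(segs$interpolated) > 0)
    total <- total + length(segs$starts)
  }
  expect_lte(fired_segments / total, 0.10)
})

test_that("a segment of identical channels is left alone", {
  row <- rnorm(1000)
  dat <- matrix(rep(row, each = 19), 19, 1000,
                dimnames = list(ten_twenty_labels(), NULL))
  rec <- new_recording(dat, 250, montage = mont19)
  segs <- interpolate_within_segments(segment_rest(rec, 2))
  expect_true(all(lengths(segs$interpolated) == 0))
})
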