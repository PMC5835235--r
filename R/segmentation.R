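#' @title Segmentation and segment-level artifact handling
#' @description After component rejection the recording can optionally be
#'   cut into segments - fixed-length windows from the file start for
#'   resting data, or event-locked windows for event data - followed by one
#'   of two mutually exclusive artifact steps: rejection of contaminated
#'   segments (amplitude threshold plus two joint-probability criteria), or
#'   per-segment interpolation of contaminated channels for short files
#'   where rejecting segments would cost too much data. Sample indices are
#'   0-based and intervals half-open.
#' @name segmentation
NULL

new_segment_set <- function(rec, seg_len_sec, starts, roi_channels = NULL) {
  structure(list(
    recording = rec, seg_len_sec = seg_len_sec,
    seg_len = as.integer(round(seg_len_sec * rec$sample_rate)),
    starts = as.integer(starts),
    rejected = logical(length(starts)),
    reasons = replicate(length(starts), character(), simplify = FALSE),
    interpolated = replicate(length(starts), character(), simplify = FALSE),
    roi_channels = roi_channels),
    class = "eeg_segment_set")
}

#' @export
print.eeg_segment_set <- function(x, ...) {
  cat(sprintf("<eeg_segment_set> %d segments of %g s (%d rejected)\n",
              length(x$starts), x$seg_len_sec, sum(x$rejected)))
  invisible(x)
}

#' Number of retained segments
#' @param segs an `eeg_segment_set`.
#' @return integer count of unrejected segments.
#' @export
n_retained_segments <- function(segs) sum(!segs$rejected)

segment_matrix <- function(segs, i) {
  idx <- segs$starts[i] + seq_len(segs$seg_len)   # starts are 0-based
  segs$recording$data[, idx, drop = FALSE]
}

#' Segment a resting-state recording into fixed windows
#'
#' Consecutive non-overlapping windows of `seg_len_sec` seconds from sample
#' 0; a trailing partial window is discarded.
#'
#' @param rec an `eeg_recording`.
#' @param seg_len_sec segment length in seconds (> 0).
#' @return an `eeg_segment_set`.
#' @export
segment_rest <- function(rec, seg_len_sec) {
  stopifnot(inherits(rec, "eeg_recording"), seg_len_sec > 0)
  len <- as.integer(round(seg_len_sec * rec$sample_rate))
  k <- n_samples(rec) %/% len
  if (k == 0L) warning("segment length exceeds the recording; 0 segments")
  new_segment_set(rec, seg_len_sec, (seq_len(k) - 1L) * len)
}

#' Segment an event recording around event markers
#'
#' One segment per matching event covering `[event + window[1], event +
#' window[2])` seconds; events whose window exceeds the recording bounds
#' are skipped with a warning. Overlapping windows are permitted.
#'
#' @param rec an `eeg_recording` with `input_kind == "event"`.
#' @param tags event labels to segment around (nonempty).
#' @param window numeric length 2: seconds before (usually <= 0) and after
#'   the event.
#' @return an `eeg_segment_set`.
#' @export
segment_events <- function(rec, tags, window) {
  stopifnot(inherits(rec, "eeg_recording"), length(tags) >= 1,
            length(window) == 2, window[2] > window[1])
  if (rec$input_kind != "event")
    stop("event segmentation requires an event-kind recording")
  ev <- rec$events[rec$events$label %in% tags, , drop = FALSE]
  fs <- rec$sample_rate
  len <- as.integer(round((window[2] - window[1]) * fs))
  starts <- ev$sample + as.integer(round(window[1] * fs))
  ok <- starts >= 0L & (starts + len) <= n_samples(rec)
  if (any(!ok))
    warning(sum(!ok), " event window(s) exceed the recording bounds; skipped")
  segs <- new_segment_set(rec, window[2] - window[1], starts[ok])
  segs$seg_len <- len
  segs
}

# joint-probability z-scores come from the estimator shared with
# bad-channel detection (jointprob_z in badchannels.R)

#' Reject artifact-contaminated segments
#'
#' Three criteria, evaluated on all channels or on an ROI subset:
#' \itemize{
#'   \item amplitude: any sample below `amp_lo` or above `amp_hi`
#'     microvolts;
#'   \item single-electrode joint probability: a channel's segment RMS
#'     amplitude is improbable relative to that same channel across
#'     segments (|z| > `z_cut`);
#'   \item electrode-group joint probability: a channel's segment RMS is
#'     improbable relative to all channels within the segment.
#' }
#' All marked segments are rejected simultaneously in a single step. The
#' joint-probability criteria need at least 8 segments; below that only the
#' amplitude criterion runs (with a warning).
#'
#' @param segs an `eeg_segment_set`.
#' @param amp_lo,amp_hi amplitude thresholds in microvolts (default -40 /
#'   +40, reflecting the smaller signal amplitude after wavelet and
#'   component cleaning).
#' @param z_cut joint-probability z cutoff (default 3).
#' @param roi optional channel labels restricting evaluation to a region of
#'   interest.
#' @return the segment set with reject flags and reasons filled in.
#' @export
reject_segments <- function(segs, amp_lo = -40, amp_hi = 40, z_cut = 3,
                            roi = NULL) {
  stopifnot(inherits(segs, "eeg_segment_set"))
  ns <- length(segs$starts)
  if (ns == 0L) return(segs)
  chans <- segs$recording$channel_ids
  if (!is.null(roi)) {
    missing <- setdiff(roi, chans)
    if (length(missing))
      stop("ROI channel(s) not in the recording: ",
           paste(missing, collapse = ", "))
    chans <- roi
    segs$roi_channels <- roi
  }
  crows <- match(chans, segs$recording$channel_ids)
  # per-segment, per-channel RMS amplitude drives both jointprob criteria
  rms <- vapply(seq_len(ns), function(i) {
    m <- segment_matrix(segs, i)[crows, , drop = FALSE]
    sqrt(rowMeans(m^2))
  }, numeric(length(crows)))
  rms <- matrix(rms, nrow = length(crows))   # channels x segments
  for (i in seq_len(ns)) {
    m <- segment_matrix(segs, i)[crows, , drop = FALSE]
    if (any(m < amp_lo) || any(m > amp_hi))
      segs$reasons[[i]] <- c(segs$reasons[[i]], "amplitude")
  }
  if (ns >= 8) {
    if (is.finite(z_cut)) {
      # single electrode: each channel across segments
      for (ci in seq_along(crows)) {
        z <- jointprob_z(rms[ci, ])
        hit <- which(abs(z) > z_cut)
        for (i in hit)
          segs$reasons[[i]] <- union(segs$reasons[[i]], "jointprob_single")
      }
      # electrode group: channels within each segment
      for (i in seq_len(ns)) {
        z <- jointprob_z(rms[, i])
        if (any(abs(z) > z_cut))
          segs$reasons[[i]] <- union(segs$reasons[[i]], "jointprob_group")
      }
    }
  } else if (ns > 0L) {
    warning("fewer than 8 segments: joint-probability criteria skipped")
  }
  segs$rejected <- lengths(segs$reasons) > 0L
  segs
}

#' Interpolate bad channels within individual segments
#'
#' The alternative to segment rejection for short files: per segment, each
#' channel is scored on four criteria - variance, median gradient (median
#' absolute first difference), amplitude range, and deviation from mean
#' amplitude (|segment-channel mean - channel grand mean|) - z-scored
#' across channels within the segment; channels with any |z| > `z_cut` are
#' repaired by spherical-spline interpolation in that segment only.
#'
#' @param segs an `eeg_segment_set` whose recording has a montage.
#' @param z_cut criterion z cutoff (default 3).
#' @return the segment set with repaired data and per-segment interpolated
#'   channel lists.
#' @export
interpolate_within_segments <- function(segs, z_cut = 3) {
  stopifnot(inherits(segs, "eeg_segment_set"))
  montage <- segs$recording$montage
  if (is.null(montage)) stop("per-segment interpolation requires a montage")
  chans <- segs$recording$channel_ids
  grand_mean <- rowMeans(segs$recording$data)
  for (i in seq_along(segs$starts)) {
    m <- segment_matrix(segs, i)
    crit <- cbind(
      variance = apply(m, 1L, stats::var),
      median_gradient = apply(m, 1L, function(x) stats::median(abs(diff(x)))),
      amp_range = apply(m, 1L, function(x) diff(range(x))),
      mean_deviation = abs(rowMeans(m) - grand_mean))
    # same robust joint-probability z as channel/segment rejection: with 4
    # criteria x many segments, plain z-scores over ~19 channels flag clean
    # tail channels far too often
    z <- apply(crit, 2L, jointprob_z)
    bad <- chans[apply(abs(z) > z_cut, 1L, any)]
    if (length(bad) && length(bad) <= length(chans) - 4) {
      seg_rec <- new_recording(m, segs$recording$sample_rate,
                               channel_ids = chans, montage = montage)
      fixed <- interpolate_bad_channels(seg_rec, bad, montage,
                                        full_order = chans)
      idx <- segs$starts[i] + seq_len(segs$seg_len)
      segs$recording$data[, idx] <- fixed$data[chans, ]
      segs$interpolated[[i]] <- bad
    }
  }
  segs
}
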