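#' Select the channel subset to be processed
#'
#' Robust ICA decomposition of short recordings requires limiting the number
#' of channels (see [ica_sample_budget()]), so processing operates on a
#' user-chosen subset that must contain all 19 mapped 10-20 channels (they
#' anchor the spatial features of automated component rejection). Channels
#' outside the subset are removed and cannot be recovered downstream.
#'
#' @param rec an `eeg_recording` with a montage attached (or `montage`
#'   supplied).
#' @param subset character vector of channel labels to retain, in the order
#'   they should appear.
#' @param montage optional `eeg_montage` overriding `rec$montage`.
#' @return The recording restricted to `subset`, in the requested order.
#' @export
select_channel_subset <- function(rec, subset, montage = rec$montage) {
  stopifnot(inherits(rec, "eeg_recording"))
  subset <- as.character(subset)
  unknown <- setdiff(subset, rec$channel_ids)
  if (length(unknown))
    stop("subset contains unknown channel label(s): ",
         paste(unknown, collapse = ", "))
  if (!is.null(montage)) {
    need <- ten_twenty_ids(montage)
    missing <- setdiff(need, subset)
    if (length(missing))
      stop("subset must include every mapped 10-20 channel; missing: ",
           paste(missing, collapse = ", "))
  }
  n_before <- length(rec$channel_ids)
  rec$data <- rec$data[subset, , drop = FALSE]
  rec$channel_ids <- subset
  rec$montage <- montage
  add_history(rec, sprintf("subset:%d->%d", n_before, length(subset)))
}

#' Minimum sample count for a reliable ICA decomposition
#'
#' The recommended constraint for a stable decomposition without
#' overlearning is at least `30 * C^2` data samples for `C` channels. The
#' returned object reports the requirement, whether the available samples
#' meet it, and (given a sampling rate) the corresponding duration.
#'
#' @param n_channels channel count `C` (positive integer).
#' @param n_samples samples available (default `NA` if only the requirement
#'   is wanted).
#' @param sample_rate optional rate in Hz to convert the requirement to
#'   seconds.
#' @return list with `n_channels`, `n_samples_available`,
#'   `n_samples_required` (= `30 * C^2`, exact integer arithmetic),
#'   `sufficient`, and `seconds_required` (NA without a rate).
#' @examples
#' ica_sample_budget(128, sample_rate = 500)  # 491520 samples, 983.04 s
#' ica_sample_budget(40, 75000)               # 48000 required, sufficient
#' @export
ica_sample_budget <- function(n_channels, n_samples = NA_integer_,
                              sample_rate = NULL) {
  if (!is.numeric(n_channels) || length(n_channels) != 1L ||
      n_channels < 1 || n_channels != round(n_channels))
    stop("`n_channels` must be a positive integer")
  C <- as.integer(n_channels)
  required <- 30L * C * C
  avail <- if (is.na(n_samples)) NA_integer_ else as.integer(n_samples)
  structure(list(
    n_channels = C,
    n_samples_available = avail,
    n_samples_required = required,
    sufficient = if (is.na(avail)) NA else avail >= required,
    seconds_required = if (is.null(sample_rate)) NA_real_
                       else required / sample_rate),
    class = "ica_sample_budget")
}

#' @export
print.ica_sample_budget <- function(x, ...) {
  cat(sprintf("ICA sample budget: C = %d needs %d samples", x$n_channels,
              x$n_samples_required))
  if (!is.na(x$n_samples_available))
    cat(sprintf("; available %d (%s)", x$n_samples_available,
                if (isTRUE(x$sufficient)) "sufficient" else "INSUFFICIENT"))
  if (!is.na(x$seconds_required))
    cat(sprintf("; %.2f s at the given rate", x$seconds_required))
  cat("\n")
  invisible(x)
}
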