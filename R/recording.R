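#' Construct an EEG recording object
#'
#' The central container of the package: a channels-by-samples matrix of
#' scalp potentials in microvolts together with its sampling rate, channel
#' labels, optional montage, optional event table, and a provenance history
#' listing every processing step applied so far.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param channel_ids character vector of channel labels, one per row of
#'   `data`. Defaults to rownames of `data` or `"ch1"`, `"ch2"`, ...
#' @param montage optional `eeg_montage` object (see [load_montage()]).
#' @param events optional data.frame with columns `label` (character) and
#'   `sample` (0-based integer sample index into the recording).
#' @param input_kind `"rest"` for continuous resting-state data or `"event"`
#'   for event-marked data.
#' @param history character vector of applied-step descriptors.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, sample_rate, channel_ids = NULL,
                          montage = NULL, events = NULL,
                          input_kind = c("rest", "event"),
                          history = character()) {
  input_kind <- match.arg(input_kind)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (!all(is.finite(data)))
    stop("`data` contains NaN/Inf values")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number (Hz)")
  if (is.null(channel_ids)) {
    channel_ids <- rownames(data)
    if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(data)))
  }
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nrow(data))
    stop("length(channel_ids) must equal nrow(data)")
  if (anyDuplicated(channel_ids))
    stop("duplicate channel labels: ",
         paste(unique(channel_ids[duplicated(channel_ids)]), collapse = ", "))
  rownames(data) <- channel_ids
  if (is.null(events)) {
    events <- data.frame(label = character(), sample = integer(),
                         stringsAsFactors = FALSE)
  } else {
    events <- as.data.frame(events)
    if (!all(c("label", "sample") %in% names(events)))
      stop("`events` needs columns `label` and `sample`")
    events$label <- as.character(events$label)
    events$sample <- as.integer(events$sample)
    if (nrow(events) &&
        (any(events$sample < 0L) || any(events$sample >= ncol(data))))
      stop("event sample indices must lie in [0, n_samples)")
  }
  structure(
    list(data = data, sample_rate = as.numeric(sample_rate),
         channel_ids = channel_ids, montage = montage, events = events,
         input_kind = input_kind, history = as.character(history)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s, %s)\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              ncol(x$data) / x$sample_rate, x$input_kind))
  if (nrow(x$events)) cat(sprintf("  events: %d\n", nrow(x$events)))
  if (length(x$history)) cat("  history:", paste(x$history, collapse = " -> "), "\n")
  invisible(x)
}

#' Number of channels / samples / duration of a recording
#' @param rec an `eeg_recording`.
#' @return integer count (or seconds for `rec_duration`).
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_channels
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$sample_rate

#' Append a provenance entry to a recording's history
#' @param rec an `eeg_recording`.
#' @param step single character descriptor of the applied step.
#' @return the recording with the step appended.
#' @export
add_history <- function(rec, step) {
  rec$history <- c(rec$history, step)
  rec
}

# Replace the data matrix, keeping labels/rate, with validation.
replace_data <- function(rec, data) {
  stopifnot(nrow(data) == length(rec$channel_ids))
  if (!all(is.finite(data))) stop("processing produced non-finite samples")
  rownames(data) <- rec$channel_ids
  rec$data <- data
  rec
}
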