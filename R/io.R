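#' @title Recording readers and writers
#' @description Two on-disk formats are supported. The native format is a
#'   raw little-endian float64 channel-major matrix (`<base>.dat`) with a
#'   JSON sidecar (`<base>.json`) holding the sampling rate, channel labels,
#'   events, input kind and processing history; it round-trips bit-exactly
#'   and is used for all intermediate saves. EDF is supported for exchange
#'   with other EEG software: samples are quantized to 16-bit integers over
#'   a configurable physical range (default +/-3276.7 microvolts, i.e. an
#'   LSB of 0.1 microvolts).
#' @name recording_io
NULL

native_paths <- function(path) {
  base <- sub("\\.(dat|json)$", "", path)
  list(dat = paste0(base, ".dat"), json = paste0(base, ".json"))
}

#' Write a recording to disk
#'
#' @param rec an `eeg_recording`.
#' @param path output path. For `format = "native"` the extension is
#'   replaced so that `<base>.dat` and `<base>.json` are written.
#' @param format `"native"` or `"edf"`.
#' @param physical_max for EDF, the symmetric physical range in microvolts
#'   mapped onto the 16-bit digital range (default 3276.7, LSB 0.1 uV).
#' @return invisibly, the main file path written.
#' @export
write_recording <- function(rec, path, format = c("native", "edf"),
                            physical_max = 3276.7) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  if (format == "native") {
    p <- native_paths(path)
    con <- tryCatch(file(p$dat, "wb"),
                    error = function(e) stop("cannot open for writing: ", p$dat))
    on.exit(close(con), add = TRUE)
    # channel-major: each channel's samples contiguous
    writeBin(as.vector(t(rec$data)), con, size = 8L, endian = "little")
    meta <- list(
      n_channels = nrow(rec$data), n_samples = ncol(rec$data),
      sample_rate = rec$sample_rate, channel_ids = rec$channel_ids,
      input_kind = rec$input_kind, history = rec$history,
      events = rec$events)
    jsonlite::write_json(meta, p$json, auto_unbox = TRUE, digits = NA)
    return(invisible(p$dat))
  }
  write_edf(rec, path, physical_max)
}

#' Read a recording from disk
#'
#' @param path input path (`<base>.dat`/`.json` pair for native, `.edf`
#'   file for EDF).
#' @param format `"native"` or `"edf"`.
#' @return An `eeg_recording` in microvolts.
#' @export
read_recording <- function(path, format = c("native", "edf")) {
  format <- match.arg(format)
  if (format == "native") {
    p <- native_paths(path)
    if (!file.exists(p$dat) || !file.exists(p$json))
      stop("cannot read native recording, missing file(s): ",
           paste(c(p$dat, p$json)[!file.exists(c(p$dat, p$json))], collapse = ", "))
    meta <- jsonlite::read_json(p$json, simplifyVector = TRUE)
    n <- meta$n_channels * meta$n_samples
    raw <- readBin(p$dat, what = "double", n = n + 1L, size = 8L,
                   endian = "little")
    if (length(raw) != n)
      stop("native data file length does not match header: ", p$dat)
    data <- matrix(raw, nrow = meta$n_channels, ncol = meta$n_samples,
                   byrow = TRUE)
    events <- meta$events
    if (is.null(events) || length(events) == 0L) events <- NULL
    rec <- new_recording(data, meta$sample_rate,
                         channel_ids = meta$channel_ids, events = events,
                         input_kind = meta$input_kind,
                         history = meta$history %||% character())
    return(add_history(rec, paste0("read:", p$dat)))
  }
  read_edf(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- EDF ----------------------------------------------------------------
# Continuous EDF with 1-second data records. When the recording length is
# not a whole number of seconds the final record is zero-padded and the true
# sample count is stored in the reserved header field as "NSAMP=<n>", which
# this package's reader honours (foreign readers see trailing zeros).

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

write_edf <- function(rec, path, physical_max = 3276.7) {
  fs <- rec$sample_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate; got ", fs)
  fs <- as.integer(round(fs))
  nc <- nrow(rec$data); ns <- ncol(rec$data)
  n_rec <- ceiling(ns / fs)
  if (max(abs(rec$data)) > physical_max)
    warning("samples exceed the EDF physical range and will be clipped")
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (nc + 1), 8),
    pad_field(paste0("NSAMP=", ns), 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(nc, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(vapply(rec$channel_ids, pad_field, "", width = 16),
                   collapse = ""), con, eos = NULL)
  rep_field <- function(x, w) paste0(rep(pad_field(x, w), nc), collapse = "")
  writeChar(rep_field("EEG", 80), con, eos = NULL)       # transducer
  writeChar(rep_field("uV", 8), con, eos = NULL)         # physical dimension
  writeChar(rep_field(-physical_max, 8), con, eos = NULL)
  writeChar(rep_field(physical_max, 8), con, eos = NULL)
  writeChar(rep_field(-32767, 8), con, eos = NULL)
  writeChar(rep_field(32767, 8), con, eos = NULL)
  writeChar(rep_field("", 80), con, eos = NULL)          # prefiltering
  writeChar(rep_field(fs, 8), con, eos = NULL)           # samples per record
  writeChar(rep_field("", 32), con, eos = NULL)          # reserved
  scale <- physical_max / 32767
  padded <- cbind(rec$data,
                  matrix(0, nc, n_rec * fs - ns))
  dig <- round(pmin(pmax(padded, -physical_max), physical_max) / scale)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  sz <- file.info(path)$size
  if (sz < 256) stop("truncated EDF header (file too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                  # version
  rd(80); rd(80); rd(8); rd(8)           # ids, dates
  hdr_bytes <- suppressWarnings(as.integer(rd(8)))
  reserved <- rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  nc <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(hdr_bytes, n_rec, rec_dur, nc)) || nc < 1)
    stop("malformed EDF header in ", path)
  if (sz < 256 * (nc + 1)) stop("truncated EDF header (signal fields): ", path)
  labels <- vapply(seq_len(nc), function(i) rd(16), "")
  vapply(seq_len(nc), function(i) rd(80), "")
  dims <- vapply(seq_len(nc), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  vapply(seq_len(nc), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(nc), function(i) rd(8), ""))
  vapply(seq_len(nc), function(i) rd(32), "")
  if (length(unique(spr)) != 1L)
    stop("EDF files with per-signal sampling rates are not supported: ", path)
  expected <- 256 * (nc + 1) + 2 * n_rec * sum(spr)
  if (sz < expected)
    stop("EDF data shorter than header promises (", sz, " < ", expected,
         " bytes): ", path)
  fs <- spr[1] / rec_dur
  total <- n_rec * spr[1]
  data <- matrix(0, nc, total)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = nc * spr[1], size = 2L,
                     signed = TRUE, endian = "little")
    data[, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
      matrix(block, nrow = nc, byrow = TRUE)
  }
  # digital -> physical, per signal; convert mV/V dimensions to uV
  unit_scale <- ifelse(tolower(dims) == "mv", 1e3,
                       ifelse(tolower(dims) == "v", 1e6, 1))
  for (i in seq_len(nc)) {
    g <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    data[i, ] <- (data[i, ] - dmin_[i]) * g + pmin_[i]
    data[i, ] <- data[i, ] * unit_scale[i]
  }
  m <- regmatches(reserved, regexec("NSAMP=([0-9]+)", reserved))[[1]]
  if (length(m) == 2L) {
    ns <- as.integer(m[2])
    if (ns <= total) data <- data[, seq_len(ns), drop = FALSE]
  }
  rec <- new_recording(data, fs, channel_ids = labels)
  add_history(rec, paste0("read:", path))
}
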