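# Improbability score of each value among its peers: log-compressed
# negative log of a leave-one-out Gaussian kernel density with a robust
# (nrd0) bandwidth. Leave-one-out keeps a far outlier's own kernel from
# masking it; the robust bandwidth keeps it from widening everyone's
# kernels; the outer log compresses the saturated scores of extreme
# outliers so that two simultaneous outliers do not dilute each other's
# z-scores.
neglog_density_scores <- function(values) {
  bw <- tryCatch(stats::bw.nrd0(values), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0)
    bw <- max(stats::sd(values), 1e-12) / 4
  n <- length(values)
  d <- vapply(seq_len(n), function(i)
    mean(stats::dnorm((values[i] - values[-i]) / bw)) / bw, numeric(1))
  raw <- -log(pmax(d, 1e-300))
  sign(raw) * log1p(abs(raw))       # signed log compression, monotone in raw
}

#' Joint-probability outlier flagging
#'
#' Estimates the empirical density of a per-channel summary statistic with a
#' Gaussian kernel (robust bandwidth), scores each channel by the negative
#' log density at its own value (its "improbability"), z-scores those
#' scores, and flags values beyond the cutoff. With fewer than 8 channels
#' the density estimate is unstable, so a plain z-score on the raw values
#' is used instead (with a warning).
#'
#' @param values named numeric vector, one summary value per channel.
#' @param z_cut two-sided z cutoff (default 3).
#' @return character vector of flagged channel names (empty when all values
#'   are identical).
#' @export
joint_probability_outliers <- function(values, z_cut = 3) {
  stopifnot(is.numeric(values))
  if (is.null(names(values))) names(values) <- as.character(seq_along(values))
  rng <- range(values)
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[1]))) return(character())
  if (length(values) < 8) {
    warning("fewer than 8 channels: falling back to a plain z-score")
    z <- (values - mean(values)) / stats::sd(values)
    return(names(values)[abs(z) > z_cut])
  }
  z <- jointprob_z(values)
  names(values)[abs(z) > z_cut]
}

# Effective joint-probability z: a unit is flagged only when both its
# improbability score AND its raw value sit beyond the cutoff, i.e. the
# effective |z| is the smaller of the two magnitudes. The value condition
# anchors the "3 standard deviations from the mean" semantics; the density
# condition keeps the flag specific to genuinely isolated values.
jointprob_z <- function(values) {
  rng <- range(values)
  if (!is.finite(diff(rng)) || diff(rng) < 1e-300) return(rep(0, length(values)))
  stat <- neglog_density_scores(values)
  sdv <- stats::sd(stat)
  sdval <- stats::sd(values)
  if (!is.finite(sdv) || sdv < 1e-12 || sdval < 1e-12)
    return(rep(0, length(values)))
  zs <- (stat - mean(stat)) / sdv
  zv <- (values - mean(values)) / sdval
  sign(zs) * pmin(abs(zs), abs(zv))
}

#' Detect bad channels (two-pass joint probability of band log power)
#'
#' Each channel is summarized by its average log power from 1 to 125 Hz
#' ([avg_log_power()]); channels whose normed joint probability of that
#' statistic falls more than `z_cut` standard deviations from the mean are
#' flagged. The evaluation runs twice - the second pass on the survivors -
#' because grossly bad channels can mask moderately bad ones in the first
#' pass. Flagged channels are excluded from all later stages until
#' [interpolate_bad_channels()] restores them.
#'
#' @param rec a filtered, line-cleaned `eeg_recording`.
#' @param z_cut z cutoff (default 3).
#' @param band power band in Hz (default `c(1, 125)`, clipped to Nyquist-1).
#' @return list of class `bad_channel_result`: `bad_ids`, `pass1_ids`,
#'   `pass2_ids`, and `stats` (per-channel average log power with pass-1
#'   z-scores).
#' @export
detect_bad_channels <- function(rec, z_cut = 3, band = c(1, 125)) {
  stopifnot(inherits(rec, "eeg_recording"))
  vals <- avg_log_power(rec, band)
  pass1 <- joint_probability_outliers(vals, z_cut)
  survivors <- setdiff(rec$channel_ids, pass1)
  pass2 <- character()
  if (length(survivors) >= 2) {
    rec2 <- rec
    rec2$data <- rec$data[survivors, , drop = FALSE]
    rec2$channel_ids <- survivors
    pass2 <- joint_probability_outliers(avg_log_power(rec2, band), z_cut)
  }
  bad <- union(pass1, pass2)
  if (length(bad) > 0.5 * length(rec$channel_ids))
    warning(sprintf("more than half of the channels flagged bad (%d of %d)",
                    length(bad), length(rec$channel_ids)))
  structure(list(bad_ids = bad, pass1_ids = pass1, pass2_ids = pass2,
                 stats = data.frame(channel = names(vals),
                                    avg_log_power = unname(vals),
                                    row.names = NULL)),
            class = "bad_channel_result")
}

#' Drop a set of channels from a recording
#' @param rec an `eeg_recording`.
#' @param ids labels to drop.
#' @return the recording without those channels.
#' @export
drop_channels <- function(rec, ids) {
  keep <- setdiff(rec$channel_ids, ids)
  if (!length(keep)) stop("cannot drop every channel")
  rec$data <- rec$data[keep, , drop = FALSE]
  rec$channel_ids <- keep
  if (length(ids)) rec <- add_history(rec, paste0("drop:", paste(ids, collapse = "+")))
  rec
}
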