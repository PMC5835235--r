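#' @title Pipeline orchestration and the processing report
#' @description [run_pipeline()] drives the full per-file stage order:
#'   read, filter (band-pass for rates >= 500 Hz, high-pass otherwise),
#'   channel-subset selection, line-noise removal, two-pass bad-channel
#'   detection, wavelet-enhanced ICA, ICA with automated component
#'   rejection, the optional segmentation branch, interpolation of bad
#'   channels, re-referencing, and output. One quality-report row is
#'   appended per file; a failing file is logged and skipped without
#'   stopping the batch.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param channel_subset labels to process (must include the 19 mapped
#'   10-20 channels); `NULL` processes all channels.
#' @param montage montage source: builtin name or file path (see
#'   [load_montage()]).
#' @param ten_twenty optional named character vector overriding the 10-20
#'   map.
#' @param input_kind `"rest"` or `"event"`.
#' @param format input file format, `"native"` or `"edf"`.
#' @param line_freq line frequency in Hz (default 60); `NA` disables
#'   line-noise removal.
#' @param segment_mode `"none"`, `"reject"` or `"interpolate"` (the two
#'   artifact options are mutually exclusive per run).
#' @param seg_len_sec resting segment length in seconds (default 2).
#' @param event_tags,event_window event segmentation inputs (event kind
#'   only).
#' @param amp_threshold_uv symmetric segment amplitude threshold (default
#'   40 microvolts).
#' @param seg_roi optional ROI channel labels for segment rejection.
#' @param reference `"average"` or a character vector of reference
#'   channels.
#' @param output_dir where outputs are written (created if needed).
#' @param seed integer seed for both ICA decompositions.
#' @param emit_intermediates save intermediate files after filtering,
#'   wavelet cleaning, ICA (with component information), component
#'   rejection and segmentation (default `FALSE`).
#' @param semi_automated export a per-stage PSD CSV for visual review
#'   (default `FALSE`).
#' @param classifier a `component_classifier` (default: shipped weights).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(channel_subset = NULL, montage = "sphere128",
                            ten_twenty = NULL,
                            input_kind = c("rest", "event"),
                            format = c("native", "edf"),
                            line_freq = 60,
                            segment_mode = c("none", "reject", "interpolate"),
                            seg_len_sec = 2, event_tags = NULL,
                            event_window = c(-0.1, 0.9),
                            amp_threshold_uv = 40, seg_roi = NULL,
                            reference = "average",
                            output_dir = tempfile("eegclean_out"),
                            seed = 1,
                            emit_intermediates = FALSE,
                            semi_automated = FALSE,
                            classifier = NULL) {
  cfg <- list(channel_subset = channel_subset, montage = montage,
              ten_twenty = ten_twenty,
              input_kind = match.arg(input_kind),
              format = match.arg(format),
              line_freq = line_freq,
              segment_mode = match.arg(segment_mode),
              seg_len_sec = seg_len_sec, event_tags = event_tags,
              event_window = event_window,
              amp_threshold_uv = amp_threshold_uv, seg_roi = seg_roi,
              reference = reference, output_dir = output_dir,
              seed = as.integer(seed),
              emit_intermediates = isTRUE(emit_intermediates),
              semi_automated = isTRUE(semi_automated),
              classifier = classifier)
  stopifnot(cfg$seg_len_sec > 0, cfg$amp_threshold_uv > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- intersect(names(raw), names(formals(pipeline_config)))
  do.call(pipeline_config, raw[keep])
}

report_columns <- c(
  "Filename", "File_length_in_sec", "Number_channels_userSelected",
  "Number_epochs_post_epoch_rejection", "Number_good_channels_selected",
  "Percent_good_channels_selected", "Interpolated_channel_IDs",
  "Number_ICs_rejected", "Percent_ICs_rejected",
  "Percent_variance_kept_of_post_waveleted_data",
  "Median_artifact_probability_of_kept_ICs",
  "Mean_artifact_probability_of_kept_ICs",
  "Range_artifact_probability_of_kept_ICs",
  "Min_artifact_probability_of_kept_ICs",
  "Max_artifact_probability_of_kept_ICs", "Flags")

#' Process one in-memory recording through the full stage order
#'
#' The per-file worker behind [run_pipeline()]; useful directly in scripts
#' and tests. Artifact-probability metrics describe the kept components and
#' are computed before any segment rejection or per-segment interpolation.
#'
#' @param rec an `eeg_recording` (with a montage, or one is attached from
#'   `cfg`).
#' @param cfg a [pipeline_config()].
#' @param filename name recorded in the report row.
#' @return list with `recording` (fully processed), `segments` (or NULL),
#'   `report` (one-row data.frame), `bad_channels`, `evaluations`, and
#'   `intermediates` (named list of recordings when
#'   `cfg$emit_intermediates`).
#' @export
process_recording <- function(rec, cfg, filename = "recording") {
  stopifnot(inherits(rec, "eeg_recording"), inherits(cfg, "pipeline_config"))
  if (is.null(rec$montage))
    rec$montage <- load_montage(cfg$montage, cfg$ten_twenty)
  flags <- character()
  inter <- list()
  keep_inter <- function(name, r) {
    if (cfg$emit_intermediates) inter[[name]] <<- r
  }
  file_len_sec <- rec_duration(rec)

  rec <- bandpass_if_high_rate(rec)
  keep_inter("filtered", rec)

  subset <- cfg$channel_subset %||% rec$channel_ids
  rec <- select_channel_subset(rec, subset)
  n_selected <- n_channels(rec)
  budget <- ica_sample_budget(n_selected, n_samples(rec), rec$sample_rate)
  if (!isTRUE(budget$sufficient))
    stop(sprintf(paste("ICA sample budget not met: %d channels need %d",
                       "samples, file has %d; select a smaller subset"),
                 budget$n_channels, budget$n_samples_required,
                 budget$n_samples_available))

  if (!is.na(cfg$line_freq))
    rec <- remove_line_noise(rec, line_noise_config(cfg$line_freq))

  bad <- withCallingHandlers(
    detect_bad_channels(rec),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  full_order <- rec$channel_ids
  rec <- drop_channels(rec, bad$bad_ids)

  wres <- wica_clean(rec, cfg$seed)
  rec <- wres$cleaned
  keep_inter("wavclean", rec)

  dec <- run_extended_infomax(rec, cfg$seed)
  evals <- classify_components(dec, rec$montage, rec$sample_rate,
                               clf = cfg$classifier %||%
                                 load_classifier_weights())
  pre_reject <- rec
  rec <- reject_and_project(rec, dec, evals)
  keep_inter("postreject", rec)
  pvk <- percent_variance_kept(pre_reject, rec)

  kept_p <- evals$artifact_probability[!evals$rejected]
  n_rej <- sum(evals$rejected)

  segs <- NULL
  n_epochs <- NA_integer_
  if (cfg$segment_mode != "none") {
    segs <- if (cfg$input_kind == "event")
      segment_events(rec, cfg$event_tags, cfg$event_window)
    else segment_rest(rec, cfg$seg_len_sec)
    segs <- withCallingHandlers(
      if (cfg$segment_mode == "reject")
        reject_segments(segs, -cfg$amp_threshold_uv, cfg$amp_threshold_uv,
                        roi = cfg$seg_roi)
      else interpolate_within_segments(segs),
      warning = function(w) {
        flags <<- c(flags, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    rec <- segs$recording
    n_epochs <- n_retained_segments(segs)
    keep_inter("segmented", rec)
  }

  rec <- interpolate_bad_channels(rec, bad$bad_ids, rec$montage,
                                  full_order = full_order)
  rec <- if (identical(cfg$reference, "average"))
    rereference(rec, "average")
  else rereference(rec, "channels", cfg$reference)

  report <- data.frame(
    Filename = filename,
    File_length_in_sec = file_len_sec,
    Number_channels_userSelected = n_selected,
    Number_epochs_post_epoch_rejection = n_epochs,
    Number_good_channels_selected = n_selected - length(bad$bad_ids),
    Percent_good_channels_selected =
      100 * (n_selected - length(bad$bad_ids)) / n_selected,
    Interpolated_channel_IDs = paste(sort(bad$bad_ids), collapse = " "),
    Number_ICs_rejected = n_rej,
    Percent_ICs_rejected = 100 * n_rej / nrow(evals),
    Percent_variance_kept_of_post_waveleted_data = pvk,
    Median_artifact_probability_of_kept_ICs =
      if (length(kept_p)) stats::median(kept_p) else NA_real_,
    Mean_artifact_probability_of_kept_ICs =
      if (length(kept_p)) mean(kept_p) else NA_real_,
    Range_artifact_probability_of_kept_ICs =
      if (length(kept_p)) max(kept_p) - min(kept_p) else NA_real_,
    Min_artifact_probability_of_kept_ICs =
      if (length(kept_p)) min(kept_p) else NA_real_,
    Max_artifact_probability_of_kept_ICs =
      if (length(kept_p)) max(kept_p) else NA_real_,
    Flags = paste(unique(flags), collapse = "; "),
    stringsAsFactors = FALSE)

  list(recording = rec, segments = segs, report = report,
       bad_channels = bad, evaluations = evals,
       decomposition = dec, intermediates = inter)
}

#' Run the pipeline over a batch of files
#'
#' All files must share one channel layout; sampling rates may differ. The
#' ICA sample budget is checked against the shortest file before any
#' processing starts. Per-file failures are logged and the batch
#' continues. The quality report is written as
#' `file.path(cfg$output_dir, "processing_report.csv")`.
#'
#' @param cfg a [pipeline_config()].
#' @param files character vector of input paths.
#' @return the quality report data.frame (one row per successfully
#'   processed file), invisibly carrying attribute `failures` (named list
#'   of error messages).
#' @export
run_pipeline <- function(cfg, files) {
  stopifnot(inherits(cfg, "pipeline_config"), length(files) >= 1)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  montage <- load_montage(cfg$montage, cfg$ten_twenty)
  recs_len <- vapply(files, function(f) {
    r <- tryCatch(read_recording(f, cfg$format), error = function(e) NULL)
    if (is.null(r)) NA_real_ else n_samples(r)
  }, numeric(1))
  n_sub <- length(cfg$channel_subset %||% ten_twenty_ids(montage))
  if (!is.null(cfg$channel_subset)) {
    shortest <- suppressWarnings(min(recs_len, na.rm = TRUE))
    b <- ica_sample_budget(n_sub, shortest)
    if (is.finite(shortest) && !isTRUE(b$sufficient))
      stop(sprintf(paste("channel subset of %d requires %d samples but the",
                         "shortest file has %d"),
                   n_sub, b$n_samples_required, as.integer(shortest)))
  }
  rows <- list()
  failures <- list()
  for (f in files) {
    res <- tryCatch({
      rec <- read_recording(f, cfg$format)
      rec$montage <- montage
      rec$input_kind <- cfg$input_kind
      out <- process_recording(rec, cfg,
                               filename = sub("\\.[a-z]+$", "", basename(f)))
      base <- file.path(cfg$output_dir,
                        paste0(sub("\\.[a-z]+$", "", basename(f)),
                               "_processed"))
      write_recording(out$recording, base, "native")
      if (cfg$emit_intermediates)
        for (nm in names(out$intermediates))
          write_recording(out$intermediates[[nm]],
                          paste0(base, "_", nm), "native")
      if (cfg$emit_intermediates)
        write_decomposition(out$recording, out$decomposition,
                            paste0(base, "_postica"))
      if (cfg$semi_automated)
        export_psd(out$recording, paste0(base, "_psd.csv"))
      utils::write.csv(out$evaluations,
                       paste0(base, "_components.csv"), row.names = FALSE)
      out$report
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[f]] <- conditionMessage(res)
      message("FAILED ", f, ": ", conditionMessage(res))
    } else rows[[f]] <- res
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(report_columns))),
                    report_columns)
  rownames(report) <- NULL
  utils::write.csv(report, file.path(cfg$output_dir, "processing_report.csv"),
                   row.names = FALSE)
  attr(report, "failures") <- failures
  report
}

#' Cohort summary of a quality report
#'
#' Mean, standard deviation and quartiles of each numeric report metric
#' across files, for users' own cohort descriptions.
#'
#' @param report a quality-report data.frame (from [run_pipeline()] or read
#'   back from its CSV).
#' @return data.frame with one row per metric and columns `mean`, `std`,
#'   `p25`, `p50`, `p75`.
#' @export
summarize_cohort <- function(report) {
  num <- report[vapply(report, is.numeric, logical(1))]
  out <- do.call(rbind, lapply(names(num), function(nm) {
    v <- num[[nm]][is.finite(num[[nm]])]
    if (!length(v)) v <- NA_real_
    data.frame(metric = nm, mean = mean(v), std = stats::sd(v),
               p25 = unname(stats::quantile(v, 0.25)),
               p50 = unname(stats::quantile(v, 0.5)),
               p75 = unname(stats::quantile(v, 0.75)))
  }))
  rownames(out) <- NULL
  out
}
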