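#' @title Automated component rejection
#' @description Every ICA component is scored on the six features of
#'   [component_features] and passed through a standardized logistic head
#'   that outputs an artifact probability in [0, 1]; components with
#'   probability strictly above 0.5 are rejected. The head's weights are not
#'   tied to any published training set: the package ships weights
#'   calibrated on its own labeled synthetic component corpus (a scripted,
#'   seeded procedure, see [calibrate_classifier()]), and externally trained
#'   weights can be supplied through the same structure.
#' @name component_rejection
NULL

feature_names <- c("mean_local_skewness", "log_alpha_power", "lambda",
                   "fit_error", "range_within_pattern",
                   "current_density_norm")

#' Extract the six-feature vector of one component
#'
#' @param source component time series.
#' @param scalp_map per-channel activation over the head model's channels.
#' @param fs sampling rate in Hz.
#' @param head an `eeg_head_model`.
#' @return named numeric vector of the six features.
#' @export
component_features <- function(source, scalp_map, fs, head) {
  f34 <- fit_one_over_f(source, fs)
  stats::setNames(
    c(mean_local_skewness(source, fs),
      log_alpha_power(source, fs),
      f34$lambda, f34$fit_error,
      range_within_pattern(scalp_map),
      current_density_norm(scalp_map, head)),
    feature_names)
}

#' Load or construct classifier weights
#'
#' @param path JSON file with fields `weights` (6, named), `bias`,
#'   `feature_mean`, `feature_sd`. Default: the calibrated weights shipped
#'   with the package (trained on the synthetic labeled corpus).
#' @return list of class `component_classifier`.
#' @export
load_classifier_weights <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "classifier_weights.json",
                        package = "eegclean", mustWork = TRUE)
  w <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_classifier(unlist(w$weights), w$bias, unlist(w$feature_mean),
                 unlist(w$feature_sd))
}

#' @rdname load_classifier_weights
#' @param weights length-6 numeric logistic weights (feature order of
#'   `component_features`).
#' @param bias scalar intercept.
#' @param feature_mean,feature_sd length-6 standardization statistics.
#' @export
new_classifier <- function(weights, bias, feature_mean, feature_sd) {
  stopifnot(length(weights) == 6, length(feature_mean) == 6,
            length(feature_sd) == 6, all(feature_sd > 0))
  structure(list(weights = stats::setNames(as.numeric(weights), feature_names),
                 bias = as.numeric(bias),
                 feature_mean = stats::setNames(as.numeric(feature_mean),
                                                feature_names),
                 feature_sd = stats::setNames(as.numeric(feature_sd),
                                              feature_names)),
            class = "component_classifier")
}

#' Artifact probability of a feature vector
#' @param clf a `component_classifier`.
#' @param features named numeric vector (or rows of a matrix) of the six
#'   features.
#' @return probability in [0, 1].
#' @export
classifier_probability <- function(clf, features) {
  if (is.matrix(features)) {
    z <- sweep(sweep(features, 2L, clf$feature_mean), 2L, clf$feature_sd, "/")
    return(as.vector(stats::plogis(z %*% clf$weights + clf$bias)))
  }
  z <- (features - clf$feature_mean) / clf$feature_sd
  stats::plogis(sum(z * clf$weights) + clf$bias)
}

#' Score every component of a decomposition
#'
#' Reads each component's scalp map from the mixing-matrix rows of the
#' 10-20 anchor channels present in the decomposition, extracts the six
#' features, and assigns an artifact probability; components with p > 0.5
#' are marked rejected. At most 4 of the 19 anchors may be missing (e.g.
#' removed as bad channels) before the spatial features become unreliable.
#'
#' @param dec an `eeg_decomposition`.
#' @param montage an `eeg_montage`.
#' @param fs sampling rate in Hz.
#' @param clf a `component_classifier` (default: shipped weights).
#' @param head optional prebuilt `eeg_head_model` (rebuilt for the available
#'   anchors otherwise).
#' @return data.frame, one row per component: the six features,
#'   `artifact_probability`, `rejected`.
#' @export
classify_components <- function(dec, montage, fs,
                                clf = load_classifier_weights(),
                                head = NULL) {
  stopifnot(inherits(dec, "eeg_decomposition"))
  ids <- ten_twenty_ids(montage)
  present <- ids[ids %in% dec$channel_ids]
  if (length(ids) - length(present) > 4)
    stop(sprintf(paste("only %d of the %d 10-20 anchor channels available;",
                       "spatial features unreliable"),
                 length(present), length(ids)))
  if (is.null(head) || !identical(head$channel_ids, present)) {
    sub <- montage
    sub$ten_twenty <- montage$ten_twenty[match(present, ids)]
    head <- build_head_model(sub)
  }
  rows <- match(present, dec$channel_ids)
  feats <- t(vapply(seq_len(nrow(dec$sources)), function(i) {
    component_features(dec$sources[i, ], dec$mixing[rows, i], fs, head)
  }, numeric(6)))
  colnames(feats) <- feature_names
  p <- classifier_probability(clf, feats)
  out <- data.frame(component = seq_len(nrow(feats)), feats,
                    artifact_probability = p, rejected = p > 0.5)
  rownames(out) <- NULL
  out
}

#' Remove rejected components from a recording
#'
#' Projects the data back to channel space without the components marked
#' rejected in `evals`.
#'
#' @param rec the `eeg_recording` the decomposition was computed from.
#' @param dec its `eeg_decomposition`.
#' @param evals the data.frame from [classify_components()].
#' @return the cleaned recording, history appended.
#' @export
reject_and_project <- function(rec, dec, evals) {
  drop <- evals$component[evals$rejected]
  data <- project_without_components(dec, drop)
  rec <- replace_data(rec, data)
  add_history(rec, sprintf("reject_components:%d/%d", length(drop),
                           nrow(evals)))
}

#' Percent of signal variance kept
#'
#' `100 * (1 - var(pre - post) / var(pre))`, with variances pooled over all
#' channels and samples; the retained-variance accounting reported after
#' component rejection.
#'
#' @param pre,post `eeg_recording`s (or matrices) of equal shape.
#' @return percent in (usually) [0, 100]; exactly 100 when `post == pre`.
#' @export
percent_variance_kept <- function(pre, post) {
  a <- if (inherits(pre, "eeg_recording")) pre$data else pre
  b <- if (inherits(post, "eeg_recording")) post$data else post
  stopifnot(all(dim(a) == dim(b)))
  vd <- stats::var(as.vector(a - b))
  vp <- stats::var(as.vector(a))
  if (vp < 1e-300) return(100)
  100 * (1 - vd / vp)
}

#' Calibrate the logistic head on a synthetic labeled corpus
#'
#' Generates `n_per_class` labeled components per class for each training
#' seed with [generate_labeled_components()], extracts the six features,
#' standardizes them, and fits a logistic regression of the artifact label
#' on the standardized features. The whole procedure is deterministic given
#' the seeds.
#'
#' @param seeds integer vector of corpus seeds (one corpus per seed).
#' @param n_per_class components per class per seed (default 2).
#' @param montage montage for scalp maps (default `standard1020`).
#' @param fs sampling rate of the synthetic components (default 250).
#' @param duration_sec component length in seconds (default 60).
#' @return a `component_classifier`.
#' @export
calibrate_classifier <- function(seeds = 1:25, n_per_class = 2,
                                 montage = load_montage("standard1020"),
                                 fs = 250, duration_sec = 60) {
  head <- build_head_model(montage)
  corpus <- do.call(rbind, lapply(seeds, function(s) {
    lc <- generate_labeled_components(seed = s, n_per_class = n_per_class,
                                      montage = montage, fs = fs,
                                      duration_sec = duration_sec)
    feats <- t(mapply(function(src, map) component_features(src, map, fs, head),
                      lc$sources, lc$maps))
    data.frame(feats, artifact = lc$artifact)
  }))
  X <- as.matrix(corpus[, feature_names])
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv < 1e-9] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  y <- as.integer(corpus$artifact)
  # ridge-regularized logistic fit: synthetic classes can be perfectly
  # separable, where an unpenalized fit would diverge
  fit <- glmnet::glmnet(Z, y, family = "binomial", alpha = 0,
                        lambda = 0.02, standardize = FALSE)
  co <- as.numeric(stats::coef(fit))
  names(co) <- c("(Intercept)", colnames(Z))
  new_classifier(co[feature_names], co["(Intercept)"], mu, sdv)
}

#' Write classifier weights to JSON
#' @param clf a `component_classifier`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_classifier_weights <- function(clf, path) {
  jsonlite::write_json(
    list(weights = as.list(clf$weights), bias = clf$bias,
         feature_mean = as.list(clf$feature_mean),
         feature_sd = as.list(clf$feature_sd)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
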