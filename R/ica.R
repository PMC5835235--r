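#' Extended Infomax ICA decomposition
#'
#' Decomposes centered, PCA-sphered channel data into maximally independent
#' sources by natural-gradient extended Infomax, whose online kurtosis-sign
#' switching separates both supergaussian sources (blinks, muscle bursts)
#' and subgaussian ones (line noise). The decomposition is deterministic
#' given `seed`; across seeds the component order and signs may differ, so
#' the seed is recorded in the result and should be logged with any
#' analysis.
#'
#' Rank-deficient data (e.g. fewer true sources than channels) is detected
#' during sphering and reduced to its effective rank with a warning; the
#' mixing and unmixing matrices then map between the full channel space and
#' the reduced component space.
#'
#' @param data channels x samples numeric matrix, or an `eeg_recording`.
#' @param seed integer seed for the decomposition's internal RNG.
#' @param max_iter maximum training passes over the data (default 512).
#' @param w_stop stop when the squared weight change per pass falls below
#'   this (default 1e-7).
#' @param ext_interval re-estimate kurtosis signs every this many blocks on
#'   6000 subsampled points (default 1).
#' @param rank_tol relative eigenvalue tolerance for rank detection
#'   (default 1e-7).
#' @return An `eeg_decomposition`: `unmixing` (components x channels,
#'   applied to centered data), `mixing` (channels x components), `sources`
#'   (components x samples), `sphering`, `channel_means`, `channel_ids`,
#'   `seed`, `converged`, `n_iter`.
#' @export
run_extended_infomax <- function(data, seed, max_iter = 512, w_stop = 1e-7,
                                 ext_interval = 1, rank_tol = 1e-7) {
  channel_ids <- NULL
  if (inherits(data, "eeg_recording")) {
    channel_ids <- data$channel_ids
    data <- data$data
  }
  stopifnot(is.matrix(data), is.numeric(data))
  K <- nrow(data); N <- ncol(data)
  if (is.null(channel_ids))
    channel_ids <- rownames(data) %||% paste0("ch", seq_len(K))
  if (N < 30 * K^2)
    warning(sprintf(paste("only %d samples for %d channels; at least %d",
                          "recommended for a reliable decomposition"),
                    N, K, 30L * K * K))
  mu <- rowMeans(data)
  Xc <- data - mu
  cv <- tcrossprod(Xc) / (N - 1)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- eg$values > rank_tol * eg$values[1]
  r <- sum(keep)
  if (r < K)
    warning(sprintf("rank-deficient data: reducing %d channels to rank %d",
                    K, r))
  E <- eg$vectors[, seq_len(r), drop = FALSE]
  sph <- diag(1 / sqrt(eg$values[seq_len(r)]), r) %*% t(E)  # r x K
  Xs <- sph %*% Xc
  fit <- .infomax_core(Xs, as.integer(seed), max_iter = as.integer(max_iter),
                       w_stop = w_stop, ext_interval = as.integer(ext_interval))
  W <- fit$W
  unmix <- W %*% sph                        # r x K on centered data
  mix <- E %*% diag(sqrt(eg$values[seq_len(r)]), r) %*% solve(W)  # K x r
  S <- unmix %*% Xc
  # order components by the channel-space variance they carry
  v <- colMeans(mix^2) * apply(S, 1L, stats::var)
  ord <- order(v, decreasing = TRUE)
  unmix <- unmix[ord, , drop = FALSE]
  mix <- mix[, ord, drop = FALSE]
  S <- S[ord, , drop = FALSE]
  # sign convention: largest-magnitude mixing weight positive
  for (i in seq_len(r)) {
    s <- sign(mix[which.max(abs(mix[, i])), i])
    if (s < 0) { mix[, i] <- -mix[, i]; unmix[i, ] <- -unmix[i, ]
                 S[i, ] <- -S[i, ] }
  }
  structure(list(unmixing = unmix, mixing = mix, sources = S,
                 sphering = sph, channel_means = mu,
                 channel_ids = channel_ids, seed = as.integer(seed),
                 converged = isTRUE(fit$converged),
                 n_iter = fit$n_iter),
            class = "eeg_decomposition")
}

#' @export
print.eeg_decomposition <- function(x, ...) {
  cat(sprintf("<eeg_decomposition> %d components x %d samples (seed %d, %s in %d passes)\n",
              nrow(x$sources), ncol(x$sources), x$seed,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Reconstruct channel data without selected components
#'
#' Projects the decomposition back to channel space with the listed
#' components removed: `mixing[, keep] %*% sources[keep, ]` plus the channel
#' means. Dropping nothing returns the decomposed input (within numerical
#' tolerance); dropping everything returns the channel means with a
#' warning.
#'
#' @param dec an `eeg_decomposition`.
#' @param drop integer indices of components to remove.
#' @return channels x samples matrix.
#' @export
project_without_components <- function(dec, drop = integer()) {
  stopifnot(inherits(dec, "eeg_decomposition"))
  r <- nrow(dec$sources)
  drop <- as.integer(drop)
  if (length(drop) && (min(drop) < 1L || max(drop) > r))
    stop("component indices out of range 1..", r)
  keep <- setdiff(seq_len(r), drop)
  if (!length(keep)) {
    warning("all components dropped; returning channel means")
    return(matrix(dec$channel_means, length(dec$channel_means),
                  ncol(dec$sources)))
  }
  dec$mixing[, keep, drop = FALSE] %*%
    dec$sources[keep, , drop = FALSE] + dec$channel_means
}

#' Save a decomposition alongside its recording
#'
#' Writes the post-ICA intermediate with the component information intact:
#' the recording in native format plus a JSON file holding the unmixing and
#' mixing matrices and the seed.
#'
#' @param rec the `eeg_recording` the decomposition belongs to.
#' @param dec an `eeg_decomposition`.
#' @param path base output path (a `.dat`/`.json` pair and
#'   `<base>_ica.json` are written).
#' @return invisibly, the ICA JSON path.
#' @export
write_decomposition <- function(rec, dec, path) {
  write_recording(rec, path, "native")
  base <- sub("\\.(dat|json)$", "", path)
  out <- paste0(base, "_ica.json")
  jsonlite::write_json(
    list(unmixing = dec$unmixing, mixing = dec$mixing,
         channel_means = dec$channel_means, channel_ids = dec$channel_ids,
         seed = dec$seed, converged = dec$converged, n_iter = dec$n_iter),
    out, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(out)
}
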