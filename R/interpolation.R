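#' @title Spherical-spline interpolation of scalp potentials
#' @description Bad channels are reconstructed from the good ones with
#'   spherical splines: the scalp field is modelled as a constant plus a
#'   weighted sum of kernels g(cos(angle)) built from a Legendre series
#'   truncated at order 7, with stiffness m = 4. The interpolation system is
#'   solved with a pseudoinverse so that any field lying in the span of the
#'   kernels at the good electrodes (in particular any spherical-harmonic
#'   field of degree <= 7) is reproduced exactly at held-out positions.
#' @name spline_interp
NULL

# P_1..P_nmax evaluated at each element of x; returns length(x) x nmax.
legendre_table <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  pm1 <- rep(1, length(x))   # P_0
  p <- x                     # P_1
  out[, 1] <- p
  if (nmax >= 2) for (n in 2:nmax) {
    pn <- ((2 * n - 1) * x * p - (n - 1) * pm1) / n
    out[, n] <- pn
    pm1 <- p; p <- pn
  }
  out
}

# Real spherical harmonics Y_nm up to degree nmax at unit-vector rows of X.
# Columns ordered n = 1..nmax, within n: m = 0, then (cos, sin) pairs for
# m = 1..n; npts x nmax*(nmax+2) matrix. Orthonormal on the sphere.
real_spherical_harmonics <- function(X, nmax) {
  z <- pmin(pmax(X[, 3], -1), 1)
  phi <- atan2(X[, 2], X[, 1])
  s <- sqrt(pmax(0, 1 - z^2))
  # associated Legendre P_n^m(z) (without Condon-Shortley phase)
  P <- vector("list", nmax + 1L)
  for (n in 0:nmax) P[[n + 1L]] <- matrix(0, length(z), n + 1L)
  P[[1]][, 1] <- 1
  for (m in 0:nmax) {
    pmm <- if (m == 0) rep(1, length(z)) else
      prod(seq(1, 2 * m - 1, by = 2)) * s^m
    P[[m + 1L]][, m + 1L] <- pmm
    if (m < nmax) {
      pm1 <- (2 * m + 1) * z * pmm
      P[[m + 2L]][, m + 1L] <- pm1
      if (m + 2L <= nmax) for (n in (m + 2L):nmax) {
        pn <- ((2 * n - 1) * z * pm1 - (n + m - 1) * pmm) / (n - m)
        P[[n + 1L]][, m + 1L] <- pn
        pmm <- pm1; pm1 <- pn
      }
    }
  }
  out <- matrix(0, length(z), nmax * (nmax + 2L))
  col <- 0L
  for (n in 1:nmax) {
    out[, col + 1L] <- sqrt((2 * n + 1) / (4 * pi)) * P[[n + 1L]][, 1]
    col <- col + 1L
    for (m in 1:n) {
      nrm <- sqrt((2 * n + 1) / (2 * pi) *
                    exp(lgamma(n - m + 1) - lgamma(n + m + 1)))
      out[, col + 1L] <- nrm * P[[n + 1L]][, m + 1L] * cos(m * phi)
      out[, col + 2L] <- nrm * P[[n + 1L]][, m + 1L] * sin(m * phi)
      col <- col + 2L
    }
  }
  out
}

# Degree weights of the order-m spline kernel in factored (Mercer) form:
# g(x, e) = sum_n s_n^2 * sum_m Y_nm(x) Y_nm(e), s_n = (n (n+1))^(-m/2).
spline_degree_scales <- function(m, nmax) {
  n <- 1:nmax
  rep((n * (n + 1))^(-m / 2), times = 2 * n + 1)
}

# Minimum-seminorm spherical-spline interpolation, solved in the factored
# harmonic basis (constant + scaled harmonics) by minimum-norm least
# squares: numerically far better conditioned than the kernel-matrix
# formulation, and exact (to solver precision) for any field in the span
# of the truncated kernel at the fitted electrodes.
# pos_good: n_good x 3 unit vectors; V: n_good x n_samples values;
# pos_at: n_at x 3. Returns n_at x n_samples.
spline_interpolate_field <- function(pos_good, V, pos_at, m = 4, nmax = 7,
                                     lambda = 0, svd_tol = 1e-12) {
  sc <- spline_degree_scales(m, nmax)
  A <- cbind(1, sweep(real_spherical_harmonics(pos_good, nmax), 2L, sc, "*"))
  sv <- svd(A)
  d <- sv$d
  keep <- d > svd_tol * d[1]
  dinv <- if (lambda > 0) d[keep] / (d[keep]^2 + lambda) else 1 / d[keep]
  theta <- sv$v[, keep, drop = FALSE] %*%
    (dinv * crossprod(sv$u[, keep, drop = FALSE], V))
  B <- cbind(1, sweep(real_spherical_harmonics(pos_at, nmax), 2L, sc, "*"))
  B %*% theta
}

#' Interpolate bad channels from good ones
#'
#' Restores the full user-selected channel set, in its original order, by
#' spherical-spline interpolation of every bad channel from the good
#' channels' signals.
#'
#' @param rec an `eeg_recording` containing the good channels (bad ones may
#'   be present or absent; present bad channels are overwritten).
#' @param bad_ids labels of channels to reconstruct.
#' @param montage an `eeg_montage` covering all involved channels.
#' @param full_order channel order of the returned recording (default: the
#'   recording's channels followed by missing bad ones).
#' @param m spline stiffness (default 4).
#' @param nmax Legendre truncation order (default 7).
#' @param lambda optional ridge added to the kernel matrix (default 0; the
#'   pseudoinverse solve already handles rank deficiency).
#' @return the recording with `bad_ids` reconstructed; history appended.
#' @export
interpolate_bad_channels <- function(rec, bad_ids, montage = rec$montage,
                                     full_order = NULL, m = 4, nmax = 7,
                                     lambda = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  bad_ids <- as.character(bad_ids)
  if (!length(bad_ids)) return(rec)
  if (is.null(montage)) stop("interpolation requires a montage")
  good <- setdiff(rec$channel_ids, bad_ids)
  if (length(good) < 4) stop("need at least 4 good channels to interpolate")
  all_ids <- if (is.null(full_order)) union(rec$channel_ids, bad_ids)
             else full_order
  missing_pos <- setdiff(all_ids, rownames(montage$positions))
  if (length(missing_pos))
    stop("montage lacks positions for: ", paste(missing_pos, collapse = ", "))
  interp <- spline_interpolate_field(
    montage$positions[good, , drop = FALSE],
    rec$data[good, , drop = FALSE],
    montage$positions[bad_ids, , drop = FALSE], m, nmax, lambda)
  data <- matrix(0, length(all_ids), n_samples(rec),
                 dimnames = list(all_ids, NULL))
  data[good, ] <- rec$data[good, ]
  data[bad_ids, ] <- interp
  rec$data <- data
  rec$channel_ids <- all_ids
  add_history(rec, paste0("interpolate:", paste(bad_ids, collapse = "+")))
}

#' Re-reference a recording
#'
#' Average mode subtracts the instantaneous mean over all retained channels;
#' channel mode subtracts the mean of the listed channels (which must be in
#' the processed channel set).
#'
#' @param rec an `eeg_recording`.
#' @param mode `"average"` or `"channels"`.
#' @param channels reference labels (channel mode only; nonempty).
#' @return the re-referenced recording, history appended.
#' @export
rereference <- function(rec, mode = c("average", "channels"),
                        channels = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  mode <- match.arg(mode)
  if (mode == "average") {
    ref <- colMeans(rec$data)
    label <- "average"
  } else {
    if (!length(channels)) stop("empty reference channel list")
    missing <- setdiff(channels, rec$channel_ids)
    if (length(missing))
      stop("reference channel(s) not in the processed set: ",
           paste(missing, collapse = ", "))
    ref <- colMeans(rec$data[channels, , drop = FALSE])
    label <- paste(channels, collapse = "+")
  }
  rec <- replace_data(rec, sweep(rec$data, 2L, ref))
  add_history(rec, paste0("reref:", label))
}
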