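#' @title Electrode montages and the 10-20 anchor set
#' @description Montage objects hold unit-sphere electrode positions
#'   (head-centered, x right, y anterior, z up) plus a mapping of the 19
#'   standard 10-20 labels onto the layout's own channel ids. The 10-20
#'   anchors drive the spatial features of automated component rejection, so
#'   every montage must carry a complete 19-entry map.
#' @name montage
NULL

# The default 19-label 10-20 anchor set. The vertex reference (Cz) is
# excluded by convention; the midline occipital electrode completes the set.
#' The 19 default 10-20 electrode labels
#' @return character vector of length 19.
#' @export
ten_twenty_labels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2", "Oz")
}

# Canonical 10-20 positions on the unit sphere. Rings at 72 deg (10% ring)
# and 36 deg (20% ring) inclination from the vertex; azimuth measured from
# the nasion direction (+y), positive toward the left (-x). Off-ring sites
# are spherical midpoints of their 10-20 neighbours.
ten_twenty_positions <- function() {
  ring <- function(incl_deg, az_deg) {
    incl <- incl_deg * pi / 180; az <- az_deg * pi / 180
    c(-sin(incl) * sin(az), sin(incl) * cos(az), cos(incl))
  }
  mid <- function(a, b) { v <- a + b; v / sqrt(sum(v^2)) }
  p <- list(
    Fpz = ring(72, 0),    Fp1 = ring(72, 18),   Fp2 = ring(72, -18),
    F7  = ring(72, 54),   F8  = ring(72, -54),
    T3  = ring(72, 90),   T4  = ring(72, -90),
    T5  = ring(72, 126),  T6  = ring(72, -126),
    O1  = ring(72, 162),  O2  = ring(72, -162), Oz  = ring(72, 180),
    Fz  = ring(36, 0),    Pz  = ring(36, 180),
    C3  = ring(36, 90),   C4  = ring(36, -90))
  p$F3 <- mid(p$Fz, p$F7); p$F4 <- mid(p$Fz, p$F8)
  p$P3 <- mid(p$Pz, p$T5); p$P4 <- mid(p$Pz, p$T6)
  out <- do.call(rbind, p[ten_twenty_labels()])
  rownames(out) <- ten_twenty_labels()
  out
}

#' Construct a montage object
#'
#' @param positions numeric matrix n x 3 with rownames giving channel labels;
#'   rows are normalized onto the unit sphere.
#' @param ten_twenty named character vector: names are the 19 10-20 labels,
#'   values are the layout channel ids they map to.
#' @param labels_1020 the expected 10-20 label set (configurable; default
#'   [ten_twenty_labels()]).
#' @return An object of class `eeg_montage` with elements `positions`
#'   (unit-norm rows) and `ten_twenty`.
#' @export
new_montage <- function(positions, ten_twenty,
                        labels_1020 = ten_twenty_labels()) {
  if (!is.matrix(positions) || ncol(positions) != 3L)
    stop("`positions` must be an n x 3 matrix")
  if (is.null(rownames(positions))) stop("`positions` needs rownames (labels)")
  nrm <- sqrt(rowSums(positions^2))
  if (any(nrm < 1e-12)) stop("electrode position at the origin cannot be normalized")
  positions <- positions / nrm
  ten_twenty <- unlist(ten_twenty)
  missing <- setdiff(labels_1020, names(ten_twenty))
  if (length(missing))
    stop("montage configuration lacks 10-20 labels: ",
         paste(missing, collapse = ", "))
  ten_twenty <- ten_twenty[labels_1020]
  unknown <- setdiff(ten_twenty, rownames(positions))
  if (length(unknown))
    stop("10-20 map points at ids absent from the layout: ",
         paste(unknown, collapse = ", "))
  structure(list(positions = positions, ten_twenty = ten_twenty),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d positions, %d-entry 10-20 map\n",
              nrow(x$positions), length(x$ten_twenty)))
  invisible(x)
}

# Quasi-uniform deterministic spiral of n points on the upper hemisphere
# (Fibonacci lattice restricted to z in [0.05, 1]).
hemisphere_lattice <- function(n) {
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(n) - 0.5
  z <- 1 - 0.95 * i / n              # z in (0.05, 1)
  az <- 2 * pi * i / golden
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(az), y = r * sin(az), z = z)
}

#' Load an electrode montage
#'
#' Accepts either the name of a packaged layout or the path of an sfp-style
#' text file with one `label x y z` line per electrode (head-centered
#' coordinates; they are projected onto the unit sphere). Builtin layouts:
#' \describe{
#'   \item{`"sphere128"`}{128 quasi-uniform upper-hemisphere positions
#'     labelled `E1..E128`, with the 19 10-20 anchors mapped to the nearest
#'     lattice electrodes.}
#'   \item{`"standard1020"`}{just the 19 canonical 10-20 electrodes, mapped
#'     to themselves.}
#' }
#' @param source builtin layout name or path to a montage text file.
#' @param ten_twenty optional named character vector overriding the 10-20
#'   map (required for user files whose labels are not the 10-20 names).
#' @param labels_1020 the 10-20 label set to require (default 19 labels).
#' @return An `eeg_montage`.
#' @export
load_montage <- function(source, ten_twenty = NULL,
                         labels_1020 = ten_twenty_labels()) {
  if (source == "standard1020") {
    pos <- ten_twenty_positions()
    map <- stats::setNames(rownames(pos), rownames(pos))
    if (!is.null(ten_twenty)) map <- ten_twenty
    return(new_montage(pos, map, labels_1020))
  }
  if (source == "sphere128") {
    pos <- hemisphere_lattice(128)
    rownames(pos) <- paste0("E", 1:128)
    if (is.null(ten_twenty)) {
      canon <- ten_twenty_positions()
      taken <- character()
      map <- character(nrow(canon))
      names(map) <- rownames(canon)
      for (lab in rownames(canon)) {
        d <- colSums((t(pos) - canon[lab, ])^2)
        d[rownames(pos) %in% taken] <- Inf
        pick <- rownames(pos)[which.min(d)]
        map[lab] <- pick
        taken <- c(taken, pick)
      }
      ten_twenty <- map
    }
    return(new_montage(pos, ten_twenty, labels_1020))
  }
  if (!file.exists(source))
    stop("montage file not found and not a builtin layout name: ", source)
  lines <- readLines(source, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(parts, length, 1L) != 4L
  if (any(bad)) stop("malformed montage line(s): ",
                     paste(lines[bad][seq_len(min(3, sum(bad)))], collapse = "; "))
  labels <- vapply(parts, `[[`, "", 1L)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop("non-numeric coordinates in montage file")
  rownames(xyz) <- labels
  if (is.null(ten_twenty)) {
    present <- intersect(labels_1020, labels)
    if (length(present) < length(labels_1020))
      stop("montage configuration lacks 10-20 labels: ",
           paste(setdiff(labels_1020, labels), collapse = ", "))
    ten_twenty <- stats::setNames(present, present)
  }
  new_montage(xyz, ten_twenty, labels_1020)
}

#' Write a montage to an sfp-style text file
#' @param montage an `eeg_montage`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_montage <- function(montage, path) {
  lines <- sprintf("%s\t%.10f\t%.10f\t%.10f", rownames(montage$positions),
                   montage$positions[, 1], montage$positions[, 2],
                   montage$positions[, 3])
  writeLines(lines, path)
  invisible(path)
}

# Layout channel ids of the 10-20 anchors, in canonical label order.
ten_twenty_ids <- function(montage) unname(montage$ten_twenty)
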