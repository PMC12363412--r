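# Pair bookkeeping used throughout the package. A self-calibrating unit has
# two sources ("1", "2") and two detectors ("A", "B"); the four source-detector
# pairs are always ordered (1A, 2B, 1B, 2A): the two short pairs first, then
# the two long ones. Dual slopes group pairs by source: {1A, 1B} and {2B, 2A}.
PAIR_NAMES <- c("1A", "2B", "1B", "2A")
OPTODE_NAMES <- c("1", "2", "A", "B")
PAIR_SOURCE <- c("1", "2", "1", "2")
PAIR_DETECTOR <- c("A", "B", "B", "A")
SRC1_PAIRS <- c(1L, 3L) # {1A, 1B}
SRC2_PAIRS <- c(2L, 4L) # {2B, 2A}

#' Detector separation of the right-angle trapezoid
#'
#' The default TRAP geometry: each detector sees the two sources at 90
#' degrees, so the source separation is `a = sqrt(25^2 + 37^2)` mm and the
#' detector separation `b = 744/a` (about 16.66 mm). This member of the
#' leg-25/diagonal-37 family makes each detector's local geometry identical
#' to that of every optode in the diagonal rectangle.
#'
#' @return Detector separation in mm.
#' @export
trap_right_angle_b <- function() 744 / sqrt(1994)

pair_distance_matrix <- function(xy) {
  d <- function(p, q) sqrt(sum((xy[p, ] - xy[q, ])^2))
  stats::setNames(
    vapply(seq_along(PAIR_NAMES),
           function(i) d(PAIR_SOURCE[i], PAIR_DETECTOR[i]), numeric(1)),
    PAIR_NAMES)
}

new_arrangement <- function(name, xy) {
  structure(list(name = name, optodes = xy, rho = pair_distance_matrix(xy)),
            class = "ds_arrangement")
}

#' Build a nominal dual-slope optode arrangement
#'
#' Constructs one of the four canonical planar self-calibrating/dual-slope
#' units. All four share a mean source-detector distance of 31 mm. The probe
#' plane is the medium surface; coordinates are in mm with x along the main
#' probe axis.
#'
#' * `LINR` (linear): sources at 0 and 62 mm, detectors at 25 and 37 mm on one
#'   line; distances `[25, 25, 37, 37]` mm.
#' * `ALIN` (asymmetric linear): detectors shifted to 20 and 32 mm; distances
#'   `[20, 30, 32, 42]` mm.
#' * `TRAP` (isosceles trapezoid): legs 25 mm, diagonals 37 mm. Those two
#'   constraints leave the detector separation `b` free subject to
#'   `a * b = 744` mm^2 (with `a` the source separation); see `trap_b`.
#' * `DRCT` (diagonal rectangle): a 25 x 37 mm rectangle with the sources on
#'   one diagonal and the detectors on the other; distances `[25, 25, 37, 37]`.
#'
#' @param name Arrangement name, one of `"LINR"`, `"ALIN"`, `"TRAP"`, `"DRCT"`.
#' @param trap_b Detector separation of the trapezoid in mm (TRAP only), in
#'   `[12, 62]`. The default `744/sqrt(1994)` (about 16.66 mm) is the
#'   right-angle trapezoid in which each detector sees the two sources at 90
#'   degrees; at `trap_b = 12` the trapezoid degenerates to the linear layout.
#' @return A `ds_arrangement`: list with `name`, a 4 x 2 coordinate matrix
#'   `optodes` (rows "1", "2", "A", "B"), and the four pair distances `rho`
#'   named `("1A", "2B", "1B", "2A")`.
#' @examples
#' arr <- ds_arrangement("LINR")
#' arr$rho # 25 25 37 37
#' @export
ds_arrangement <- function(name = c("LINR", "ALIN", "TRAP", "DRCT"),
                           trap_b = trap_right_angle_b()) {
  name <- match.arg(name)
  xy <- switch(name,
    LINR = rbind("1" = c(0, 0), "2" = c(62, 0), A = c(25, 0), B = c(37, 0)),
    ALIN = rbind("1" = c(0, 0), "2" = c(62, 0), A = c(20, 0), B = c(32, 0)),
    DRCT = rbind("1" = c(0, 0), "2" = c(25, 37), A = c(25, 0), B = c(0, 37)),
    TRAP = {
      b <- trap_b
      if (!is.numeric(b) || length(b) != 1L || !is.finite(b) ||
          b < 12 || b > 62)
        stop("trap_b must lie in [12, 62] mm for legs 25 mm and diagonals 37 mm")
      a <- 744 / b
      h <- sqrt(625 - ((a - b) / 2)^2) # leg constraint; >= 0 on [12, 62]
      rbind("1" = c(-a / 2, 0), "2" = c(a / 2, 0),
            A = c(-b / 2, h), B = c(b / 2, h))
    })
  colnames(xy) <- c("x", "y")
  new_arrangement(name, xy)
}

#' Source-detector pair distances of an arrangement
#'
#' Euclidean center-to-center distances for the ordered pairs
#' (1A, 2B, 1B, 2A), recomputed from the current optode coordinates.
#'
#' @param arr A `ds_arrangement` (possibly displaced).
#' @return Named numeric vector of four distances in mm.
#' @export
pair_distances <- function(arr) {
  stopifnot(inherits(arr, "ds_arrangement"))
  pair_distance_matrix(arr$optodes)
}

#' Displace optodes in the probe plane
#'
#' Returns a new arrangement with the named optodes moved by the given
#' in-plane offsets and the pair distances recomputed. The input arrangement
#' is not modified, so the nominal geometry stays retrievable at the caller.
#'
#' @param arr A `ds_arrangement`.
#' @param offsets Offsets in mm: either a named list of length-2 numeric
#'   vectors, or a numeric matrix with rownames, naming a subset of
#'   `c("1", "2", "A", "B")`. Optodes not named stay at their current
#'   positions.
#' @return A displaced `ds_arrangement`.
#' @examples
#' arr <- ds_arrangement("LINR")
#' displace_optodes(arr, list(A = c(0, 1)))$rho[["1A"]] # sqrt(626)
#' @export
displace_optodes <- function(arr, offsets) {
  stopifnot(inherits(arr, "ds_arrangement"))
  if (is.list(offsets)) {
    offsets <- do.call(rbind, offsets)
  }
  targets <- rownames(offsets)
  if (is.null(targets) || !all(targets %in% rownames(arr$optodes)))
    stop("offsets must be named with a subset of optodes ",
         paste(OPTODE_NAMES, collapse = ", "))
  xy <- arr$optodes
  xy[targets, ] <- xy[targets, , drop = FALSE] + offsets
  new_arrangement(arr$name, xy)
}

#' Points on a circle around a nominal position
#'
#' Equally spaced positions on a circle, starting at angle 0 (+x axis) and
#' proceeding counterclockwise. Used to orbit an optode around its nominal
#' position when computing circle-orbit RMS error metrics.
#'
#' @param center Length-2 numeric, circle center (mm).
#' @param radius Circle radius in mm (>= 0).
#' @param n_angles Number of points (>= 1).
#' @return `n_angles` x 2 matrix of positions.
#' @export
circle_positions <- function(center, radius, n_angles) {
  stopifnot(length(center) == 2L, radius >= 0, n_angles >= 1)
  th <- 2 * pi * (seq_len(n_angles) - 1L) / n_angles
  cbind(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th))
}

#' @export
print.ds_arrangement <- function(x, ...) {
  cat("Dual-slope arrangement:", x$name, "\n")
  cat("Optode positions (mm):\n")
  print(round(x$optodes, 4))
  cat("Pair distances rho (mm):",
      paste(sprintf("%s=%.4g", names(x$rho), x$rho), collapse = ", "), "\n")
  invisible(x)
}

#' Read an arrangement from a YAML configuration file
#'
#' The file must contain a `name` field; optionally `trap_b` (mm, TRAP only)
#' and `coordinates`, a mapping from optode label to `[x, y]` in mm that
#' overrides the canonical coordinates.
#'
#' @param path Path to a YAML file.
#' @return A `ds_arrangement`.
#' @export
read_arrangement <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$name)) stop("arrangement config needs a 'name' field")
  arr <- if (is.null(cfg$trap_b)) ds_arrangement(cfg$name)
         else ds_arrangement(cfg$name, trap_b = cfg$trap_b)
  if (!is.null(cfg$coordinates)) {
    xy <- arr$optodes
    for (nm in names(cfg$coordinates)) {
      if (!nm %in% rownames(xy)) stop("unknown optode in config: ", nm)
      xy[nm, ] <- as.numeric(cfg$coordinates[[nm]])
    }
    arr <- new_arrangement(arr$name, xy)
  }
  arr
}

#' Write arrangement coordinates as CSV
#'
#' @param arr A `ds_arrangement`.
#' @param path Output CSV path (columns: optode, x, y).
#' @return The path, invisibly.
#' @export
write_arrangement <- function(arr, path) {
  df <- data.frame(optode = rownames(arr$optodes),
                   x = arr$optodes[, "x"], y = arr$optodes[, "y"],
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
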