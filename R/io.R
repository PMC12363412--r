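#' Write a reflectance set as CSV
#'
#' Layout: one row per source-detector pair with columns `pair`,
#' `rho_actual_mm`, `rho_nominal_mm`, `amplitude`, `phase_deg`. This is the
#' interchange format through which externally measured FD-NIRS data can be
#' fed to the inversion functions.
#'
#' @param set A `reflectance_set`.
#' @param path Output CSV path.
#' @param rho_nominal Optional nominal distances (mm) to record alongside
#'   the actual ones; defaults to the actual distances.
#' @return The path, invisibly.
#' @export
write_reflectance_csv <- function(set, path, rho_nominal = NULL) {
  stopifnot(inherits(set, "reflectance_set"))
  if (is.null(rho_nominal)) rho_nominal <- set$rho
  df <- data.frame(pair = names(set$R),
                   rho_actual_mm = unname(set$rho),
                   rho_nominal_mm = unname(rho_nominal),
                   amplitude = Mod(set$R),
                   phase_deg = Arg(set$R) * 180 / pi)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a reflectance set from CSV
#'
#' Inverse of [write_reflectance_csv()]. Rows may appear in any order but
#' must cover exactly the pairs 1A, 2B, 1B, 2A.
#'
#' @param path CSV path.
#' @param inst The [fd_instrument()] the data were acquired with.
#' @return List with the `reflectance_set` (`set`, with `medium = NULL`
#'   since the medium is unknown for measured data) and the recorded
#'   nominal distances (`rho_nominal`).
#' @export
read_reflectance_csv <- function(path, inst = fd_instrument()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair", "rho_actual_mm", "rho_nominal_mm", "amplitude",
            "phase_deg")
  if (!all(need %in% names(df)))
    stop("reflectance CSV must have columns: ", paste(need, collapse = ", "))
  if (!setequal(df$pair, PAIR_NAMES))
    stop("reflectance CSV must contain exactly the pairs ",
         paste(PAIR_NAMES, collapse = ", "))
  df <- df[match(PAIR_NAMES, df$pair), ]
  set <- new_reflectance_set(
    complex(modulus = df$amplitude, argument = df$phase_deg * pi / 180),
    df$rho_actual_mm, medium = NULL, inst = inst)
  list(set = set,
       rho_nominal = stats::setNames(df$rho_nominal_mm, PAIR_NAMES))
}

#' Write a zero-change polyline as CSV
#'
#' Exports the polyline of a [zero_change_lines()] result (offsets from the
#' nominal optode position, mm) for use in probe CAD.
#'
#' @param line A `zero_change_line`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_zero_change_csv <- function(line, path) {
  stopifnot(inherits(line, "zero_change_line"))
  df <- data.frame(arrangement = line$arrangement, optode = line$optode,
                   quantity = line$quantity,
                   dx_mm = line$polyline[, 1], dy_mm = line$polyline[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
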