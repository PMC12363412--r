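#' Optical properties of a homogeneous medium
#'
#' @param mua Absorption coefficient in 1/mm (> 0).
#' @param musp Reduced scattering coefficient in 1/mm (> 0).
#' @return A `ds_medium` list with fields `mua` and `musp`.
#' @examples
#' ds_medium(0.01, 1.0) # typical bulk tissue values in the near infrared
#' @export
ds_medium <- function(mua, musp) {
  stopifnot(is.numeric(mua), is.numeric(musp), length(mua) == 1L,
            length(musp) == 1L, is.finite(mua), is.finite(musp),
            mua > 0, musp > 0)
  structure(list(mua = mua, musp = musp), class = "ds_medium")
}

#' Frequency-domain instrument settings
#'
#' @param fmod Modulation frequency in Hz. Default 100 MHz.
#' @param n_index Refractive index of the medium. Default 1.4 (soft tissue).
#' @param Reff Effective internal reflection coefficient of the
#'   boundary (Fresnel-integral value; about 0.493 at n = 1.4).
#' @return An `fd_instrument` list with `fmod`, `n_index`, `Reff`, and the
#'   speed of light in the medium `v` (mm/s).
#' @export
fd_instrument <- function(fmod = 100e6, n_index = 1.4, Reff = 0.493) {
  stopifnot(fmod >= 0, n_index >= 1, Reff >= 0, Reff < 1)
  structure(list(fmod = fmod, n_index = n_index, Reff = Reff,
                 v = 2.99792458e11 / n_index),
            class = "fd_instrument")
}

#' The study grid of optical properties
#'
#' The 3 x 3 grid of media spanning bulk tissue values recovered by FD-NIRS
#' on the adult forehead: absorption 0.005, 0.010, 0.015 1/mm crossed with
#' reduced scattering 0.5, 1.0, 1.5 1/mm.
#'
#' @return Data frame with columns `mua` and `musp` (9 rows; `musp` varies
#'   fastest, matching the row order of the reported tables).
#' @export
study_grid <- function() {
  data.frame(mua = rep(c(0.005, 0.010, 0.015), each = 3L),
             musp = rep(c(0.5, 1.0, 1.5), times = 3L))
}
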