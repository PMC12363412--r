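# Semi-infinite FD diffusion reflectance with an extrapolated boundary:
# two image-like source terms in flux form. The global constant factor is
# irrelevant here because every downstream use takes slopes of logarithms or
# ratios. Time-harmonic convention e^(-i*omega*t): the complex wavenumber
# k = sqrt((mua - i*omega/v)/D) is taken on the branch with Re(k) > 0, so
# Im(k) < 0 and the phase of the reflectance increases with distance.
semi_infinite_reflectance <- function(rho, mua, D, z0, inst) {
  omega <- 2 * pi * inst$fmod
  zb <- 2 * D * (1 + inst$Reff) / (1 - inst$Reff)
  k <- sqrt(complex(real = mua, imaginary = -omega / inst$v) / D)
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  z0 * (k + 1 / r1) * exp(-k * r1) / r1^2 +
    (z0 + 2 * zb) * (k + 1 / r2) * exp(-k * r2) / r2^2
}

#' Complex reflectance of a semi-infinite homogeneous medium
#'
#' Frequency-domain photon-diffusion reflectance at the surface of a
#' semi-infinite homogeneous medium, extrapolated-boundary (two image
#' sources, flux form). This is the data-generating model: it uses the
#' absorption-independent diffusion coefficient `D = 1/(3 musp)` and source
#' depth `z0 = 1/musp`. Intensity is `Mod(R)`, phase is `Arg(R)` (rad).
#'
#' @param rho Source-detector distance(s) in mm (> 0); vectorized.
#' @param medium A [ds_medium()].
#' @param inst An [fd_instrument()].
#' @return Complex reflectance, same length as `rho` (arbitrary common
#'   scale).
#' @seealso [inverse_reflectance()] for the inversion-side convention.
#' @export
complex_reflectance <- function(rho, medium, inst = fd_instrument()) {
  stopifnot(all(rho > 0))
  semi_infinite_reflectance(rho, medium$mua,
                            D = 1 / (3 * medium$musp), z0 = 1 / medium$musp,
                            inst)
}

#' Inversion-side diffusion reflectance
#'
#' Same closed form as [complex_reflectance()] but with the diffusion
#' coefficient convention used by the inverse models:
#' `D = 1/(3 (mua + musp))` and `z0 = 1/(mua + musp)`, so that the complex
#' wavenumber equals the complex effective attenuation coefficient
#' `sqrt(3 (mua + musp) (mua - i omega/v))` exactly. The iterative
#' absolute inversion builds its correction factor from this model.
#'
#' @inheritParams complex_reflectance
#' @return Complex reflectance, same length as `rho`.
#' @export
inverse_reflectance <- function(rho, medium, inst = fd_instrument()) {
  stopifnot(all(rho > 0))
  mt <- medium$mua + medium$musp
  semi_infinite_reflectance(rho, medium$mua, D = 1 / (3 * mt), z0 = 1 / mt,
                            inst)
}

new_reflectance_set <- function(R, rho, medium, inst) {
  structure(list(R = stats::setNames(R, PAIR_NAMES),
                 rho = stats::setNames(rho, PAIR_NAMES),
                 medium = medium, inst = inst),
            class = "reflectance_set")
}

#' Forward data for the four pairs of an arrangement
#'
#' Evaluates the forward model at the arrangement's actual (possibly
#' displaced) pair distances. When simulating a position error, the data are
#' always generated at the true, displaced distances; assuming nominal
#' distances is the inverse model's mistake, not the data's.
#'
#' @param arr A `ds_arrangement` (possibly displaced).
#' @param medium A [ds_medium()].
#' @param inst An [fd_instrument()].
#' @return A `reflectance_set`: complex `R` and distances `rho` named
#'   `("1A", "2B", "1B", "2A")`, plus the generating `medium` and `inst`.
#' @export
reflectance_set <- function(arr, medium, inst = fd_instrument()) {
  stopifnot(inherits(arr, "ds_arrangement"))
  new_reflectance_set(complex_reflectance(arr$rho, medium, inst),
                      arr$rho, medium, inst)
}

#' Baseline and absorption-perturbed data
#'
#' Generates a baseline set and a second set in which only the absorption
#' coefficient is increased by `delta_mua`, with identical geometry. Used to
#' test dual-slope recovery of absorption changes.
#'
#' @inheritParams reflectance_set
#' @param delta_mua True absorption change in 1/mm (default 1e-4).
#' @return List with elements `baseline` and `perturbed` (both
#'   `reflectance_set`) and the true `delta_mua`.
#' @export
perturbed_pair <- function(arr, medium, inst = fd_instrument(),
                           delta_mua = 1e-4) {
  list(baseline = reflectance_set(arr, medium, inst),
       perturbed = reflectance_set(
         arr, ds_medium(medium$mua + delta_mua, medium$musp), inst),
       delta_mua = delta_mua)
}

# Area-uniform quadrature nodes over a disk of radius R: Gauss-Legendre in
# r^2 (so weights are exact for the area measure) times a uniform angular
# grid. Returns nodes (x, y) and weights summing to 1.
disk_quadrature <- function(R, n_radial, n_angular) {
  g <- pracma::gaussLegendre(n_radial, 0, 1)
  r <- R * sqrt(g$x)
  th <- 2 * pi * (seq_len(n_angular) - 1L) / n_angular
  list(x = as.vector(outer(r, th, function(r, t) r * cos(t))),
       y = as.vector(outer(r, th, function(r, t) r * sin(t))),
       w = as.vector(outer(g$w, rep(1 / n_angular, n_angular))))
}

#' Reflectance averaged over finite optode areas
#'
#' Double area average of the point-to-point forward kernel over a source
#' disk and a detector disk whose centers are `rho` apart, by fixed-order
#' polar quadrature on each disk. Quantifies the error committed by treating
#' real optodes (typical source radius 0.3 mm, detector radius 1.5 mm) as
#' points. With both radii zero this equals [complex_reflectance()] exactly.
#'
#' @inheritParams complex_reflectance
#' @param rho Center-to-center distance in mm (scalar).
#' @param source_radius,detector_radius Disk radii in mm (>= 0).
#' @param n_radial,n_angular Quadrature orders per disk. The defaults (8
#'   radial x 16 angular) are converged to better than 1e-6 relative for
#'   radii up to a few mm at the distances studied here.
#' @return A single complex reflectance value.
#' @export
finite_optode_reflectance <- function(rho, medium, inst = fd_instrument(),
                                      source_radius = 0.3,
                                      detector_radius = 1.5,
                                      n_radial = 8L, n_angular = 16L) {
  stopifnot(length(rho) == 1L, rho > 0,
            source_radius >= 0, detector_radius >= 0)
  if (source_radius + detector_radius > rho / 2)
    stop("optode radii comparable to the separation: quadrature unreliable")
  if (source_radius == 0 && detector_radius == 0)
    return(complex_reflectance(rho, medium, inst))
  s <- disk_quadrature(source_radius, n_radial, n_angular)
  d <- disk_quadrature(detector_radius, n_radial, n_angular)
  acc <- 0 + 0i
  for (i in seq_along(s$x)) {
    dist <- sqrt((rho + d$x - s$x[i])^2 + (d$y - s$y[i])^2)
    acc <- acc + s$w[i] * sum(d$w * complex_reflectance(dist, medium, inst))
  }
  acc
}

#' Add instrument noise to a reflectance set
#'
#' Independent Gaussian noise per pair: multiplicative on the amplitude
#' (relative standard deviation `sigma_I_rel`) and additive on the phase
#' (standard deviation `sigma_phi`, rad). Typical FD-NIRS instrument values
#' are 0.1% and 0.1 degree.
#'
#' @param set A `reflectance_set`.
#' @param sigma_I_rel Relative amplitude noise (fraction, >= 0).
#' @param sigma_phi Phase noise in rad (>= 0).
#' @param seed Optional integer seed for reproducibility; if `NULL`, the
#'   current RNG stream is used.
#' @return A noisy `reflectance_set`.
#' @export
add_noise <- function(set, sigma_I_rel = 0.001, sigma_phi = 0.1 * pi / 180,
                      seed = NULL) {
  stopifnot(inherits(set, "reflectance_set"), sigma_I_rel >= 0,
            sigma_phi >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(set$R)
  factor <- (1 + stats::rnorm(n, 0, sigma_I_rel)) *
    complex(modulus = 1, argument = stats::rnorm(n, 0, sigma_phi))
  new_reflectance_set(set$R * factor, set$rho, set$medium, set$inst)
}

#' Complex mean total pathlength
#'
#' The complex mean total optical pathlength per distance,
#' `L = -d ln(R)/d mua`, of the data-generating forward model. Its real part
#' maps absorption changes to intensity changes, its imaginary part to phase
#' changes. Computed analytically by default (closed-form derivative of the
#' two-image-source expression); `method = "numeric"` uses a central finite
#' difference, which agrees with the analytic form to better than 1e-6
#' relative and serves as a self-consistency check.
#'
#' @inheritParams complex_reflectance
#' @param method `"analytic"` or `"numeric"`.
#' @param step Absorption step in 1/mm for the finite difference.
#' @return Complex pathlengths (mm), same length as `rho`.
#' @export
complex_pathlengths <- function(rho, medium, inst = fd_instrument(),
                                method = c("analytic", "numeric"),
                                step = 1e-6) {
  method <- match.arg(method)
  if (method == "numeric") {
    up <- complex_reflectance(rho, ds_medium(medium$mua + step, medium$musp),
                              inst)
    dn <- complex_reflectance(rho, ds_medium(medium$mua - step, medium$musp),
                              inst)
    return(-(log(up) - log(dn)) / (2 * step))
  }
  # d/dmua of each image term z*(k + 1/r)*exp(-k*r)/r^2 collapses to
  # -k'(mua) * k * z * exp(-k*r)/r with k' = 1/(2 k D), hence
  # L = sum_i z_i exp(-k r_i)/r_i / (2 D R).
  D <- 1 / (3 * medium$musp)
  z0 <- 1 / medium$musp
  omega <- 2 * pi * inst$fmod
  zb <- 2 * D * (1 + inst$Reff) / (1 - inst$Reff)
  k <- sqrt(complex(real = medium$mua, imaginary = -omega / inst$v) / D)
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  num <- z0 * exp(-k * r1) / r1 + (z0 + 2 * zb) * exp(-k * r2) / r2
  num / (2 * D * complex_reflectance(rho, medium, inst))
}

#' Pathlengths for the four pairs of an arrangement
#'
#' @inheritParams reflectance_set
#' @return Named complex vector of pathlengths (mm) at the arrangement's
#'   pair distances.
#' @export
pathlength_set <- function(arr, medium, inst = fd_instrument()) {
  stopifnot(inherits(arr, "ds_arrangement"))
  stats::setNames(complex_pathlengths(arr$rho, medium, inst), PAIR_NAMES)
}

#' @export
print.reflectance_set <- function(x, ...) {
  cat("FD reflectance set (fmod =", format(x$inst$fmod, big.mark = ","),
      "Hz)\n")
  df <- data.frame(pair = names(x$R), rho_mm = round(unname(x$rho), 4),
                   amplitude = signif(Mod(x$R), 6),
                   phase_deg = round(Arg(x$R) * 180 / pi, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
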