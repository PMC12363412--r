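# Relative error (%) of one recovered quantity for a displaced arrangement,
# inverting with the nominal distances. Absolute quantities are compared to
# the true medium; absorption changes to the true delta_mua, with the
# assumed medium re-estimated from the displaced baseline each time.
point_error <- function(disp, rho_nominal, quantity, method, medium, inst,
                        delta_mua) {
  if (quantity %in% c("mua", "musp")) {
    set <- reflectance_set(disp, medium, inst)
    fit <- if (method == "iterative") fit_iterative(set, rho_nominal, inst)
           else fit_slopes(set, rho_nominal, inst)
    100 * (fit[[quantity]] - medium[[quantity]]) / medium[[quantity]]
  } else {
    pp <- perturbed_pair(disp, medium, inst, delta_mua)
    d <- fit_delta_mua(pp$baseline, pp$perturbed, rho_nominal, inst = inst)
    rec <- if (quantity == "dmua_I") d$dmua_I else d$dmua_phi
    100 * (rec - delta_mua) / delta_mua
  }
}

#' Error map over a square displacement grid
#'
#' Displaces one optode over a square grid of in-plane offsets around its
#' nominal position; at each offset, forward data are generated at the true
#' (displaced) distances and inverted assuming the nominal distances. The
#' map records the relative error (%) of the recovered quantity against the
#' truth: the true medium value for `mua`/`musp`, or the true absorption
#' change for the `dmua_*` quantities (whose assumed medium is re-estimated
#' by the iterative method at every offset). Grid points where the inversion
#' fails are recorded as `NA`.
#'
#' @param arr A nominal `ds_arrangement`.
#' @param optode Optode to displace: one of `"1"`, `"2"`, `"A"`, `"B"`.
#' @param quantity `"mua"`, `"musp"`, `"dmua_I"`, or `"dmua_phi"`.
#' @param medium True [ds_medium()].
#' @param inst An [fd_instrument()].
#' @param method Absolute inversion: `"iterative"` (default) or `"slopes"`.
#'   Ignored for the change quantities, which always use the iterative
#'   method for the assumed medium.
#' @param halfwidth Half-width of the square in mm (default 10, i.e. a
#'   20 mm x 20 mm square).
#' @param step Grid step in mm; must divide `halfwidth` so the nominal
#'   position is a grid node.
#' @param delta_mua True absorption change (1/mm) for the `dmua_*` maps.
#' @return An `error_map`: grid vectors `dx`, `dy` (mm), a
#'   `length(dx) x length(dy)` matrix `values` (% error), and metadata.
#' @export
sweep_square <- function(arr, optode,
                         quantity = c("mua", "musp", "dmua_I", "dmua_phi"),
                         medium, inst = fd_instrument(),
                         method = c("iterative", "slopes"),
                         halfwidth = 10, step = 0.5, delta_mua = 1e-4) {
  quantity <- match.arg(quantity)
  method <- match.arg(method)
  stopifnot(inherits(arr, "ds_arrangement"),
            optode %in% rownames(arr$optodes),
            halfwidth > 0, step > 0,
            abs(halfwidth / step - round(halfwidth / step)) < 1e-9)
  dx <- seq(-halfwidth, halfwidth, by = step)
  dy <- dx
  rho_nom <- arr$rho
  vals <- matrix(NA_real_, length(dx), length(dy))
  for (j in seq_along(dy)) {
    for (i in seq_along(dx)) {
      off <- stats::setNames(list(c(dx[i], dy[j])), optode)
      vals[i, j] <- tryCatch(
        point_error(displace_optodes(arr, off), rho_nom, quantity, method,
                    medium, inst, delta_mua),
        error = function(e) NA_real_)
    }
  }
  structure(list(dx = dx, dy = dy, values = vals, optode = optode,
                 quantity = quantity, method = method,
                 arrangement = arr$name, medium = medium),
            class = "error_map")
}

# Recover (mua, musp) for one displaced configuration, nominal rho assumed.
recover_displaced <- function(arr, offsets, rho_nominal, method, medium,
                              inst) {
  set <- reflectance_set(displace_optodes(arr, offsets), medium, inst)
  fit <- if (method == "iterative") fit_iterative(set, rho_nominal, inst)
         else fit_slopes(set, rho_nominal, inst)
  c(fit$mua, fit$musp)
}

#' Circle-orbit RMS error from 1 mm-scale optode displacement
#'
#' The headline robustness metric: each optode in `optodes` orbits a circle
#' of the given radius around its nominal position; for every configuration
#' the forward data are generated at the true displaced distances and
#' inverted assuming the nominal distances; the result is the RMS deviation
#' of the recovered coefficients from the nominal-position recovery,
#' normalized to that recovery, in percent. Normalizing to the
#' nominal-position recovery (not the truth) isolates the position error
#' from the inversion's own systematic bias.
#'
#' Sampling: a single optode uses a deterministic grid of `n_angles` equally
#' spaced angles; two optodes use the full product grid of angle pairs
#' (`n_angles^2` configurations); three or more use seeded Monte Carlo with
#' independent uniform angles per optode (`mc_samples` draws). Identical
#' angles for all optodes would be a rigid translation with exactly zero
#' error, so co-varied optodes must be displaced independently.
#'
#' @param arr A nominal `ds_arrangement`.
#' @param optodes Character vector naming the displaced optodes (subset of
#'   `c("1","2","A","B")`).
#' @param medium True [ds_medium()].
#' @param inst An [fd_instrument()].
#' @param method `"iterative"` (default) or `"slopes"`.
#' @param radius Orbit radius in mm (default 1: the 2 mm diameter circle).
#' @param n_angles Angles per optode for the deterministic grids (default
#'   72, i.e. 5 degree spacing).
#' @param mc_samples Monte Carlo draws for three or more optodes.
#' @param seed Optional seed for the Monte Carlo sampler.
#' @return A `sigma_result`: `sigma_mua_rel` and `sigma_musp_rel` (%),
#'   the nominal-position recovery `nominal` (1/mm), `n_samples`,
#'   `n_failed`, `sampling`, `optodes`, and `seed`.
#' @export
sigma_circle <- function(arr, optodes, medium, inst = fd_instrument(),
                         method = c("iterative", "slopes"), radius = 1,
                         n_angles = 72L, mc_samples = 4096L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(arr, "ds_arrangement"), length(optodes) >= 1L,
            all(optodes %in% rownames(arr$optodes)),
            !anyDuplicated(optodes), radius >= 0, n_angles >= 1L)
  m <- length(optodes)
  sampling <- if (m == 1L) "angle_grid" else if (m == 2L) "product_grid"
              else "monte_carlo"
  angles <- switch(sampling,
    angle_grid = matrix(2 * pi * (seq_len(n_angles) - 1L) / n_angles,
                        ncol = 1L),
    product_grid = {
      th <- 2 * pi * (seq_len(n_angles) - 1L) / n_angles
      as.matrix(expand.grid(th, th))
    },
    monte_carlo = {
      if (!is.null(seed)) set.seed(seed)
      matrix(stats::runif(mc_samples * m, 0, 2 * pi), ncol = m)
    })
  rho_nom <- arr$rho
  set_nom <- reflectance_set(arr, medium, inst)
  fit_nom <- if (method == "iterative") fit_iterative(set_nom, rho_nom, inst)
             else fit_slopes(set_nom, rho_nom, inst)
  nominal <- c(mua = fit_nom$mua, musp = fit_nom$musp)
  recs <- matrix(NA_real_, nrow(angles), 2L)
  for (i in seq_len(nrow(angles))) {
    offs <- lapply(seq_len(m), function(j)
      radius * c(cos(angles[i, j]), sin(angles[i, j])))
    names(offs) <- optodes
    recs[i, ] <- tryCatch(
      recover_displaced(arr, offs, rho_nom, method, medium, inst),
      error = function(e) c(NA_real_, NA_real_))
  }
  ok <- stats::complete.cases(recs)
  dev2 <- sweep(recs[ok, , drop = FALSE], 2L, nominal)^2
  structure(list(
    sigma_mua_rel = 100 * sqrt(mean(dev2[, 1])) / nominal["mua"],
    sigma_musp_rel = 100 * sqrt(mean(dev2[, 2])) / nominal["musp"],
    nominal = nominal, n_samples = sum(ok), n_failed = sum(!ok),
    sampling = sampling, optodes = optodes, radius = radius,
    method = method, seed = seed),
    class = "sigma_result")
}

#' @export
print.sigma_result <- function(x, ...) {
  cat(sprintf(paste0("Circle-orbit RMS error (radius %g mm, %s over %d ",
                     "configurations, optode(s) %s, %s method):\n"),
              x$radius, x$sampling, x$n_samples,
              paste(x$optodes, collapse = ","), x$method))
  cat(sprintf("  sigma(mua)/mua:   %.3g%%\n  sigma(musp)/musp: %.3g%%\n",
              x$sigma_mua_rel, x$sigma_musp_rel))
  if (x$n_failed > 0) cat("  (", x$n_failed, "failed inversions excluded )\n")
  invisible(x)
}

#' Zero-change line of an error map
#'
#' Extracts the locus of optode positions along which the recovered quantity
#' does not change from its nominal-position value: the zero-level contour
#' of `values - values[0, 0]`, by bilinear marching squares. Movement along
#' this line is harmless; movement across it changes the recovered value,
#' so a rigid probe support should be built perpendicular to the line's
#' tangent at the nominal position.
#'
#' @param map An `error_map` from [sweep_square()].
#' @return A `zero_change_line`: `polyline` (ordered n x 2 matrix of offsets
#'   in mm through the nominal position), unit `tangent` at the nominal
#'   position, and `support_direction` (unit vector perpendicular to the
#'   tangent), plus the map's metadata.
#' @export
zero_change_lines <- function(map) {
  stopifnot(inherits(map, "error_map"))
  i0 <- which(abs(map$dx) < 1e-12)
  j0 <- which(abs(map$dy) < 1e-12)
  if (length(i0) != 1L || length(j0) != 1L)
    stop("map grid must contain the nominal position (0, 0)")
  z <- map$values - map$values[i0, j0]
  cl <- grDevices::contourLines(map$dx, map$dy, z, levels = 0)
  if (!length(cl))
    stop("no zero-change contour through the nominal cell")
  near2 <- vapply(cl, function(s) min(s$x^2 + s$y^2), numeric(1))
  seg <- cl[[which.min(near2)]]
  poly <- cbind(x = seg$x, y = seg$y)
  k <- which.min(poly[, 1]^2 + poly[, 2]^2)
  lo <- max(1L, k - 1L)
  hi <- min(nrow(poly), k + 1L)
  tg <- poly[hi, ] - poly[lo, ]
  tg <- tg / sqrt(sum(tg^2))
  structure(list(polyline = poly, tangent = tg,
                 support_direction = c(-tg[2], tg[1]),
                 optode = map$optode, quantity = map$quantity,
                 arrangement = map$arrangement),
            class = "zero_change_line")
}

#' @export
print.zero_change_line <- function(x, ...) {
  cat(sprintf(paste0("Zero-change line (%s, optode %s, %s): %d vertices\n",
                     "  tangent at nominal: (%.3f, %.3f)\n",
                     "  support direction:  (%.3f, %.3f)\n"),
              x$arrangement, x$optode, x$quantity, nrow(x$polyline),
              x$tangent[1], x$tangent[2],
              x$support_direction[1], x$support_direction[2]))
  invisible(x)
}

#' @export
as.data.frame.error_map <- function(x, ...) {
  data.frame(arrangement = x$arrangement, optode = x$optode,
             quantity = x$quantity, method = x$method,
             dx = rep(x$dx, times = length(x$dy)),
             dy = rep(x$dy, each = length(x$dx)),
             error_pct = as.vector(x$values))
}

#' Write an error map as long-format CSV
#'
#' @param map An `error_map`.
#' @param path Output CSV path (columns: arrangement, optode, quantity,
#'   method, dx, dy, error_pct).
#' @return The path, invisibly.
#' @export
write_error_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
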