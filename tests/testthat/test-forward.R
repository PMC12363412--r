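test_that("forward model matches an arbitrary-precision oracle to 12 digits", {
  # Frozen from an independent re-implementation of the same closed form in
  # 50-digit arithmetic (mpmath): rho = 31 mm, mua = 0.01, musp = 1.0.
  oracle <- complex(real = 4.116249732016215e-6,
                    imaginary = 3.239172858922333e-6)
  got <- complex_reflectance(31, MED_REF, INST)
  expect_lt(Mod(got - oracle) / Mod(oracle), 1e-12)
})

test_that("phase vanishes in the continuous-wave limit and grows with distance", {
  cw <- fd_instrument(fmod = 0)
  rho <- seq(10, 60, by = 5)
  expect_equal(Arg(complex_reflectance(rho, MED_REF, cw)), rep(0, length(rho)))
  ph <- Arg(complex_reflectance(rho, MED_REF, INST))
  expect_true(all(diff(ph) > 0))
})

test_that("amplitude decays strictly with distance", {
  rho <- seq(10, 60, by = 0.5)
  expect_true(all(diff(Mod(complex_reflectance(rho, MED_REF, INST))) < 0))
})

test_that("linearized intensity is asymptotically linear with slope -Re(k)", {
  # far from the source ln(rho^2 |R|) decays like the effective attenuation
  # of the data-generating model, k = sqrt(3 musp (mua - i omega/v))
  rho <- seq(200, 400, by = 50)
  y <- log(rho^2 * Mod(complex_reflectance(rho, MED_REF, INST)))
  slopes <- diff(y) / diff(rho)
  omega <- 2 * pi * INST$fmod
  k <- sqrt(3 * MED_REF$musp *
              complex(real = MED_REF$mua, imaginary = -omega / INST$v))
  expect_equal(mean(slopes), -Re(k), tolerance = 1e-3)
  expect_lt(max(abs(slopes - slopes[1])) / abs(slopes[1]), 1e-3)
})

test_that("reflectance sets follow the actual geometry, not the nominal one", {
  arr <- ds_arrangement("LINR")
  set <- reflectance_set(arr, MED_REF, INST)
  expect_identical(set$R[["1A"]], set$R[["2B"]]) # equal distances
  expect_identical(set$R[["1B"]], set$R[["2A"]])

  disp <- displace_optodes(arr, list(A = c(1, 0)))
  set_d <- reflectance_set(disp, MED_REF, INST)
  expect_identical(set_d$R[["1A"]],
                   complex_reflectance(26, MED_REF, INST))

  # rigid translation leaves the whole set bit-for-bit unchanged
  shift <- displace_optodes(arr, list("1" = c(4, 9), "2" = c(4, 9),
                                      A = c(4, 9), B = c(4, 9)))
  expect_identical(reflectance_set(shift, MED_REF, INST)$R, set$R)
})

test_that("absorption perturbation attenuates intensity at fixed geometry", {
  arr <- ds_arrangement("LINR")
  pp <- perturbed_pair(arr, MED_REF, INST, delta_mua = 1e-4)
  expect_equal(pp$delta_mua, 1e-4)
  expect_true(all(Mod(pp$perturbed$R) < Mod(pp$baseline$R)))
  same <- perturbed_pair(arr, MED_REF, INST, delta_mua = 0)
  expect_identical(same$baseline$R, same$perturbed$R)
})

test_that("finite-optode averaging reduces to the point kernel and converges", {
  r0 <- finite_optode_reflectance(31, MED_REF, INST, 0, 0)
  expect_identical(r0, complex_reflectance(31, MED_REF, INST))
  r <- finite_optode_reflectance(31, MED_REF, INST, 0.3, 1.5)
  dense <- finite_optode_reflectance(31, MED_REF, INST, 0.3, 1.5,
                                     n_radial = 16L, n_angular = 32L)
  expect_lt(Mod(r - dense) / Mod(dense), 1e-6)
  # the kernel is convex in the separation, so by Jensen's inequality the
  # disk average slightly exceeds the point value at the center distance
  expect_gt(Mod(r), Mod(complex_reflectance(31, MED_REF, INST)))
  expect_error(finite_optode_reflectance(5, MED_REF, INST, 1, 2),
               "radii")
})

test_that("instrument noise is reproducible and vanishes at zero sigma", {
  set <- reflectance_set(ds_arrangement("LINR"), MED_REF, INST)
  expect_identical(add_noise(set, 0, 0)$R, set$R)
  n1 <- add_noise(set, 0.001, 0.1 * pi / 180, seed = 11)
  n2 <- add_noise(set, 0.001, 0.1 * pi / 180, seed = 11)
  expect_identical(n1$R, n2$R)
  expect_false(any(n1$R == set$R))
})

test_that("analytic pathlengths agree with finite differences and behave physically", {
  for (med in list(MED_REF, ds_medium(0.005, 0.5), ds_medium(0.015, 1.5))) {
    La <- complex_pathlengths(c(25, 31, 37), med, INST)
    Ln <- complex_pathlengths(c(25, 31, 37), med, INST, method = "numeric")
    expect_lt(max(Mod(La - Ln) / Mod(La)), 1e-6)
    expect_true(all(Re(La) > 0))
    expect_true(all(diff(Mod(La)) > 0)) # longer paths at larger rho
  }
  cw <- complex_pathlengths(31, MED_REF, fd_instrument(fmod = 0))
  expect_equal(Im(cw), 0)
  expect_gt(Re(cw), 0)
})

test_that("pathlength sets follow the arrangement distances", {
  arr <- ds_arrangement("ALIN")
  L <- pathlength_set(arr, MED_REF, INST)
  expect_named(L, c("1A", "2B", "1B", "2A"))
  expect_equal(unname(L),
               complex_pathlengths(unname(arr$rho), MED_REF, INST))
})

test_that("reflectance sets round-trip through the CSV interchange layout", {
  arr <- displace_optodes(ds_arrangement("LINR"), list(A = c(0.7, -0.2)))
  set <- reflectance_set(arr, MED_REF, INST)
  path <- tempfile(fileext = ".csv")
  write_reflectance_csv(set, path, rho_nominal = ds_arrangement("LINR")$rho)
  back <- read_reflectance_csv(path, INST)
  expect_equal(back$set$R, set$R, tolerance = 1e-12)
  expect_equal(back$set$rho, set$rho, tolerance = 1e-12)
  expect_equal(unname(back$rho_nominal), RHO_SHORT_LONG)
  # inversion on re-read data matches inversion on the original
  f1 <- fit_iterative(set, back$rho_nominal, INST)
  f2 <- fit_iterative(back$set, back$rho_nominal, INST)
  expect_equal(f1$mua, f2$mua, tolerance = 1e-9)
  expect_equal(f1$musp, f2$musp, tolerance = 1e-9)
})
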