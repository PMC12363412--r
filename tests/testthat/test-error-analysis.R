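test_that("rigid co-translation of all optodes produces exactly zero error", {
  for (nm in c("LINR", "DRCT")) {
    arr <- ds_arrangement(nm)
    nom <- fit_iterative(reflectance_set(arr, MED_REF, INST), arr$rho)
    shift <- displace_optodes(arr, list("1" = c(0.6, -0.8),
                                        "2" = c(0.6, -0.8),
                                        A = c(0.6, -0.8), B = c(0.6, -0.8)))
    got <- fit_iterative(reflectance_set(shift, MED_REF, INST), arr$rho)
    expect_identical(got$mua, nom$mua)
    expect_identical(got$musp, nom$musp)
  }
})

test_that("error maps are anchored at the nominal recovery", {
  arr <- ds_arrangement("LINR")
  map <- sweep_square(arr, "1", "mua", MED_REF, INST,
                      halfwidth = 2, step = 1)
  expect_equal(dim(map$values), c(5L, 5L))
  nom <- fit_iterative(reflectance_set(arr, MED_REF, INST), arr$rho)
  expect_equal(map$values[3, 3],
               100 * (nom$mua - MED_REF$mua) / MED_REF$mua,
               tolerance = 1e-9)
  dmap <- sweep_square(arr, "A", "dmua_I", MED_REF, INST,
                       halfwidth = 1, step = 1)
  expect_equal(dmap$values[2, 2], 0, tolerance = 1) # within linearization
  df <- as.data.frame(map)
  expect_equal(nrow(df), 25L)
  expect_equal(df$error_pct[df$dx == 0 & df$dy == 0], map$values[3, 3])
})

test_that("zero orbit radius gives zero sigma", {
  s <- sigma_circle(ds_arrangement("LINR"), "A", MED_REF, INST,
                    radius = 0, n_angles = 8)
  expect_equal(unname(s$sigma_mua_rel), 0)
  expect_equal(unname(s$sigma_musp_rel), 0)
})

test_that("sigma respects the documented symmetry equivalences", {
  pairs <- list(list("LINR", "A", "B"), list("LINR", "1", "2"),
                list("TRAP", "1", "2"), list("DRCT", "1", "B"))
  for (p in pairs) {
    arr <- ds_arrangement(p[[1]])
    s1 <- sigma_circle(arr, p[[2]], MED_REF, INST, n_angles = 24)
    s2 <- sigma_circle(arr, p[[3]], MED_REF, INST, n_angles = 24)
    expect_lt(abs(s1$sigma_mua_rel - s2$sigma_mua_rel) / s2$sigma_mua_rel,
              0.005)
    expect_lt(abs(s1$sigma_musp_rel - s2$sigma_musp_rel) /
                s2$sigma_musp_rel, 0.005)
  }
})

test_that("sigma is converged in the number of orbit angles", {
  arr <- ds_arrangement("LINR")
  s36 <- sigma_circle(arr, "A", MED_REF, INST, n_angles = 36)
  s72 <- sigma_circle(arr, "A", MED_REF, INST, n_angles = 72)
  expect_lt(abs(s36$sigma_mua_rel - s72$sigma_mua_rel) / s72$sigma_mua_rel,
            0.005)
  expect_lt(abs(s36$sigma_musp_rel - s72$sigma_musp_rel) /
              s72$sigma_musp_rel, 0.005)
})

test_that("Monte Carlo sampling is seeded and reproducible", {
  arr <- ds_arrangement("LINR")
  s1 <- sigma_circle(arr, c("1", "2", "A"), MED_REF, INST,
                     mc_samples = 128, seed = 9)
  s2 <- sigma_circle(arr, c("1", "2", "A"), MED_REF, INST,
                     mc_samples = 128, seed = 9)
  expect_identical(s1$sigma_mua_rel, s2$sigma_mua_rel)
  expect_identical(s1$sigma_musp_rel, s2$sigma_musp_rel)
  expect_equal(s1$sampling, "monte_carlo")
  expect_equal(s1$n_samples, 128L)
})

test_that("zero-change lines pass through the origin with the right support direction", {
  arr <- ds_arrangement("LINR")
  for (q in c("mua", "musp")) {
    map <- sweep_square(arr, "1", q, MED_REF, INST,
                        halfwidth = 3, step = 0.5)
    zl <- zero_change_lines(map)
    # passes within one grid cell of the nominal position
    expect_lt(min(sqrt(rowSums(zl$polyline^2))), map$dx[2] - map$dx[1])
    # along the probe axis the error varies; across it, it does not:
    # the zero-change line is the y axis, the support the x axis
    expect_lt(abs(zl$tangent[1]), 0.05)
    expect_gt(abs(zl$support_direction[1]), 0.998)
    # the error interpolated along the polyline stays near zero
    interp <- apply(zl$polyline, 1, function(p) {
      i <- findInterval(p[1], map$dx, rightmost.closed = TRUE)
      j <- findInterval(p[2], map$dy, rightmost.closed = TRUE)
      fx <- (p[1] - map$dx[i]) / (map$dx[i + 1] - map$dx[i])
      fy <- (p[2] - map$dy[j]) / (map$dy[j + 1] - map$dy[j])
      z <- map$values - map$values[map$dx == 0, map$dy == 0]
      (1 - fx) * (1 - fy) * z[i, j] + fx * (1 - fy) * z[i + 1, j] +
        (1 - fx) * fy * z[i, j + 1] + fx * fy * z[i + 1, j + 1]
    })
    expect_lt(max(abs(interp)), 0.1)
  }
})

test_that("error maps round-trip through CSV", {
  map <- sweep_square(ds_arrangement("LINR"), "A", "musp", MED_REF, INST,
                      halfwidth = 1, step = 1)
  path <- tempfile(fileext = ".csv")
  write_error_map(map, path)
  df <- read.csv(path)
  expect_equal(df$error_pct, as.vector(map$values))
  expect_equal(unique(df$quantity), "musp")
})
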