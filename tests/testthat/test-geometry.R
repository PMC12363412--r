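test_that("nominal arrangements have the canonical pair distances", {
  expect_equal(unname(ds_arrangement("LINR")$rho), RHO_SHORT_LONG)
  expect_equal(unname(ds_arrangement("ALIN")$rho), RHO_ALIN)
  expect_equal(unname(ds_arrangement("DRCT")$rho), RHO_SHORT_LONG)
  expect_equal(unname(ds_arrangement("TRAP")$rho), RHO_SHORT_LONG,
               tolerance = 1e-12)
  for (nm in c("LINR", "ALIN", "TRAP", "DRCT"))
    expect_equal(mean(ds_arrangement(nm)$rho), 31, tolerance = 1e-9)
})

test_that("self-calibrating pairing holds at nominal positions", {
  for (nm in c("LINR", "TRAP", "DRCT")) {
    rho <- ds_arrangement(nm)$rho
    expect_equal(rho[["1A"]], rho[["2B"]], tolerance = 1e-12)
    expect_equal(rho[["1B"]], rho[["2A"]], tolerance = 1e-12)
  }
})

test_that("trapezoid legs and diagonals are 25 and 37 mm for any valid b", {
  for (b in c(13, trap_right_angle_b(), 24, 40, 61)) {
    rho <- ds_arrangement("TRAP", trap_b = b)$rho
    expect_equal(unname(rho), RHO_SHORT_LONG, tolerance = 1e-9)
  }
  expect_error(ds_arrangement("TRAP", trap_b = 11), "trap_b")
  expect_error(ds_arrangement("TRAP", trap_b = 70), "trap_b")
})

test_that("trapezoid degenerates to the collinear layout at b = 12", {
  arr <- ds_arrangement("TRAP", trap_b = 12)
  expect_equal(max(abs(arr$optodes[, "y"])), 0, tolerance = 1e-9)
  # centered LINR: sources at +/-31, detectors at +/-6
  expect_equal(sort(unname(arr$optodes[, "x"])), sort(c(-31, 31, -6, 6)),
               tolerance = 1e-9)
})

test_that("the default trapezoid puts the sources at right angles as seen from each detector", {
  arr <- ds_arrangement("TRAP")
  for (det in c("A", "B")) {
    v1 <- arr$optodes["1", ] - arr$optodes[det, ]
    v2 <- arr$optodes["2", ] - arr$optodes[det, ]
    expect_equal(sum(v1 * v2), 0, tolerance = 1e-9)
  }
})

test_that("pair distances are invariant under rigid motion", {
  for (nm in c("LINR", "ALIN", "TRAP", "DRCT")) {
    arr <- ds_arrangement(nm)
    shifted <- displace_optodes(arr, list("1" = c(5, -3), "2" = c(5, -3),
                                          A = c(5, -3), B = c(5, -3)))
    expect_equal(shifted$rho, arr$rho, tolerance = 1e-9)
    th <- 0.7
    rot <- arr
    rot$optodes <- arr$optodes %*% matrix(c(cos(th), -sin(th),
                                            sin(th), cos(th)), 2)
    expect_equal(unname(pair_distances(rot)), unname(arr$rho),
                 tolerance = 1e-9)
  }
})

test_that("displacements move only their targets and recompute distances", {
  arr <- ds_arrangement("LINR")
  expect_equal(displace_optodes(arr, list(A = c(0, 0)))$rho, arr$rho)
  moved <- displace_optodes(arr, list(A = c(1, 0)))
  expect_equal(unname(moved$rho), c(26, 25, 37, 36))
  expect_equal(moved$optodes["B", ], arr$optodes["B", ])
  expect_equal(displace_optodes(arr, list(A = c(0, 1)))$rho[["1A"]],
               sqrt(626))
  expect_equal(unname(arr$rho), RHO_SHORT_LONG) # original untouched
  expect_error(displace_optodes(arr, list(Z = c(1, 0))), "subset")
})

test_that("circle positions are equally spaced, start on +x, and average to the center", {
  ctr <- c(3, -2)
  expect_true(all(circle_positions(ctr, 0, 5) ==
                    matrix(ctr, 5, 2, byrow = TRUE)))
  p4 <- circle_positions(ctr, 1, 4)
  expect_equal(p4, cbind(x = ctr[1] + c(1, 0, -1, 0),
                         y = ctr[2] + c(0, 1, 0, -1)), tolerance = 1e-12)
  for (n in c(2, 3, 7, 72))
    expect_equal(colMeans(circle_positions(ctr, 2.5, n)),
                 c(x = ctr[1], y = ctr[2]), tolerance = 1e-12)
})

test_that("arrangements round-trip through config and CSV files", {
  cfg <- tempfile(fileext = ".yml")
  writeLines(c("name: TRAP", "trap_b: 20"), cfg)
  arr <- read_arrangement(cfg)
  expect_equal(arr$optodes, ds_arrangement("TRAP", trap_b = 20)$optodes)

  cfg2 <- tempfile(fileext = ".yml")
  writeLines(c("name: LINR", "coordinates:", "  A: [24, 0]"), cfg2)
  expect_equal(read_arrangement(cfg2)$rho[["1A"]], 24)

  out <- tempfile(fileext = ".csv")
  write_arrangement(arr, out)
  df <- read.csv(out)
  expect_equal(df$optode, c("1", "2", "A", "B"))
  expect_equal(cbind(df$x, df$y), unname(arr$optodes))
})
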