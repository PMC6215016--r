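test_that("peak location returns the depth of a delta dose and is shift-equivariant", {
  g <- tiny_grid()
  dose <- array(0, g$shape)
  dose[5, 5, 6] <- 1          # voxel-centre depth 27.5 mm
  k <- manual_kernel(g, fluence = dose, dose = dose)
  expect_identical(locate_bragg_peak(k), 27.5)

  k2 <- k
  k2$dose <- shift_axis(k$dose, 3, 2)   # +10 mm at 5 mm voxels
  expect_identical(locate_bragg_peak(k2), 37.5)

  k$dose[] <- 0
  expect_error(locate_bragg_peak(k), "all zero")
})

test_that("ties in the depth-dose maximum break towards the shallower depth", {
  g <- tiny_grid()
  dose <- array(0, g$shape)
  dose[5, 5, 4] <- 1
  dose[5, 5, 8] <- 1
  k <- manual_kernel(g, fluence = dose, dose = dose)
  expect_identical(locate_bragg_peak(k), (4 - 0.5) * 5)
})

test_that("depth interpolation is exact at references and reproduces quadratics", {
  refs <- reference_beam_points("proton")
  expect_identical(interp_bragg_depth(132, refs), 109)
  expect_equal(interp_bragg_depth(refs$energy, refs), refs$depth)

  # references on an exact quadratic -> interpolant equals it everywhere
  qe <- c(80, 110, 150, 180)
  quad <- function(x) 3 + 0.2 * x + 0.004 * x^2
  qrefs <- data.frame(energy = qe, depth = quad(qe))
  xs <- seq(80, 180, by = 2.5)
  expect_equal(interp_bragg_depth(xs, qrefs), quad(xs), tolerance = 1e-10)
})

test_that("depth interpolation brackets, refuses extrapolation, and is continuous", {
  refs <- reference_beam_points("proton")
  d150 <- interp_bragg_depth(150, refs)
  expect_gt(d150, 109); expect_lt(d150, 141)
  expect_error(interp_bragg_depth(200, refs), "extrapolation")
  expect_error(interp_bragg_depth(50, refs), "extrapolation")
  # continuity at the interval joins
  for (e0 in refs$energy[2:3]) {
    lo <- interp_bragg_depth(e0 - 1e-7, refs)
    hi <- interp_bragg_depth(e0 + 1e-7, refs)
    expect_lt(abs(hi - lo), 1e-4)
  }
})

test_that("library returns reference kernels bit-identically", {
  lib <- build_kernel_library("proton", small_grid(), default_params())
  for (i in 1:4) {
    k <- kernel_at(lib, lib$ref_table$energy[i])
    expect_identical(k$dose, lib$refs[[i]]$dose)
    expect_identical(k$fluence, lib$refs[[i]]$fluence)
  }
  expect_error(kernel_at(lib, 50), "outside the library range")
})

test_that("interpolated kernels land on the interpolated depth curve", {
  lib <- build_kernel_library("proton", small_grid(), default_params())
  vox <- lib$grid$voxel[3]
  for (e in c(90, 120, 145, 170)) {
    k <- kernel_at(lib, e)
    expect_lte(abs(k$bragg_depth - interp_bragg_depth(e, lib$ref_table)),
               vox + 1e-9)
  }
})

test_that("Bragg depth is monotone and total dose continuous across the library", {
  lib <- build_kernel_library("proton", small_grid(), default_params())
  depths <- vapply(seq(73, 182, by = 5), function(e)
    kernel_at(lib, e)$bragg_depth, numeric(1))
  expect_true(all(diff(depths) >= 0))
  expect_true(any(diff(depths) > 0))
  # mass continuity at the library's 1 MeV/u step, across a reference
  # energy (132 MeV/u) where the bracketing pair changes
  totals <- vapply(126:138, function(e) sum(kernel_at(lib, e)$dose),
                   numeric(1))
  expect_lt(max(abs(diff(totals)) / totals[-1]), 0.05)
})

test_that("peak-aligning translations lose under 1% of the dose", {
  # shifting a reference kernel deeper to align its peak with the
  # highest-energy peak keeps the whole distribution inside the grid
  lib <- build_kernel_library("proton", small_grid(), default_params())
  vox <- lib$grid$voxel[3]
  z_hi <- lib$ref_table$depth[4]
  for (i in 1:3) {
    k <- lib$refs[[i]]
    up <- shift_axis(k$dose, 3, (z_hi - k$bragg_depth) / vox)
    expect_lt(abs(sum(up) - sum(k$dose)) / sum(k$dose), 0.01)
    # and the round trip back restores the integral
    back <- shift_axis(up, 3, (k$bragg_depth - z_hi) / vox)
    expect_lt(abs(sum(back) - sum(k$dose)) / sum(k$dose), 0.01)
  }
})

test_that("proton library has 110 energies at 1 MeV/u and warns on non-dividing steps", {
  lib <- build_kernel_library("proton", small_grid(), default_params())
  expect_length(library_energies(lib, 1), 110)
  expect_warning(e <- library_energies(lib, 40), "truncated")
  expect_equal(max(e), 153)
})

test_that("nearest-voxel alignment mode shifts by whole voxels only", {
  lib <- build_kernel_library("proton", small_grid(), default_params())
  k <- kernel_at(lib, 120, align_mode = "nearest")
  vox <- lib$grid$voxel[3]
  expect_lte(abs(k$bragg_depth - interp_bragg_depth(120, lib$ref_table)), vox)
})
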