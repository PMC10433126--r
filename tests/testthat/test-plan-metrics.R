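# Volumes, histograms, conformity/gradient metrics, iso-surfaces

test_that("mask volumes recover analytic solids within voxelization error", {
  spec <- grid_spec(60, 1)
  ten <- array(FALSE, rep(60, 3)); ten[1:10, 1, 1] <- TRUE
  expect_equal(mask_volume(structure_mask(spec, ten)), 10)
  sph <- ellipsoid_mask(c(30, 30, 30), c(10, 10, 10), spec)
  expect_equal(mask_volume(sph), 4 / 3 * pi * 1000, tolerance = 0.02)
  ell <- ellipsoid_mask(c(30, 30, 30), c(10, 8, 6), spec)
  expect_equal(mask_volume(ell), 4 / 3 * pi * 480, tolerance = 0.02)
  empty <- structure_mask(spec, array(FALSE, rep(60, 3)))
  expect_warning(v <- mask_volume(empty), "empty")
  expect_identical(v, 0)
})

test_that("histograms conserve volume and behave on uniform fields", {
  spec <- grid_spec(30, 1)
  vals <- array(0, rep(30, 3))
  mask <- ellipsoid_mask(c(15, 15, 15), c(8, 8, 8), spec)
  vals[mask$voxels] <- 10
  g <- dose_grid(spec, vals)
  h <- dvh(g, mask, bin_width = 1)
  vol <- mask_volume(mask)
  expect_equal(sum(h$differential_mm3), vol, tolerance = 1e-9)
  # all volume in the [10, 11) bin
  expect_equal(h$differential_mm3[11], vol)
  expect_true(all(h$differential_mm3[-11] == 0))
  expect_true(all(h$cumulative_mm3[h$bin_edges <= 10] == vol))
  expect_true(all(h$cumulative_mm3[h$bin_edges > 10] == 0))
  expect_equal(h$cumulative_mm3[1], vol)
})

test_that("a linear ramp yields a staircase cumulative and the right median", {
  spec <- grid_spec(40, 1)
  ramp <- array(rep(seq(0, 20, length.out = 40), times = 40 * 40),
                rep(40, 3))
  g <- dose_grid(spec, ramp)
  box <- array(TRUE, rep(40, 3))
  mask <- structure_mask(spec, box)
  h <- dvh(g, mask, bin_width = 0.5)
  expect_equal(sum(h$differential_mm3), 40^3)
  expect_true(all(diff(h$cumulative_mm3) <= 0))
  expect_equal(bed3d:::dvh_median(h), 10, tolerance = 0.5 / 10 + 0.03)
  expect_equal(percent_volume_at(g, mask, 10), 50, tolerance = 0.03)
})

test_that("histogram conservation and monotonicity hold on random fields", {
  spec <- grid_spec(20, 1)
  for (seed in 1:5) {
    set.seed(seed)
    g <- dose_grid(spec, array(rexp(20^3, 1 / 5), rep(20, 3)))
    mask <- structure_mask(spec, array(runif(20^3) < 0.3, rep(20, 3)))
    h <- dvh(g, mask, bin_width = runif(1, 0.2, 2))
    expect_equal(sum(h$differential_mm3), mask_volume(mask),
                 tolerance = 1e-9)
    expect_true(all(diff(h$cumulative_mm3) <= 0))
    expect_equal(h$cumulative_mm3[1], mask_volume(mask))
  }
})

test_that("iso-level volumes follow Gaussian shell geometry", {
  cm <- fix_gauss_model(sigma = 5)
  spec <- grid_spec(140, 0.5)
  plan <- quick_plan(4, 35, 35, 35, 2, 5)
  g <- accumulate_dose(plan, list("4" = cm), spec)
  mx <- max(g$values)
  expect_identical(isolevel_volume(g, mx * 1.1), 0)
  r50 <- 5 * sqrt(2 * log(2))  # FWHM/2 of the sigma = 5 Gaussian
  expect_equal(isolevel_volume(g, mx / 2), 4 / 3 * pi * r50^3,
               tolerance = 0.03)
  expect_equal(isolevel_volume(g, mx / 4) / isolevel_volume(g, mx / 2),
               2^(3 / 2), tolerance = 0.05)
  expect_equal(gradient_index(g, mx / 2), 2^(3 / 2), tolerance = 0.05)
})

test_that("a heavier falloff tail strictly increases the gradient index", {
  # GI of a pure Gaussian at a fixed relative level is scale invariant,
  # so steepness is varied through the tail weight, not the width
  spec <- grid_spec(100, 0.5)
  co <- bed3d:::grid_coords(spec)
  r2 <- outer(outer((co - 25)^2, (co - 25)^2, "+"), (co - 25)^2, "+")
  g_steep <- dose_grid(spec, 10 * exp(-r2 / (2 * 16)))
  g_tailed <- dose_grid(spec, 10 * (0.85 * exp(-r2 / (2 * 16)) +
                                      0.15 * exp(-r2 / (2 * 64))))
  expect_gt(gradient_index(g_tailed, 5), gradient_index(g_steep, 5))
  expect_gte(gradient_index(g_steep, 5), 1)
})

test_that("the Paddick conformity index spans its textbook cases", {
  spec <- grid_spec(40, 1)
  vals <- array(0, rep(40, 3))
  sph <- ellipsoid_mask(c(20, 20, 20), c(8, 8, 8), spec)
  vals[sph$voxels] <- 10
  g <- dose_grid(spec, vals)
  # prescription exactly covers the target
  expect_equal(paddick_ci(g, sph, 10), 1)
  # target wholly inside the prescription, TV = PIV/2 (by construction)
  inner <- ellipsoid_mask(c(20, 20, 20), c(8, 8, 8) / 2^(1 / 3), spec)
  ci <- paddick_ci(g, inner, 10)
  expect_equal(ci, sum(inner$voxels) / sum(sph$voxels), tolerance = 1e-12)
  expect_equal(ci, 0.5, tolerance = 0.03)
  # disjoint target and prescription
  far <- ellipsoid_mask(c(35, 35, 35), c(3, 3, 3), spec)
  expect_equal(paddick_ci(g, far, 10), 0)
  expect_error(paddick_ci(g, sph, 99), "undefined")
  expect_error(gradient_index(g, 99), "undefined")
  for (lev in c(2, 5, 10)) {
    ci <- paddick_ci(g, sph, lev)
    expect_true(ci > 0 && ci <= 1)
  }
})

test_that("percent volume at a level hits its boundary cases", {
  spec <- grid_spec(20, 1)
  set.seed(3)
  g <- dose_grid(spec, array(runif(20^3, 0, 20), rep(20, 3)))
  mask <- ellipsoid_mask(c(10, 10, 10), c(6, 6, 6), spec)
  expect_equal(percent_volume_at(g, mask, 0), 100)
  expect_equal(percent_volume_at(g, mask, 21), 0)
  p <- percent_volume_at(g, mask, 10)
  expect_true(p > 0 && p < 100)
})

test_that("iso-surfaces are geometrically faithful on a Gaussian ball", {
  cm <- fix_gauss_model(sigma = 3)
  spec <- grid_spec(100, 0.5)
  g <- accumulate_dose(quick_plan(4, 25, 25, 25, 2, 5), list("4" = cm),
                       spec)
  mx <- max(g$values)
  msh <- extract_isosurface(g, mx / 2)
  radii <- sqrt(rowSums(sweep(msh$vertices, 2, c(25, 25, 25))^2))
  r50 <- 3 * sqrt(2 * log(2))
  expect_lt(max(abs(radii - r50)), 0.6)
  expect_equal(mesh_volume(msh), isolevel_volume(g, mx / 2),
               tolerance = 0.05)
  # vertices stay inside the grid and faces index real vertices
  co <- bed3d:::grid_coords(spec)
  expect_true(all(msh$vertices >= min(co) & msh$vertices <= max(co)))
  expect_true(all(msh$faces >= 1 & msh$faces <= nrow(msh$vertices)))
  expect_error(extract_isosurface(g, mx * 2), "empty mesh")
})

test_that("plan metrics are stable under grid refinement", {
  cm <- fix_gauss_model(sigma = 7)
  plan <- quick_plan(4, 40, 40, 40, 2, 5)
  mask_for <- function(spec) ellipsoid_mask(c(40, 40, 40), c(9, 9, 9), spec)
  g1 <- accumulate_dose(plan, list("4" = cm), grid_spec(80, 1))
  g2 <- accumulate_dose(plan, list("4" = cm), grid_spec(160, 0.5))
  lev <- max(g1$values) / 2
  ci1 <- paddick_ci(g1, mask_for(grid_spec(80, 1)), lev)
  ci2 <- paddick_ci(g2, mask_for(grid_spec(160, 0.5)), lev)
  expect_lt(abs(ci1 - ci2) / ci2, 0.03)
  gi1 <- gradient_index(g1, lev)
  gi2 <- gradient_index(g2, lev)
  expect_lt(abs(gi1 - gi2) / gi2, 0.03)
})
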