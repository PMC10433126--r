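# Voxel dose mapping: ellipsoid-expansion coefficient, per-shot fields,
# superposition

test_that("the ellipsoid-expansion coefficient matches its closed forms", {
  expect_identical(ellipsoid_coefficient(c(100, 100, 100),
                                         c(100, 100, 100), c(6, 6, 5)), 0)
  # equal FWHMs: L reduces to the Euclidean offset
  expect_equal(ellipsoid_coefficient(c(103, 100, 100), c(100, 100, 100),
                                     c(6, 6, 6)), 3)
  # anisotropic: L = (6*6*5)^(1/3) * 3/6
  expect_equal(ellipsoid_coefficient(c(103, 100, 100), c(100, 100, 100),
                                     c(6, 6, 5)), 180^(1 / 3) / 2,
               tolerance = 1e-12)
  expect_error(ellipsoid_coefficient(c(1, 2, 3), c(0, 0, 0), c(6, 0, 5)),
               "positive")
})

test_that("dose depends only on radius for isotropic falloff", {
  iso <- c(100, 100, 100)
  fwhm <- c(6, 6, 6)
  probes <- rbind(c(103, 104, 100), c(100, 103, 104), c(104, 100, 103),
                  c(95, 100, 100), c(100, 100, 95))
  L <- ellipsoid_coefficient(probes, iso, fwhm)
  expect_equal(L[1], L[2], tolerance = 1e-9)
  expect_equal(L[2], L[3], tolerance = 1e-9)
  expect_equal(L[4], L[5], tolerance = 1e-9)
})

test_that("the shot contour is the half-FWHM ellipsoid and is consistent with the profile", {
  cm <- fix_model(8)
  shot <- quick_plan(8, 100, 100, 100, 2, 5)[1, ]
  ct <- shot_contour(shot, cm)
  expect_equal(unname(ct$semiaxes), unname(cm$fwhm / 2))
  expect_equal(ct$center, c(100, 100, 100))
  # Eq-8 identity: ellipsoid volume equals the sphere at the geometric
  # mean of the semiaxes
  l50 <- prod(ct$semiaxes)^(1 / 3)
  expect_equal(ct$volume_mm3, 4 / 3 * pi * l50^3, tolerance = 1e-12)
  # points on the contour evaluate to half maximum through the profile
  th <- seq(0, pi, length.out = 7)[-c(1, 7)]
  for (t in th) {
    p <- ct$center + ct$semiaxes * c(sin(t) * cos(2 * t), sin(t) * sin(2 * t),
                                     cos(t))
    L <- ellipsoid_coefficient(p, ct$center, cm$fwhm)
    expect_equal(evaluate_profile(cm, L), 0.5, tolerance = 0.02)
  }
  expect_error(shot_contour(quick_plan(4, 100, 100, 100, 2, 5)[1, ], cm),
               "mismatch")
})

test_that("per-shot dose fields obey the rate-time product and linearity", {
  cm <- fix_model(4)
  spec <- grid_spec(60, 1)
  shot <- quick_plan(4, 30, 30, 30, 2, 5)[1, ]
  f <- shot_dose_field(shot, cm, spec)
  dense <- expand_shot_field(f)
  expect_equal(dense[30, 30, 30], 10, tolerance = 0.01 * 10)
  # voxel near the half-max contour along x
  hx <- round(cm$fwhm[["x"]] / 2)
  L <- ellipsoid_coefficient(c(30 + hx, 30, 30), c(30, 30, 30), cm$fwhm)
  expect_equal(dense[30 + hx, 30, 30],
               10 * evaluate_profile(cm, L), tolerance = 1e-9)
  # doubling the duration doubles every voxel exactly
  shot2 <- shot; shot2$duration_min <- 10
  f2 <- shot_dose_field(shot2, cm, spec)
  expect_equal(f2$values, 2 * f$values, tolerance = 1e-12)
})

test_that("the bounding-box restriction is invisible against full-grid evaluation", {
  cm <- fix_model(4)
  spec <- grid_spec(48, 1)
  shot <- quick_plan(4, 20, 24, 28, 1.7, 6)[1, ]
  dense <- expand_shot_field(shot_dose_field(shot, cm, spec))
  co <- bed3d:::grid_coords(spec)
  full <- array(0, rep(48, 3))
  for (k in 1:48) {
    pts <- as.matrix(expand.grid(x = co, y = co, z = rep(co[k], 1)))
    L <- ellipsoid_coefficient(pts, c(20, 24, 28), cm$fwhm)
    full[, , k] <- matrix(1.7 * 6 * evaluate_profile(cm, L), 48, 48)
  }
  expect_lt(max(abs(dense - full)), 1e-12)
  # beyond l_max both are exactly zero
  expect_identical(dense[48, 48, 48], 0)
})

test_that("dose superposes linearly and distant shots do not interact", {
  cm <- fix_model(4)
  spec <- grid_spec(200, 1)
  single <- accumulate_dose(quick_plan(4, 30, 30, 30, 2, 5),
                            list("4" = cm), spec)
  twice <- accumulate_dose(quick_plan(4, c(30, 30), c(30, 30), c(30, 30),
                                      2, 5), list("4" = cm), spec)
  expect_equal(twice$values, 2 * single$values, tolerance = 1e-12)
  apart <- accumulate_dose(quick_plan(4, c(10, 190), c(10, 190), c(10, 190),
                                      2, 5), list("4" = cm), spec)
  expect_equal(max(apart$values), max(single$values), tolerance = 1e-9)
  # a region far from every shot receives nothing
  expect_identical(apart$values[100, 100, 100], 0)
  expect_error(accumulate_dose(quick_plan(8, 30, 30, 30, 2, 5),
                               list("4" = cm), spec), "8")
})

test_that("per-shot fields reconstruct the total exactly when retained", {
  cm <- fix_model(4)
  spec <- grid_spec(40, 1)
  plan <- quick_plan(4, c(18, 22, 20), c(20, 20, 23), c(20, 19, 21),
                     c(2, 1.5, 2.5), c(5, 3, 8), c(2, 4, 0))
  dg <- accumulate_dose(plan, list("4" = cm), spec, keep_per_shot = TRUE)
  total <- Reduce(`+`, lapply(dg$per_shot, expand_shot_field))
  expect_lt(max(abs(total - dg$values)), 1e-9)
})

test_that("halving the grid spacing moves interpolated dose by under 1%", {
  cm <- fix_model(18)
  plan <- quick_plan(18, 30, 30, 30, 2, 5)
  g1 <- accumulate_dose(plan, list("18" = cm), grid_spec(60, 1))
  g2 <- accumulate_dose(plan, list("18" = cm), grid_spec(120, 0.5))
  set.seed(7)
  probes <- cbind(runif(20, 23, 37), runif(20, 23, 37), runif(20, 23, 37))
  v1 <- interp_grid(g1, probes)
  v2 <- interp_grid(g2, probes)
  expect_lt(max(abs(v1 - v2) / max(v2)), 0.01)
})

test_that("an isocenter outside the matrix warns but still contributes its overlap", {
  cm <- fix_model(4)
  spec <- grid_spec(20, 1)
  plan <- suppressWarnings(
    quick_plan(4, 22, 10, 10, 2, 5))  # inside frame box, outside this grid
  expect_warning(f <- shot_dose_field(plan[1, ], cm, spec),
                 "outside")
  dense <- expand_shot_field(f)
  expect_gt(dense[20, 10, 10], 0)
})
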