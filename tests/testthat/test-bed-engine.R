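# Interaction factor, its quadrature oracle, and grid-level BED

test_that("timelines accumulate beam-on times and gaps", {
  tl <- build_timeline(quick_plan(4, c(100, 100), c(100, 100), c(100, 100),
                                  2, c(5, 3), c(2, 0)))
  expect_equal(tl$start_times, c(0, 7))
  tl0 <- build_timeline(quick_plan(4, rep(100, 3), rep(100, 3), rep(100, 3),
                                   2, c(1, 2, 3), 0))
  expect_equal(tl0$start_times, c(0, 1, 3))
  expect_equal(build_timeline(quick_plan(4, 100, 100, 100, 2, 5))$start_times,
               0)
})

test_that("single-shot interaction factor matches the Lea-Catcheside closed form", {
  tl <- build_timeline(quick_plan(4, 100, 100, 100, 2, 2))
  mu <- 1
  dt <- 2
  closed <- 2 / (mu^2 * dt^2) * (mu * dt - 1 + exp(-mu * dt))
  expect_equal(phi(3, tl, mu), closed, tolerance = 1e-12)
  expect_equal(phi_numeric_oracle(3, tl, mu), closed, tolerance = 1e-7)
  # acute limit: no repair during a vanishing exposure
  expect_equal(phi(3, tl, 1e-6), 1, tolerance = 1e-5)
})

test_that("phi agrees with the quadrature oracle over randomized plans", {
  for (seed in 1:12) {
    cs <- random_phi_case(seed)
    p <- phi(cs$doses, cs$timeline, cs$mu)
    po <- phi_numeric_oracle(cs$doses, cs$timeline, cs$mu)
    expect_lt(abs(p - po) / p, 1e-6)
  }
})

test_that("phi limits behave physically", {
  plan <- quick_plan(4, rep(100, 3), rep(100, 3), rep(100, 3), 2,
                     c(5, 8, 3), c(4, 6, 0))
  tl <- build_timeline(plan)
  d <- c(2, 1, 3)
  # no repair (mu -> 0): full interaction, Phi -> (sum d)^2 / sum d^2
  expect_equal(phi(d, tl, 1e-8), sum(d)^2 / sum(d^2), tolerance = 1e-5)
  # instant repair (mu -> infinity): Phi -> 0
  expect_lt(phi(d, tl, 1e4), 1e-3)
  # widening any gap cannot increase Phi (cross terms decay)
  wider <- plan
  wider$gap_after_min[1] <- 20
  expect_lt(phi(d, build_timeline(wider), 0.5), phi(d, tl, 0.5))
  # infinite separation: dose-squared-weighted mean of the self terms
  far <- quick_plan(4, rep(100, 2), rep(100, 2), rep(100, 2), 2,
                    c(5, 5), c(1e6, 0))
  tlf <- build_timeline(far)
  A <- timing_weights(tlf, 0.5)$diag
  d2 <- c(2, 2)
  expect_equal(phi(d2, tlf, 0.5), sum(d2^2 * A) / sum(d2^2),
               tolerance = 1e-10)
})

test_that("zero-dose shots only contribute elapsed time", {
  with_shot <- quick_plan(4, rep(100, 3), rep(100, 3), rep(100, 3), 2,
                          c(5, 2, 5), c(1, 1, 0))
  tl3 <- build_timeline(with_shot)
  # dropping the zero-dose middle shot but keeping the elapsed time
  without <- quick_plan(4, rep(100, 2), rep(100, 2), rep(100, 2), 2,
                        c(5, 5), c(4, 0))
  tl2 <- build_timeline(without)
  mu <- 0.3
  expect_equal(phi(c(2, 0, 3), tl3, mu), phi(c(2, 3), tl2, mu),
               tolerance = 1e-12)
  expect_error(phi(c(0, 0, 0), tl3, mu), "zero")
})

test_that("swapping the doses of equal-duration shots leaves phi unchanged", {
  plan <- quick_plan(4, rep(100, 2), rep(100, 2), rep(100, 2), 2,
                     c(6, 6), c(3, 0))
  tl <- build_timeline(plan)
  expect_equal(phi(c(1, 4), tl, 0.7), phi(c(4, 1), tl, 0.7),
               tolerance = 1e-12)
})

test_that("timing weights stay in their physical ranges", {
  for (seed in 13:18) {
    cs <- random_phi_case(seed)
    tw <- timing_weights(cs$timeline, cs$mu)
    expect_true(all(tw$diag > 0 & tw$diag <= 1))
    up <- tw$cross[upper.tri(tw$cross)]
    if (length(up)) expect_true(all(up >= 0 & up < 2))
    # phi bounded by the full-interaction ratio
    p <- phi(cs$doses, cs$timeline, cs$mu)
    expect_gt(p, 0)
    expect_lte(p, sum(cs$doses)^2 / sum(cs$doses^2) + 1e-12)
  }
})

test_that("voxel BED has the acute single- and split-shot limits", {
  rp <- rp_fix(alpha_beta = 8.2)
  D <- 12
  tl1 <- build_timeline(quick_plan(4, 100, 100, 100, 2, 1e-4))
  expect_equal(bed_voxel(D, tl1, rp), D + D^2 / 8.2, tolerance = 1e-3)
  # two coincident acute shots, zero gap: full interaction restores (sum d)^2
  tl2 <- build_timeline(quick_plan(4, rep(100, 2), rep(100, 2), rep(100, 2),
                                   2, 1e-4, 0))
  expect_equal(bed_voxel(c(D / 2, D / 2), tl2, rp), D + D^2 / 8.2,
               tolerance = 1e-3)
  expect_identical(bed_voxel(c(0, 0), tl2, rp), 0)
  # protraction strictly reduces BED below the acute value
  tl_long <- build_timeline(quick_plan(4, 100, 100, 100, 2, 60))
  expect_lt(bed_voxel(D, tl_long, rp), D + D^2 / 8.2)
})

test_that("grid-level BED equals voxelwise BED and dominates physical dose", {
  cm <- fix_model(4)
  spec <- grid_spec(20, 1)
  plan <- quick_plan(4, c(9, 11, 10), c(10, 10, 12), c(10, 10, 9),
                     c(2, 1.5, 2.5), c(5, 3, 8), c(2, 4, 0))
  dg <- accumulate_dose(plan, list("4" = cm), spec, keep_per_shot = TRUE)
  tl <- build_timeline(plan)
  rp <- rp_fix()
  bg <- compute_bed(dg, tl, rp)
  dense <- lapply(dg$per_shot, expand_shot_field)
  for (v in seq(1, 20^3, by = 37)) {
    idx <- arrayInd(v, rep(20, 3))
    d <- vapply(dense, function(a) a[idx], 0)
    expect_equal(bg$values[idx], bed_voxel(d, tl, rp), tolerance = 1e-9)
  }
  expect_true(all(bg$values >= dg$values - 1e-12))
  expect_true(all(bg$values[dg$values == 0] == 0))
  # doubling alpha/beta shrinks the quadratic excess everywhere dosed
  rp2 <- rp_fix(alpha_beta = 2 * 2.47)
  bg2 <- compute_bed(dg, tl, rp2)
  dosed <- dg$values > 0
  expect_true(all((bg2$values - dg$values)[dosed] <
                    (bg$values - dg$values)[dosed]))
  expect_error(compute_bed(accumulate_dose(plan, list("4" = cm), spec),
                           tl, rp), "per-shot")
})

test_that("a single-shot BED field is the quadratic transform of its dose", {
  cm <- fix_model(4)
  spec <- grid_spec(24, 1)
  plan <- quick_plan(4, 12, 12, 12, 2, 10)
  dg <- accumulate_dose(plan, list("4" = cm), spec, keep_per_shot = TRUE)
  tl <- build_timeline(plan)
  rp <- rp_fix(alpha_beta = 8.2)
  bg <- compute_bed(dg, tl, rp)
  g <- (phi(1, tl, rp$mu_fast) + rp$partition_c * phi(1, tl, rp$mu_slow)) /
    (1 + rp$partition_c)
  expect_equal(bg$values, dg$values + g * dg$values^2 / 8.2,
               tolerance = 1e-9)
})
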