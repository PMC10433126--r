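# Shared fixtures. Fitted collimator models are memoised per test run:
# fitting is deterministic, so caching only saves time, never hides state.

.fixture_cache <- new.env(parent = emptyenv())

# noise-free fixture model for one collimator label
fix_model <- function(collimator, seed = 1L, noise_sd = 0) {
  key <- sprintf("cm_%s_%d_%g", collimator, seed, noise_sd)
  if (is.null(.fixture_cache[[key]])) {
    tabs <- sim_profile_tables(collimator, noise_sd = noise_sd, seed = seed)
    .fixture_cache[[key]] <- fit_collimator(tabs)
  }
  .fixture_cache[[key]]
}

# three identical isotropic pure-Gaussian axis tables, exp(-t^2/(2 sigma^2))
gauss_tables <- function(sigma = 3, spacing = 0.5, collimator = 4) {
  ext <- spacing * ceiling(4 * sigma / spacing)
  off <- seq(-ext, ext, by = spacing)
  lapply(c("x", "y", "z"), function(ax)
    profile_table(collimator, ax, off, exp(-off^2 / (2 * sigma^2))))
}

fix_gauss_model <- function(sigma = 3) {
  key <- sprintf("gauss_%g", sigma)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- fit_collimator(gauss_tables(sigma))
  .fixture_cache[[key]]
}

# example repair parameters (literature-style bi-exponential values)
rp_fix <- function(alpha_beta = 2.47)
  repair_params(alpha_beta, t_half_fast = 11.4, t_half_slow = 129.6,
                partition_c = 0.98)

# one-line plan constructor for single/few-shot fixtures
quick_plan <- function(collimator, x, y, z, rate, dur, gap = 0) {
  n <- length(x)
  gk_plan(data.frame(collimator_mm = rep_len(collimator, n),
                     x_mm = x, y_mm = y, z_mm = z,
                     dose_rate_gy_min = rep_len(rate, n),
                     duration_min = rep_len(dur, n),
                     gap_after_min = rep_len(gap, n)))
}

# random but seeded plan + dose vector for phi property tests
random_phi_case <- function(seed) {
  set.seed(seed)
  n <- sample(1:6, 1)
  plan <- quick_plan(8, runif(n, 90, 110), runif(n, 90, 110),
                     runif(n, 90, 110), runif(n, 1, 3),
                     runif(n, 0.5, 30), c(runif(max(n - 1, 0), 0, 60), 0)[1:n])
  list(timeline = build_timeline(plan),
       doses = runif(n, 0.1, 5),
       mu = sample(c(0.01, 0.1, 1, 5), 1))
}
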