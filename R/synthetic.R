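#' Simulate single-shot dose-falloff profile tables
#'
#' Emulates measured per-axis falloff curves (as TMR10 dosimetry or
#' radiochromic film would supply) for one collimator.  The truth curve
#' is a flattened-top Gaussian,
#' `f(t) = exp(-(max(|t| - s, 0) / w)^2)`, whose shoulder half-width `s`
#' makes single-term Gaussian fits imperfect so the multi-term fitting
#' machinery is genuinely exercised; `w` is set from the requested FWHM
#' (`FWHM = 2 s + 2 w sqrt(ln 2)`), so the generator's true FWHM is
#' known exactly and is recorded in the `true_fwhm` attribute of each
#' table.  Seeded Gaussian measurement noise is added, the sample at
#' offset 0 is pinned to 1 and values are clipped into `[0, 1.05]`.
#'
#' Default FWHM triples are fixture conventions near the nominal
#' collimator sizes (z narrowest, as z-profiles are in practice), not
#' measured machine values: 4 mm -> (6, 6, 4.8), 8 mm -> (11, 11, 9),
#' 14 mm -> (18, 18, 15.5), 18 mm -> (24, 24, 20) mm.
#'
#' @param collimator Collimator label (4, 8, 14 or 18).
#' @param fwhm Length-3 true FWHM (x, y, z) in mm; default per
#'   collimator as above.
#' @param shoulder Flat-top half-width as a fraction of FWHM/2 (0 =
#'   pure Gaussian).
#' @param noise_sd Measurement noise standard deviation (fraction of
#'   maximum), in `[0, 0.02]`.
#' @param spacing Sample spacing in mm.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and seed (Mersenne-Twister stream).
#' @return A named list of three [profile_table()]s (`x`, `y`, `z`),
#'   each carrying attributes `true_fwhm`, `shoulder_mm` and `seed`.
#' @export
sim_profile_tables <- function(collimator, fwhm = NULL, shoulder = 0.25,
                               noise_sd = 0.005, spacing = 0.5,
                               seed = 1L) {
  collimator <- match_collimator(collimator)
  if (is.null(fwhm)) fwhm <- default_fixture_fwhm(collimator)
  stopifnot(length(fwhm) == 3L, all(fwhm > 0))
  if (noise_sd < 0 || noise_sd > 0.02)
    stop("noise_sd must lie in [0, 0.02]", call. = FALSE)
  if (shoulder < 0 || shoulder >= 1)
    stop("shoulder must lie in [0, 1) (fraction of the half-width)",
         call. = FALSE)
  set.seed(as.integer(seed))
  out <- list()
  for (ax in 1:3) {
    s <- shoulder * fwhm[ax] / 2
    w <- (fwhm[ax] / 2 - s) / sqrt(log(2))
    ext <- spacing * ceiling((s + 3.2 * w) / spacing)
    off <- seq(-ext, ext, by = spacing)
    truth <- exp(-(pmax(abs(off) - s, 0) / w)^2)
    rd <- truth + stats::rnorm(length(off), sd = noise_sd)
    rd[off == 0] <- 1
    rd <- pmin(pmax(rd, 0), 1.05)
    tb <- profile_table(collimator, c("x", "y", "z")[ax], off, rd)
    attr(tb, "true_fwhm") <- fwhm[ax]
    attr(tb, "shoulder_mm") <- s
    attr(tb, "seed") <- as.integer(seed)
    out[[c("x", "y", "z")[ax]]] <- tb
  }
  out
}

default_fixture_fwhm <- function(collimator) {
  switch(as.character(collimator),
         "4" = c(6, 6, 4.8),
         "8" = c(11, 11, 9),
         "14" = c(18, 18, 15.5),
         "18" = c(24, 24, 20))
}

#' Simulate a randomized multi-shot plan
#'
#' Shots are drawn uniformly: isocenters inside the target extent box,
#' collimators from the supplied mix, dose rates, durations and gaps
#' from their ranges.  Delivery order is the randomized draw order,
#' then fixed.  A pure function of its arguments and seed.
#'
#' @param n_shots Number of shots (>= 1).
#' @param center Target centre, Leksell mm.
#' @param extent Half-extent of the target box per axis, mm.
#' @param collimators Collimator labels to draw from.
#' @param dose_rate_range Gy/min range.
#' @param duration_range Beam-on minutes range (> 0).
#' @param gap_range Inter-shot gap minutes range (>= 0).
#' @param seed Integer seed.
#' @param name Plan name.
#' @return A [gk_plan()].
#' @export
sim_plan <- function(n_shots = 5L, center = c(100, 100, 100),
                     extent = c(10, 10, 10),
                     collimators = c(4, 8, 14, 18),
                     dose_rate_range = c(1.5, 3.5),
                     duration_range = c(0.5, 30),
                     gap_range = c(0, 60),
                     seed = 1L, name = NULL) {
  stopifnot(n_shots >= 1L, all(extent > 0),
            all(duration_range > 0), all(gap_range >= 0),
            all(dose_rate_range > 0))
  set.seed(as.integer(seed))
  runifr <- function(n, r) stats::runif(n, r[1], r[2])
  shots <- data.frame(
    collimator_mm = sample(rep(collimators, length.out = max(n_shots,
                                                             length(collimators))),
                           n_shots),
    x_mm = runifr(n_shots, center[1] + c(-1, 1) * extent[1]),
    y_mm = runifr(n_shots, center[2] + c(-1, 1) * extent[2]),
    z_mm = runifr(n_shots, center[3] + c(-1, 1) * extent[3]),
    dose_rate_gy_min = runifr(n_shots, dose_rate_range),
    duration_min = runifr(n_shots, duration_range),
    gap_after_min = runifr(n_shots, gap_range))
  shots$gap_after_min[n_shots] <- 0
  gk_plan(shots, name = if (is.null(name)) sprintf("sim-plan-seed%d", seed)
          else name)
}

#' Ellipsoidal structure mask
#'
#' Voxelizes an analytic ellipsoid: a voxel belongs to the structure
#' iff its centre lies inside.
#'
#' @param center Ellipsoid centre, Leksell mm.
#' @param semiaxes Length-3 semiaxes, mm.
#' @param spec A [grid_spec()].
#' @param label Structure name.
#' @return A [structure_mask()].
#' @export
ellipsoid_mask <- function(center, semiaxes, spec = grid_spec(),
                           label = "target") {
  stopifnot(all(semiaxes > 0))
  co <- grid_coords(spec)
  a1 <- ((co - center[1]) / semiaxes[1])^2
  a2 <- ((co - center[2]) / semiaxes[2])^2
  a3 <- ((co - center[3]) / semiaxes[3])^2
  inside <- outer(outer(a1, a2, "+"), a3, "+") <= 1
  structure_mask(spec, inside, label = label)
}

#' Tubular (tract-like) structure mask
#'
#' Voxelizes a tube of given radius around a polyline, emulating an
#' elongated organ at risk such as a pyramidal tract whose length
#' exceeds 150 mm — the kind of structure that motivates a full-frame
#' 200-voxel calculation matrix.  The default centreline is a gentle
#' arc of about 165 mm running superior-inferior through the frame.
#'
#' @param control_points Polyline control points (m x 3, Leksell mm);
#'   `NULL` for the default tract fixture.
#' @param radius Tube radius, mm.
#' @param spec A [grid_spec()].
#' @param label Structure name.
#' @return A [structure_mask()] with attribute `centerline_length_mm`.
#' @export
tract_mask <- function(control_points = NULL, radius = 3,
                       spec = grid_spec(), label = "tract") {
  if (radius <= 0) stop("radius must be > 0 mm", call. = FALSE)
  if (is.null(control_points)) control_points <- default_tract_polyline()
  cp <- matrix(as.numeric(control_points), ncol = 3)
  co <- grid_coords(spec)
  lo_mm <- min(co); hi_mm <- max(co)
  if (any(cp < lo_mm) || any(cp > hi_mm))
    stop("tract polyline exits the calculation matrix", call. = FALSE)
  if (radius < spec$spacing / 2)
    warning("tube radius ", radius, " mm is below half the voxel spacing; ",
            "the mask may be empty")

  # densify the polyline so per-segment voxelization stays local
  seg_len <- sqrt(rowSums((cp[-1, , drop = FALSE] -
                             cp[-nrow(cp), , drop = FALSE])^2))
  total_len <- sum(seg_len)
  pts <- densify_polyline(cp, step = max(min(radius, 2), spec$spacing) / 2)

  n <- spec$n_per_axis
  vox <- array(FALSE, rep(n, 3L))
  n_seg <- nrow(pts) - 1L
  for (s in seq_len(n_seg)) {
    p <- pts[s, ]; q <- pts[s + 1L, ]
    rng <- lapply(1:3, function(ax) {
      which(co >= min(p[ax], q[ax]) - radius &
              co <= max(p[ax], q[ax]) + radius)
    })
    if (any(vapply(rng, length, 0L) == 0L)) next
    gx <- co[rng[[1]]]; gy <- co[rng[[2]]]; gz <- co[rng[[3]]]
    # the tube has flat ends: beyond the first/last segment nothing is
    # included; interior junctions are covered by adjacent segments
    d2 <- point_segment_dist2(gx, gy, gz, p, q,
                              cap_lo = s > 1L, cap_hi = s < n_seg)
    hit <- d2 <= radius^2
    vox[rng[[1]], rng[[2]], rng[[3]]] <-
      vox[rng[[1]], rng[[2]], rng[[3]]] | hit
  }
  out <- structure_mask(spec, vox, label = label)
  attr(out, "centerline_length_mm") <- total_len
  out
}

default_tract_polyline <- function() {
  z <- seq(20, 180, length.out = 17)           # 160 mm span plus curvature
  x <- 100 + 18 * sin((z - 20) / 160 * pi)
  y <- 90 + 0.08 * (z - 100)
  cbind(x, y, z)
}

densify_polyline <- function(cp, step) {
  out <- cp[1, , drop = FALSE]
  for (s in seq_len(nrow(cp) - 1L)) {
    p <- cp[s, ]; q <- cp[s + 1L, ]
    len <- sqrt(sum((q - p)^2))
    m <- max(1L, ceiling(len / step))
    tfrac <- seq_len(m) / m
    out <- rbind(out, outer(tfrac, q - p) + rep(p, each = m))
  }
  out
}

# squared distance from every voxel centre in the (gx, gy, gz) box to
# the segment p-q, returned as a 3-D array; with cap_lo/cap_hi FALSE the
# corresponding end is flat (points projecting beyond it are excluded)
point_segment_dist2 <- function(gx, gy, gz, p, q, cap_lo = TRUE,
                                cap_hi = TRUE) {
  d <- q - p
  dd <- sum(d^2)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  X <- array(gx, c(nx, ny, nz))
  Y <- array(rep(gy, each = nx), c(nx, ny, nz))
  Z <- array(rep(gz, each = nx * ny), c(nx, ny, nz))
  if (dd == 0) {
    return((X - p[1])^2 + (Y - p[2])^2 + (Z - p[3])^2)
  }
  tpar <- ((X - p[1]) * d[1] + (Y - p[2]) * d[2] + (Z - p[3]) * d[3]) / dd
  beyond_lo <- tpar < 0
  beyond_hi <- tpar > 1
  tpar[beyond_lo] <- 0
  tpar[beyond_hi] <- 1
  d2 <- (X - (p[1] + tpar * d[1]))^2 + (Y - (p[2] + tpar * d[2]))^2 +
    (Z - (p[3] + tpar * d[3]))^2
  if (!cap_lo) d2[beyond_lo] <- Inf
  if (!cap_hi) d2[beyond_hi] <- Inf
  d2
}
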