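#' Fit a full collimator falloff model from three axis profiles
#'
#' Collapses the per-axis falloff curves of one collimator into a single
#' radial profile over the ellipsoid-expansion coefficient `L`.  For a
#' grid of iso-dose levels the signed per-axis half-widths `a`, `b`, `c`
#' are read off each fitted axis model (negative on the left side, as
#' both sides of the falloff are used), each level is mapped to the
#' signed geometric mean `L = sign * (|a||b||c|)^(1/3)`, and the pooled
#' `(L, level)` cloud is fitted with the same Gaussian-sum machinery as
#' the axes.  The model records per-axis FWHM values and a truncation
#' radius `l_max` beyond which the relative dose is defined to be 0.
#'
#' `build_radial_profile()` is an alias kept for symmetry with the other
#' engine verbs.
#'
#' @param tables A list of three [profile_table()] objects for the same
#'   collimator (axes x, y, z, in any order, named or not).
#' @param max_terms,rmse_tol Passed to [fit_axis_profile()].
#' @param levels Iso-dose level grid used to build the `L` cloud.
#' @return An object of class `"collimator_model"`: a list with elements
#'   `collimator`, `fwhm` (named x/y/z, mm), `axis_models`,
#'   `radial_model` and `l_max` (mm).
#' @examples
#' tabs <- sim_profile_tables(8, noise_sd = 0)
#' cm <- fit_collimator(tabs)
#' cm
#' evaluate_profile(cm, c(0, cm$fwhm[["x"]] / 2))
#' @export
fit_collimator <- function(tables, max_terms = 4L, rmse_tol = 0.005,
                           levels = seq(0.95, 0.05, by = -0.05)) {
  stopifnot(length(tables) == 3L)
  axes <- vapply(tables, attr, "", "axis")
  if (!setequal(axes, c("x", "y", "z")))
    stop("need one profile table per axis x, y, z; got: ",
         paste(axes, collapse = ", "), call. = FALSE)
  tables <- tables[match(c("x", "y", "z"), axes)]
  labs <- vapply(tables, attr, 0, "collimator")
  if (length(unique(labs)) != 1L)
    stop("axis tables mix collimators: ", paste(labs, collapse = ", "),
         call. = FALSE)

  axis_models <- lapply(tables, fit_axis_profile,
                        max_terms = max_terms, rmse_tol = rmse_tol)
  names(axis_models) <- c("x", "y", "z")
  fw <- lapply(axis_models, compute_fwhm, details = TRUE)
  fwhm <- vapply(fw, `[[`, 0, "fwhm")

  # profile centre per axis: midpoint of the half-maximum crossings (the
  # argmax is ill-conditioned for flat-topped profiles)
  centre <- vapply(fw, function(f) (f$left + f$right) / 2, 0)

  # signed half-widths per level and side, read off the fitted axis
  # models; crossings extrapolated beyond the measured offset range do
  # not count, so axes whose level ranges fail to overlap error out
  span <- lapply(tables, function(tb) range(tb$offset_mm))
  cloud_L <- 0; cloud_p <- 1  # the shared peak point
  usable <- 0L
  for (lev in levels) {
    hw <- matrix(NA_real_, 3, 2)
    for (ax in 1:3) {
      h <- tryCatch(
        level_halfwidths(axis_models[[ax]], lev, centre[ax]),
        error = function(e) c(NA_real_, NA_real_))
      pos <- centre[ax] + h
      h[pos < span[[ax]][1] | pos > span[[ax]][2]] <- NA_real_
      hw[ax, ] <- h
    }
    if (any(is.na(hw))) next
    usable <- usable + 1L
    for (side in 1:2) {
      sgn <- if (side == 1) -1 else 1
      cloud_L <- c(cloud_L, sgn * prod(abs(hw[, side]))^(1 / 3))
      cloud_p <- c(cloud_p, lev)
    }
  }
  if (usable < 5L)
    stop("level-grid error: axes share only ", usable,
         " usable iso-dose levels; profiles do not overlap enough",
         call. = FALSE)

  ord <- order(cloud_L)
  pooled <- data.frame(offset_mm = cloud_L[ord], rel_dose = cloud_p[ord])
  class(pooled) <- c("profile_table", "data.frame")
  attr(pooled, "collimator") <- labs[1]
  attr(pooled, "axis") <- "x"  # axis label irrelevant for the radial fit
  radial <- fit_axis_profile(pooled, max_terms = max_terms,
                             rmse_tol = rmse_tol)

  structure(list(collimator = labs[1],
                 fwhm = fwhm,
                 axis_models = axis_models,
                 radial_model = radial,
                 l_max = find_l_max(radial, max(abs(cloud_L)))),
            class = "collimator_model")
}

#' @rdname fit_collimator
#' @export
build_radial_profile <- fit_collimator

# signed half-widths (left, right) of model at an iso-dose level,
# relative to the peak position; bisection between lattice brackets
level_halfwidths <- function(model, level, t_peak) {
  vapply(c(-1, 1), function(dir) {
    span <- max(abs(model$v)) + 8 * max(model$w)
    step <- max(min(model$w) / 8, span / 4096)
    lattice <- t_peak + dir * seq(0, span, by = step)
    vals <- predict(model, lattice)
    above <- vals >= level
    if (!above[1] || all(above))
      stop("level ", level, " not bracketed")
    k <- which(!above)[1] - 1L
    a <- lattice[k]; b <- lattice[k + 1L]
    while (abs(b - a) > 1e-7) {
      m <- (a + b) / 2
      if (predict(model, m) >= level) a <- m else b <- m
    }
    (a + b) / 2 - t_peak
  }, 0)
}

# smallest radius at which the fitted radial profile drops below 1e-3;
# beyond it the profile is truncated to exactly zero
find_l_max <- function(radial, data_span) {
  bound <- max(data_span * 2, max(abs(radial$v)) + 10 * max(radial$w))
  tt <- seq(0, bound, by = 0.01)
  vals <- predict(radial, tt)
  k <- which(vals < 0.001)
  if (!length(k)) return(bound)
  tt[k[1]]
}

#' Evaluate a collimator radial profile
#'
#' Relative dose fraction at radial coordinate `L >= 0`: the fitted
#' Gaussian sum clamped to `[0, 1]`, and exactly 0 beyond the truncation
#' radius `l_max` (Gaussian sums may re-rise outside the fitted range;
#' truncation plus clamping keeps extrapolation safe).
#'
#' @param model A `"collimator_model"` from [fit_collimator()].
#' @param L Numeric vector of non-negative radial coordinates (mm).
#' @return Relative dose fractions in `[0, 1]`, same length as `L`.
#' @export
evaluate_profile <- function(model, L) {
  stopifnot(inherits(model, "collimator_model"))
  if (any(L < 0))
    stop("evaluate_profile requires L >= 0 (the spatial mapping yields ",
         "non-negative L)", call. = FALSE)
  out <- predict(model$radial_model, L)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out[L > model$l_max] <- 0
  out
}

#' @export
print.collimator_model <- function(x, ...) {
  cat(sprintf("Collimator model: %g mm\n", x$collimator))
  cat(sprintf("  FWHM (x, y, z): %.3f, %.3f, %.3f mm\n",
              x$fwhm[["x"]], x$fwhm[["y"]], x$fwhm[["z"]]))
  cat(sprintf("  radial Gaussian sum: %d term(s), truncation l_max %.2f mm\n",
              x$radial_model$n_terms, x$l_max))
  invisible(x)
}

#' @export
coef.collimator_model <- function(object, ...) coef(object$radial_model)

#' @export
predict.collimator_model <- function(object, L, ...) evaluate_profile(object, L)

#' @export
plot.collimator_model <- function(x, ...,
                                  L = seq(0, x$l_max, length.out = 400)) {
  graphics::plot(L, evaluate_profile(x, L), type = "l",
                 xlab = "L (mm)", ylab = "relative dose",
                 main = sprintf("%g mm collimator radial falloff",
                                x$collimator), ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Serialize fitted collimator models to JSON
#'
#' Models serialise as
#' `{collimator, fwhm:{x,y,z}, radial:{n,u[],v[],w[]}, l_max}`.  Only the
#' radial model and FWHM triple are stored: that is all the dose and BED
#' engines consume.  Serialisation is deterministic, so identical models
#' write byte-identical files.
#'
#' @param models A single `"collimator_model"` or a list of them.
#' @param path Output JSON path.
#' @return `path`, invisibly (writer); a named list of models keyed by
#'   collimator label (reader).
#' @export
write_collimator_models <- function(models, path) {
  if (inherits(models, "collimator_model")) models <- list(models)
  payload <- lapply(models, function(m) {
    list(collimator = m$collimator,
         fwhm = as.list(m$fwhm),
         radial = list(n = m$radial_model$n_terms, u = m$radial_model$u,
                       v = m$radial_model$v, w = m$radial_model$w),
         l_max = m$l_max)
  })
  names(payload) <- vapply(models, function(m) as.character(m$collimator), "")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_collimator_models
#' @export
read_collimator_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(payload, function(p) {
    structure(list(collimator = match_collimator(p$collimator),
                   fwhm = c(x = p$fwhm$x, y = p$fwhm$y, z = p$fwhm$z),
                   axis_models = NULL,
                   radial_model = gaussian_sum(p$radial$u, p$radial$v,
                                               p$radial$w),
                   l_max = p$l_max),
              class = "collimator_model")
  })
  names(out) <- names(payload)
  out
}
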