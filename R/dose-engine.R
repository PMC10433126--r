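#' Ellipsoid-expansion coefficient
#'
#' Maps a 3D offset from an isocenter to the radial coordinate `L` of
#' the collimator falloff curve,
#' \deqn{L = (F_x F_y F_z)^{1/3}
#'   \sqrt{\frac{(x-x_i)^2}{F_x^2} + \frac{(y-y_i)^2}{F_y^2} +
#'         \frac{(z-z_i)^2}{F_z^2}},}
#' with `F` the per-axis FWHM values.  Surfaces of constant `L` are the
#' expanding iso-dose ellipsoids; `L` equals the radius of the sphere
#' with the same volume as the ellipsoid through the point, and reduces
#' to the Euclidean offset when the three FWHM are equal.
#'
#' @param point Numeric matrix (n x 3) or length-3 vector of Leksell
#'   coordinates (mm).
#' @param isocenter Length-3 isocenter coordinates (mm).
#' @param fwhm Length-3 positive FWHM values (mm), order x, y, z.
#' @return Non-negative `L` values (mm).
#' @export
ellipsoid_coefficient <- function(point, isocenter, fwhm) {
  if (any(fwhm <= 0)) stop("all FWHM values must be positive",
                           call. = FALSE)
  p <- matrix(as.numeric(point), ncol = 3)
  g <- prod(fwhm)^(1 / 3)
  s <- ((p[, 1] - isocenter[1]) / fwhm[1])^2 +
       ((p[, 2] - isocenter[2]) / fwhm[2])^2 +
       ((p[, 3] - isocenter[3]) / fwhm[3])^2
  unname(g * sqrt(s))
}

#' Half-maximum contour ellipsoid of one shot
#'
#' The contour of one shot is the iso-dose surface at half the maximum:
#' the ellipsoid centred on the isocenter with semiaxes `FWHM/2`, i.e.
#' the locus where `L / (F_x F_y F_z)^{1/3} = 1/2`.
#'
#' @param shot One row of a [gk_plan()] (data frame with the plan
#'   columns).
#' @param model The matching [fit_collimator()] model.
#' @return A list with `center` (mm), `semiaxes` (mm, x/y/z) and
#'   `volume_mm3`.
#' @export
shot_contour <- function(shot, model) {
  stopifnot(inherits(model, "collimator_model"))
  if (shot$collimator_mm != model$collimator)
    stop("collimator mismatch: shot uses ", shot$collimator_mm,
         " mm but model is for ", model$collimator, " mm", call. = FALSE)
  semi <- model$fwhm / 2
  list(center = c(shot$x_mm, shot$y_mm, shot$z_mm),
       semiaxes = semi,
       volume_mm3 = 4 / 3 * pi * prod(semi))
}

#' Per-shot dose field
#'
#' Physical dose of one shot on the calculation matrix:
#' `d_i(voxel) = dose_rate * duration * F_L(L(voxel))`.  Evaluation is
#' restricted to the bounding box of the `l_max` truncation ellipsoid —
#' voxels beyond it are exactly zero — and the field is returned
#' sparsely as that box; values are identical to a full-grid evaluation.
#'
#' @param shot One plan row.
#' @param model Matching [fit_collimator()] model.
#' @param spec A [grid_spec()].
#' @return An object of class `"shot_field"`: list with `ranges` (list
#'   of index ranges per axis), `values` (box array) and `spec`.  Use
#'   [expand_shot_field()] for the dense grid.
#' @export
shot_dose_field <- function(shot, model, spec) {
  stopifnot(inherits(model, "collimator_model"), inherits(spec, "grid_spec"))
  if (shot$collimator_mm != model$collimator)
    stop("collimator mismatch: shot uses ", shot$collimator_mm,
         " mm but model is for ", model$collimator, " mm", call. = FALSE)
  iso <- c(shot$x_mm, shot$y_mm, shot$z_mm)
  coords <- grid_coords(spec)
  extent <- range(coords)
  if (any(iso < extent[1] - spec$spacing / 2 |
            iso > extent[2] + spec$spacing / 2))
    warning("isocenter (", paste(round(iso, 2), collapse = ", "),
            ") mm lies outside the calculation matrix; ",
            "only the overlapping region is computed")
  g <- prod(model$fwhm)^(1 / 3)
  half <- model$fwhm * model$l_max / g  # box half-widths where L <= l_max
  ranges <- lapply(1:3, function(ax) {
    which(coords >= iso[ax] - half[ax] & coords <= iso[ax] + half[ax])
  })
  nb <- vapply(ranges, length, 0L)
  if (any(nb == 0L)) {
    return(structure(list(ranges = lapply(1:3, function(i) integer()),
                          values = array(numeric(0), c(0, 0, 0)),
                          spec = spec),
                     class = "shot_field"))
  }
  a1 <- ((coords[ranges[[1]]] - iso[1]) / model$fwhm[1])^2
  a2 <- ((coords[ranges[[2]]] - iso[2]) / model$fwhm[2])^2
  a3 <- ((coords[ranges[[3]]] - iso[3]) / model$fwhm[3])^2
  s <- outer(outer(a1, a2, "+"), a3, "+")
  L <- g * sqrt(s)
  vals <- shot$dose_rate_gy_min * shot$duration_min *
    evaluate_profile(model, as.numeric(L))
  structure(list(ranges = ranges,
                 values = array(vals, dim = nb),
                 spec = spec),
            class = "shot_field")
}

#' @rdname shot_dose_field
#' @param field A `"shot_field"`.
#' @export
expand_shot_field <- function(field) {
  out <- array(0, rep(field$spec$n_per_axis, 3L))
  if (length(field$values))
    out[field$ranges[[1]], field$ranges[[2]], field$ranges[[3]]] <-
      field$values
  out
}

#' Total physical dose of a plan
#'
#' Superposes the per-shot dose fields of all shots on the calculation
#' matrix.  With `keep_per_shot = TRUE` the sparse per-shot fields are
#' retained on the returned grid, as required by [compute_bed()].
#'
#' @param plan A [gk_plan()].
#' @param models Named list of [fit_collimator()] models keyed by
#'   collimator label (e.g. `"4"`, `"8"`, `"14"`, `"18"`).
#' @param spec A [grid_spec()].
#' @param keep_per_shot Retain sparse per-shot fields for BED
#'   computation.
#' @return A [dose_grid()] with `values = sum of the per-shot fields`.
#' @examples
#' tabs <- sim_profile_tables(8, noise_sd = 0)
#' cm <- fit_collimator(tabs)
#' plan <- sim_plan(n_shots = 2, seed = 1, collimators = 8)
#' dg <- accumulate_dose(plan, list("8" = cm), grid_spec(64, 2))
#' summary(dg)
#' @export
accumulate_dose <- function(plan, models, spec = grid_spec(),
                            keep_per_shot = FALSE) {
  validate_plan(plan)
  labs <- unique(plan$collimator_mm)
  missing <- setdiff(as.character(labs), names(models))
  if (length(missing))
    stop("no collimator model for label(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  total <- array(0, rep(spec$n_per_axis, 3L))
  fields <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    f <- shot_dose_field(plan[i, ], models[[as.character(plan$collimator_mm[i])]],
                         spec)
    if (length(f$values))
      total[f$ranges[[1]], f$ranges[[2]], f$ranges[[3]]] <-
        total[f$ranges[[1]], f$ranges[[2]], f$ranges[[3]]] + f$values
    fields[[i]] <- f
  }
  dose_grid(spec, total, per_shot = if (keep_per_shot) fields)
}
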