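#' Binary structure mask
#'
#' Target or organ-at-risk voxelization on the same calculation matrix
#' as the dose/BED grids (a voxel belongs to the structure iff its
#' centre lies inside the analytic shape; partial-volume weighting is
#' not modelled).
#'
#' @param spec A [grid_spec()], must match the companion grid.
#' @param voxels Logical (or 0/1) 3D array.
#' @param label Structure name.
#' @return An object of class `"structure_mask"`.
#' @export
structure_mask <- function(spec, voxels, label = "structure") {
  stopifnot(inherits(spec, "grid_spec"),
            identical(dim(voxels), rep(spec$n_per_axis, 3L)))
  structure(list(spec = spec, voxels = array(as.logical(voxels), dim(voxels)),
                 label = label),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("Structure mask '%s': %d voxel(s), %.1f mm^3\n",
              x$label, sum(x$voxels), mask_volume(x)))
  invisible(x)
}

#' Structure volume
#'
#' Volume by voxel counting: set voxels times `spacing^3`.
#'
#' @param mask A [structure_mask()].
#' @return Volume in mm^3 (0 with a warning for an empty mask).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  nv <- sum(mask$voxels)
  if (nv == 0L) warning("mask '", mask$label, "' is empty")
  nv * mask$spec$spacing^3
}

check_same_grid <- function(grid, mask) {
  if (!same_spec(grid$spec, mask$spec))
    stop("grid and mask are on different calculation matrices",
         call. = FALSE)
}

#' (BED-)dose-volume histogram
#'
#' Differential and cumulative volume histograms of the grid values
#' inside a structure.  Bins are half-open `[lo, hi)` from 0 to the
#' structure maximum; the cumulative curve follows the planning
#' convention, volume with value at-or-above each bin edge, so its
#' first entry is the full structure volume and the differential
#' volumes sum to it exactly.
#'
#' @param grid A `"dose_grid"` or `"bed_grid"`.
#' @param mask A [structure_mask()] on the same matrix.
#' @param bin_width Bin width in Gy (or Gy_\{alpha/beta\}); default
#'   0.5.
#' @return An object of class `"dvh"`: list with `bin_edges`,
#'   `differential_mm3` (per bin) and `cumulative_mm3` (per edge), plus
#'   `label` and `quantity`.
#' @export
dvh <- function(grid, mask, bin_width = 0.5) {
  check_same_grid(grid, mask)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  vals <- grid$values[mask$voxels]
  if (!length(vals)) stop("mask '", mask$label, "' is empty",
                          call. = FALSE)
  vox3 <- grid$spec$spacing^3
  n_bins <- floor(max(vals) / bin_width) + 1L
  edges <- bin_width * (0:n_bins)
  idx <- pmin(floor(vals / bin_width) + 1L, n_bins)  # [lo, hi) binning
  differential <- tabulate(idx, nbins = n_bins) * vox3
  cumulative <- vapply(edges, function(e) sum(vals >= e) * vox3, 0)
  structure(list(bin_edges = edges, differential_mm3 = differential,
                 cumulative_mm3 = cumulative, label = mask$label,
                 quantity = if (inherits(grid, "bed_grid")) "BED" else "dose"),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("%s-volume histogram for '%s': %d bins, volume %.1f mm^3\n",
              x$quantity, x$label, length(x$differential_mm3),
              x$cumulative_mm3[1]))
  cat(sprintf("  median %s %.2f, max edge %.2f\n", x$quantity,
              dvh_median(x), max(x$bin_edges)))
  invisible(x)
}

#' @export
plot.dvh <- function(x, type = c("cumulative", "differential"), ...) {
  type <- match.arg(type)
  if (type == "cumulative") {
    graphics::plot(x$bin_edges, x$cumulative_mm3, type = "s",
                   xlab = x$quantity, ylab = "volume (mm^3)",
                   main = paste("Cumulative", x$quantity, "VH:", x$label), ...)
  } else {
    mids <- x$bin_edges[-length(x$bin_edges)] + diff(x$bin_edges) / 2
    graphics::plot(mids, x$differential_mm3, type = "h",
                   xlab = x$quantity, ylab = "volume per bin (mm^3)",
                   main = paste("Differential", x$quantity, "VH:", x$label),
                   ...)
  }
  invisible(x)
}

# median dose/BED from the cumulative curve (edge where volume first
# drops below half); resolution is one bin width
dvh_median <- function(x) {
  half <- x$cumulative_mm3[1] / 2
  x$bin_edges[which(x$cumulative_mm3 <= half)[1]]
}

#' @rdname dvh
#' @param path CSV output path (columns `edge`, `differential_mm3`,
#'   `cumulative_mm3`; the differential column holds the volume of the
#'   bin starting at each edge, 0 for the last edge).
#' @export
write_dvh <- function(x, path) {
  stopifnot(inherits(x, "dvh"))
  df <- data.frame(edge = x$bin_edges,
                   differential_mm3 = c(x$differential_mm3, 0),
                   cumulative_mm3 = x$cumulative_mm3)
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Iso-level volume
#'
#' Volume of the whole-grid region with value at or above a level (the
#' "iso-dose volume" / "iso-BED volume").
#'
#' @param grid A `"dose_grid"` or `"bed_grid"`.
#' @param level Threshold (> 0), in the grid's units.
#' @return Volume in mm^3.
#' @export
isolevel_volume <- function(grid, level) {
  stopifnot(level > 0)
  sum(grid$values >= level) * grid$spec$spacing^3
}

#' Paddick conformity index
#'
#' `CI = TV_PIV^2 / (TV * PIV)` with `TV` the target volume, `PIV` the
#' prescription iso-level volume and `TV_PIV` their intersection: 1 for
#' perfect conformity, penalising both under-coverage and spill.
#'
#' @param grid A `"dose_grid"` or `"bed_grid"`.
#' @param mask Target [structure_mask()].
#' @param prescription_level Prescription value in the grid's units.
#' @return CI in `[0, 1]`.
#' @export
paddick_ci <- function(grid, mask, prescription_level) {
  check_same_grid(grid, mask)
  tv <- sum(mask$voxels)
  if (tv == 0L) stop("target mask is empty", call. = FALSE)
  piv_vox <- grid$values >= prescription_level
  piv <- sum(piv_vox)
  if (piv == 0L)
    stop("undefined conformity index: prescription iso-level volume is ",
         "empty at level ", prescription_level, call. = FALSE)
  both <- sum(piv_vox & mask$voxels)
  both^2 / (tv * piv)
}

#' Gradient index
#'
#' `GI = V(level/2) / V(level)`: the ratio of the half-prescription to
#' the prescription iso-level volume, measuring dose-falloff steepness
#' outside the prescription surface (>= 1 always; ~2.8 for a Gaussian
#' falloff prescribed at half maximum).
#'
#' @inheritParams isolevel_volume
#' @param prescription_level Prescription value (> 0).
#' @return GI (dimensionless, >= 1).
#' @export
gradient_index <- function(grid, prescription_level) {
  vp <- isolevel_volume(grid, prescription_level)
  if (vp == 0)
    stop("undefined gradient index: prescription iso-level volume is ",
         "empty at level ", prescription_level, call. = FALSE)
  isolevel_volume(grid, prescription_level / 2) / vp
}

#' Percentage structure volume at or above a level
#'
#' @inheritParams paddick_ci
#' @param level Threshold in the grid's units.
#' @return Percentage of the structure volume (0-100).
#' @export
percent_volume_at <- function(grid, mask, level) {
  check_same_grid(grid, mask)
  tv <- sum(mask$voxels)
  if (tv == 0L) stop("mask is empty", call. = FALSE)
  100 * sum(mask$voxels & grid$values >= level) / tv
}
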