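#' Calculation-matrix specification
#'
#' The default calculation matrix is 200 x 200 x 200 voxels at 1 mm
#' spacing, covering the Leksell frame volume.  Voxel `[i, j, k]`
#' (1-based) has its centre at Leksell coordinate
#' `(i, j, k) * spacing` mm, so with the defaults the frame reference
#' (100, 100, 100) — the central maximum of a centred shot — coincides
#' with a voxel centre and the sampled peak equals the true peak.  Dose
#' is evaluated at voxel centres (point sampling).
#'
#' @param n_per_axis Voxels per axis (>= 2).
#' @param spacing Voxel spacing in mm (> 0).
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(n_per_axis = 200L, spacing = 1) {
  n_per_axis <- as.integer(n_per_axis)
  if (n_per_axis < 2L) stop("n_per_axis must be >= 2", call. = FALSE)
  if (spacing <= 0) stop("spacing must be > 0 mm", call. = FALSE)
  structure(list(n_per_axis = n_per_axis, spacing = spacing),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Calculation matrix: %d^3 voxels, %g mm spacing\n",
              x$n_per_axis, x$spacing))
  invisible(x)
}

# voxel-centre coordinates along one axis (Leksell mm)
grid_coords <- function(spec) seq_len(spec$n_per_axis) * spec$spacing

same_spec <- function(a, b)
  a$n_per_axis == b$n_per_axis && isTRUE(all.equal(a$spacing, b$spacing))

#' Scalar field containers
#'
#' `dose_grid()` wraps a 3D array of absorbed dose (Gy) on a
#' [grid_spec()]; `bed_grid` objects (from [compute_bed()]) are the same
#' shape with values in Gy_\{alpha/beta\} plus the repair parameters
#' used.  Per-shot fields, when retained, are stored sparsely as
#' bounding boxes and reconstruct exactly.
#'
#' @param spec A [grid_spec()].
#' @param values 3D numeric array, dim `rep(spec$n_per_axis, 3)`,
#'   non-negative.
#' @param per_shot Optional list of sparse per-shot fields (class
#'   `"shot_field"`), as produced by [shot_dose_field()].
#' @return An object of class `"dose_grid"`.
#' @export
dose_grid <- function(spec, values, per_shot = NULL) {
  stopifnot(inherits(spec, "grid_spec"),
            identical(dim(values), rep(spec$n_per_axis, 3L)))
  if (any(values < 0)) stop("dose values must be non-negative",
                            call. = FALSE)
  structure(list(spec = spec, values = values, per_shot = per_shot),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  kind <- if (inherits(x, "bed_grid")) "BED" else "dose"
  mx <- which_max_voxel(x)
  cat(sprintf("%s grid: %d^3 voxels, %g mm spacing\n", kind,
              x$spec$n_per_axis, x$spec$spacing))
  cat(sprintf("  max %.3f %s at voxel centre (%g, %g, %g) mm\n",
              max(x$values), if (kind == "BED") "Gy_a/b" else "Gy",
              mx[1], mx[2], mx[3]))
  if (!is.null(x$per_shot))
    cat(sprintf("  per-shot fields retained: %d\n", length(x$per_shot)))
  invisible(x)
}

#' @export
summary.dose_grid <- function(object, ...) {
  v <- object$values
  out <- c(max = max(v), mean = mean(v),
           nonzero_mm3 = sum(v > 0) * object$spec$spacing^3)
  out
}

# Leksell coordinates (mm) of the voxel centre holding the grid maximum
which_max_voxel <- function(grid) {
  idx <- arrayInd(which.max(grid$values), dim(grid$values))
  as.numeric(idx) * grid$spec$spacing
}

#' Trilinear interpolation of a grid field
#'
#' @param grid A `"dose_grid"` (or `"bed_grid"`).
#' @param points Numeric matrix (n x 3) of Leksell coordinates in mm.
#' @return Interpolated values; points outside the voxel-centre hull
#'   return `NA`.
#' @export
interp_grid <- function(grid, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  sp <- grid$spec$spacing
  n <- grid$spec$n_per_axis
  f <- points / sp            # fractional 1-based index
  i0 <- floor(f)
  t <- f - i0
  out <- rep(NA_real_, nrow(points))
  ok <- apply(i0 >= 1 & i0 <= n - 1, 1, all)
  for (r in which(ok)) {
    i <- i0[r, 1]; j <- i0[r, 2]; k <- i0[r, 3]
    tx <- t[r, 1]; ty <- t[r, 2]; tz <- t[r, 3]
    v <- grid$values
    c00 <- v[i, j, k] * (1 - tx) + v[i + 1, j, k] * tx
    c10 <- v[i, j + 1, k] * (1 - tx) + v[i + 1, j + 1, k] * tx
    c01 <- v[i, j, k + 1] * (1 - tx) + v[i + 1, j, k + 1] * tx
    c11 <- v[i, j + 1, k + 1] * (1 - tx) + v[i + 1, j + 1, k + 1] * tx
    out[r] <- (c00 * (1 - ty) + c10 * ty) * (1 - tz) +
      (c01 * (1 - ty) + c11 * ty) * tz
  }
  out
}

#' NRRD read/write for scalar grids
#'
#' Minimal NRRD support sufficient for the package's grids: 3-D
#' `double`/`float`/`uint8` data, `raw` (little-endian) or `text`
#' encoding, `spacings` recorded in mm.  A JSON sidecar
#' (`<path>.json`) carries provenance (seed, config hash, package
#' version) when written through [run_pipeline()].
#'
#' @param grid A `"dose_grid"`/`"bed_grid"`, or for masks any object
#'   with `spec` and `values`.
#' @param path Output `.nrrd` path.
#' @param encoding `"raw"` or `"text"`.
#' @return `write_nrrd()` returns `path` invisibly; `read_nrrd()`
#'   returns a `"dose_grid"`.
#' @export
write_nrrd <- function(grid, path, encoding = c("raw", "text")) {
  encoding <- match.arg(encoding)
  n <- grid$spec$n_per_axis
  sp <- grid$spec$spacing
  hdr <- c("NRRD0004",
           "# bed3d scalar grid",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %d %d %d", n, n, n),
           sprintf("spacings: %.17g %.17g %.17g", sp, sp, sp),
           sprintf("encoding: %s", encoding),
           if (encoding == "raw") "endian: little",
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.numeric(grid$values), con, size = 8, endian = "little")
  } else {
    writeLines(sprintf("%.17g", as.numeric(grid$values)), con)
  }
  invisible(path)
}

#' @rdname write_nrrd
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || line == "") break
    hdr <- c(hdr, line)
  }
  get_field <- function(key) {
    hit <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^", key, ": "), "", hit[1])
  }
  if (!grepl("^NRRD", hdr[1])) stop("not an NRRD file: ", path,
                                    call. = FALSE)
  sizes <- as.integer(strsplit(get_field("sizes"), " +")[[1]])
  if (length(sizes) != 3 || length(unique(sizes)) != 1)
    stop("only cubic 3-D NRRD grids are supported", call. = FALSE)
  spacing <- as.numeric(strsplit(get_field("spacings"), " +")[[1]])[1]
  type <- get_field("type")
  enc <- get_field("encoding")
  nvox <- prod(sizes)
  vals <- if (enc == "raw") {
    size <- switch(type, double = 8, float = 4, uchar = 1, uint8 = 1,
                   stop("unsupported NRRD type: ", type, call. = FALSE))
    what <- if (size == 1) "integer" else "numeric"
    readBin(con, what, n = nvox, size = size, endian = "little",
            signed = size > 1)
  } else if (enc %in% c("text", "txt", "ascii")) {
    as.numeric(scan(con, what = double(), n = nvox, quiet = TRUE))
  } else stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  dose_grid(grid_spec(sizes[1], spacing), array(as.numeric(vals), sizes))
}
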