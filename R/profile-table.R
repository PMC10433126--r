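#' Single-shot dose-falloff profile table
#'
#' A `profile_table` holds one measured (or simulated) single-shot
#' dose-falloff curve along one frame axis: signed offsets from the profile
#' centre in mm against relative dose as a fraction of the maximum
#' (1.0 = peak).  Relative dose is stored as a fraction throughout the
#' package; percent appears only at I/O boundaries.
#'
#' @param collimator Collimator label, one of 4, 8, 14, 18 (nominal mm).
#' @param axis Axis label, one of `"x"`, `"y"`, `"z"`.
#' @param offset_mm Numeric vector of signed offsets from the profile
#'   centre, strictly increasing, spanning both sides of 0.
#' @param rel_dose Relative dose fraction at each offset, in `[0, 1.05]`
#'   (a small measurement overshoot above 1 is tolerated).
#'
#' @return A data frame of class `"profile_table"` with columns
#'   `offset_mm` and `rel_dose` and attributes `collimator` and `axis`.
#' @seealso [fit_axis_profile()], [sim_profile_tables()]
#' @export
profile_table <- function(collimator, axis, offset_mm, rel_dose) {
  collimator <- match_collimator(collimator)
  axis <- match.arg(as.character(axis), c("x", "y", "z"))
  stopifnot(length(offset_mm) == length(rel_dose))
  out <- data.frame(offset_mm = as.numeric(offset_mm),
                    rel_dose = as.numeric(rel_dose))
  attr(out, "collimator") <- collimator
  attr(out, "axis") <- axis
  class(out) <- c("profile_table", "data.frame")
  validate_profile_table(out)
  out
}

match_collimator <- function(label) {
  lab <- as.numeric(label)
  if (length(lab) != 1L || is.na(lab) || !lab %in% c(4, 8, 14, 18))
    stop("collimator label must be one of 4, 8, 14, 18 (mm), got: ",
         deparse(label), call. = FALSE)
  lab
}

validate_profile_table <- function(x) {
  off <- x$offset_mm
  rd <- x$rel_dose
  if (any(!is.finite(off)) || any(!is.finite(rd)))
    stop("profile table contains non-finite values", call. = FALSE)
  if (any(diff(off) <= 0))
    stop("profile offsets must be strictly increasing", call. = FALSE)
  if (min(off) >= 0 || max(off) <= 0)
    stop("profile must cover both sides of offset 0", call. = FALSE)
  if (any(rd < 0) || any(rd > 1.05))
    stop("relative dose must lie in [0, 1.05] (fraction of maximum)",
         call. = FALSE)
  # the peak sample must sit near the profile centre
  near0 <- abs(off) <= 2 * stats::median(diff(off))
  if (!any(rd[near0] >= 0.99))
    stop("no sample with relative dose >= 0.99 near offset 0; ",
         "profile is not centred or not peak-normalised", call. = FALSE)
  invisible(x)
}

#' @export
print.profile_table <- function(x, ...) {
  cat(sprintf("Dose-falloff profile: %g mm collimator, %s axis\n",
              attr(x, "collimator"), attr(x, "axis")))
  cat(sprintf("  %d samples, offsets %.2f .. %.2f mm, peak %.4f\n",
              nrow(x), min(x$offset_mm), max(x$offset_mm), max(x$rel_dose)))
  invisible(x)
}

#' Read and write dose-profile tables
#'
#' Profile CSVs carry one collimator per file with columns
#' `collimator_mm`, `axis`, `offset_mm`, `rel_dose` (header required,
#' UTF-8).  `read_profile_tables()` returns a named list of
#' [profile_table()] objects keyed by axis.
#'
#' @param path CSV file path.
#' @return For `read_profile_tables()`, a list with elements `x`, `y`,
#'   `z`; for `write_profile_tables()`, `path`, invisibly.
#' @export
read_profile_tables <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("cannot parse profile CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("collimator_mm", "axis", "offset_mm", "rel_dose")
  if (!all(need %in% names(df)))
    stop("profile CSV '", path, "' must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$offset_mm))) |
                 !is.finite(suppressWarnings(as.numeric(df$rel_dose))))
  if (length(bad))
    stop("profile CSV '", path, "': unparseable numeric value at data row ",
         bad[1], " (file line ", bad[1] + 1L, ")", call. = FALSE)
  lab <- unique(df$collimator_mm)
  if (length(lab) != 1L)
    stop("profile CSV '", path, "' mixes collimators: ",
         paste(lab, collapse = ", "), call. = FALSE)
  out <- lapply(c(x = "x", y = "y", z = "z"), function(ax) {
    sub <- df[df$axis == ax, , drop = FALSE]
    if (!nrow(sub))
      stop("profile CSV '", path, "' is missing axis '", ax, "'",
           call. = FALSE)
    sub <- sub[order(sub$offset_mm), , drop = FALSE]
    profile_table(lab, ax, sub$offset_mm, sub$rel_dose)
  })
  out
}

#' @rdname read_profile_tables
#' @param tables A list of three [profile_table()] objects (axes x, y, z)
#'   for one collimator.
#' @export
write_profile_tables <- function(tables, path) {
  rows <- do.call(rbind, lapply(tables, function(tb) {
    data.frame(collimator_mm = attr(tb, "collimator"),
               axis = attr(tb, "axis"),
               offset_mm = tb$offset_mm,
               rel_dose = tb$rel_dose)
  }))
  utils::write.csv(format_num_df(rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# full-precision numeric formatting so CSV round trips to 1e-12
format_num_df <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  df
}
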