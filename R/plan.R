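#' Multi-isocenter treatment plan
#'
#' A `gk_plan` is an ordered table of shots; delivery order is row order.
#' Each shot carries its collimator label, isocenter Leksell coordinates
#' (mm), dose rate at the profile maximum (Gy/min), beam-on duration
#' (min) and the gap before the next shot (min).  Durations must be
#' strictly positive (the interaction factor divides by them); users
#' wanting effectively acute shots should use short durations, whose
#' limiting behaviour is exact.
#'
#' @param shots A data frame with columns `collimator_mm`, `x_mm`,
#'   `y_mm`, `z_mm`, `dose_rate_gy_min`, `duration_min`,
#'   `gap_after_min` (a `shot_index` column is accepted and used to
#'   check ordering).
#' @param name Plan identifier.
#' @return A data frame of class `"gk_plan"`.
#' @export
gk_plan <- function(shots, name = "plan") {
  need <- c("collimator_mm", "x_mm", "y_mm", "z_mm",
            "dose_rate_gy_min", "duration_min", "gap_after_min")
  if (!all(need %in% names(shots)))
    stop("plan must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if ("shot_index" %in% names(shots)) {
    if (any(shots$shot_index != seq_len(nrow(shots))))
      shots <- shots[order(shots$shot_index), , drop = FALSE]
  }
  shots <- as.data.frame(shots)[, need]
  shots <- cbind(shot_index = seq_len(nrow(shots)), shots)
  rownames(shots) <- NULL
  attr(shots, "name") <- name
  class(shots) <- c("gk_plan", "data.frame")
  validate_plan(shots)
  shots
}

validate_plan <- function(plan) {
  if (nrow(plan) < 1L) stop("plan must contain at least one shot",
                            call. = FALSE)
  for (lab in plan$collimator_mm) match_collimator(lab)
  if (any(plan$duration_min <= 0))
    stop("shot durations must be > 0 min", call. = FALSE)
  if (any(plan$dose_rate_gy_min <= 0))
    stop("shot dose rates must be > 0 Gy/min", call. = FALSE)
  if (any(plan$gap_after_min < 0))
    stop("inter-shot gaps must be >= 0 min", call. = FALSE)
  xyz <- as.matrix(plan[, c("x_mm", "y_mm", "z_mm")])
  if (any(!is.finite(xyz)) || any(xyz < 0) || any(xyz > 200))
    stop("isocenters must lie within the Leksell frame box [0, 200] mm",
         call. = FALSE)
  invisible(plan)
}

#' @export
print.gk_plan <- function(x, ...) {
  cat(sprintf("Treatment plan '%s': %d shot(s), total beam-on %.2f min\n",
              attr(x, "name"), nrow(x), sum(x$duration_min)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read and write plans
#'
#' Plans round-trip as CSV or JSON with identical field names
#' (`shot_index`, `collimator_mm`, `x_mm`, `y_mm`, `z_mm`,
#' `dose_rate_gy_min`, `duration_min`, `gap_after_min`); the format is
#' chosen from the file extension.  Floating-point values survive the
#' round trip to 1e-12.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @param plan A [gk_plan()].
#' @return `read_plan()` returns a [gk_plan()]; `write_plan()` returns
#'   `path` invisibly.
#' @export
read_plan <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    nm <- if (is.null(obj$name)) "plan" else obj$name
    shots <- if (is.data.frame(obj)) obj else as.data.frame(obj$shots)
    gk_plan(shots, name = nm)
  } else {
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) stop("cannot parse plan CSV '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
    gk_plan(df, name = sub("\\.[^.]*$", "", basename(path)))
  }
}

#' @rdname read_plan
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "gk_plan"))
  df <- as.data.frame(plan)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(name = attr(plan, "name"), shots = df),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(format_num_df(df), path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}
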