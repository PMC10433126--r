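#' Fit collimator models for every profile CSV in a directory
#'
#' Reads each `*.csv` profile table in `profiles_dir` (one collimator
#' per file, axes x/y/z), fits the per-axis and radial models and
#' serializes them to one JSON file.  Per-collimator FWHM values and
#' fit RMSE are reported via `message()`.  Re-running on identical
#' input produces a byte-identical JSON file.
#'
#' @param profiles_dir Directory of profile CSVs.
#' @param out_model_file Output JSON path.
#' @param max_terms,rmse_tol Passed to [fit_collimator()].
#' @return Named list of `"collimator_model"`s, invisibly.
#' @export
fit_profiles_dir <- function(profiles_dir, out_model_file,
                             max_terms = 4L, rmse_tol = 0.005) {
  files <- list.files(profiles_dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files))
    stop("no profile CSVs found in '", profiles_dir, "'", call. = FALSE)
  models <- list()
  for (f in sort(files)) {
    tabs <- read_profile_tables(f)
    cm <- fit_collimator(tabs, max_terms = max_terms, rmse_tol = rmse_tol)
    models[[as.character(cm$collimator)]] <- cm
    message(sprintf(
      "collimator %g mm: FWHM (%.3f, %.3f, %.3f) mm, radial RMSE %.2e",
      cm$collimator, cm$fwhm[["x"]], cm$fwhm[["y"]], cm$fwhm[["z"]],
      cm$radial_model$rmse))
  }
  write_collimator_models(models, out_model_file)
  invisible(models)
}

#' Run configuration for the full analysis pipeline
#'
#' Bundles the paths and parameters of a fit -> dose -> BED -> metrics
#' run.  All referenced input paths must exist at validation time.
#'
#' @param plan_file Plan CSV/JSON path.
#' @param model_file Fitted collimator-model JSON (from
#'   [fit_profiles_dir()]).
#' @param repair_file Radiobiology config JSON (see
#'   [read_repair_params()]).
#' @param out_dir Output directory (created if absent).
#' @param masks Named list of [structure_mask()] objects (may be
#'   empty).
#' @param grid A [grid_spec()].
#' @param bin_width DVH bin width (Gy).
#' @param prescription_level Prescription level (Gy for dose metrics;
#'   the same BED grid level is also reported) or `NULL` to use 50% of
#'   the dose maximum.
#' @param seed Integer seed recorded in every output sidecar.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(plan_file, model_file, repair_file, out_dir,
                       masks = list(), grid = grid_spec(),
                       bin_width = 0.5, prescription_level = NULL,
                       seed = 1L) {
  for (p in c(plan_file, model_file, repair_file))
    if (!file.exists(p)) stop("input path does not exist: ", p,
                              call. = FALSE)
  structure(list(plan_file = plan_file, model_file = model_file,
                 repair_file = repair_file, out_dir = out_dir,
                 masks = masks, grid = grid, bin_width = bin_width,
                 prescription_level = prescription_level,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full dose -> BED -> metrics pipeline
#'
#' Executes [accumulate_dose()] (retaining per-shot fields),
#' [build_timeline()], [compute_bed()], and per-mask [dvh()] and plan
#' metrics; writes `dose.nrrd`, `bed.nrrd`, one DVH CSV per mask and
#' quantity, and `metrics.json` (CI, GI, percent-volume entries,
#' volumes, and an echo of the configuration).  Every output carries a
#' JSON sidecar with the config hash, seed and package version, so two
#' runs with equal hashes are bit-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the dose grid, BED grid, histograms
#'   and metrics.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.2f s", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }
  plan <- stage("read-plan", read_plan(config$plan_file))
  models <- stage("read-models", read_collimator_models(config$model_file))
  params <- stage("read-repair", read_repair_params(config$repair_file))
  dose <- stage("dose", accumulate_dose(plan, models, config$grid,
                                        keep_per_shot = TRUE))
  timeline <- build_timeline(plan)
  bed <- stage("bed", compute_bed(dose, timeline, params))

  hash <- config_hash(config, plan)
  side <- function(path, extra = list()) {
    payload <- c(list(config_hash = hash, seed = config$seed,
                      package = "bed3d",
                      version = as.character(utils::packageVersion("bed3d")),
                      format_version = 1L),
                 extra)
    jsonlite::write_json(payload, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  dose_path <- file.path(config$out_dir, "dose.nrrd")
  bed_path <- file.path(config$out_dir, "bed.nrrd")
  stage("write-grids", {
    dose_out <- dose; dose_out$per_shot <- NULL
    write_nrrd(dose_out, dose_path); side(dose_path)
    write_nrrd(bed, bed_path)
    side(bed_path, list(alpha_beta_gy = params$alpha_beta,
                        mu_fast_per_min = params$mu_fast,
                        mu_slow_per_min = params$mu_slow,
                        partition_c = params$partition_c))
  })

  level <- if (is.null(config$prescription_level)) max(dose$values) / 2
           else config$prescription_level
  hists <- list()
  metrics <- list()
  stage("metrics", {
    for (lab in names(config$masks)) {
      mask <- config$masks[[lab]]
      h_dose <- dvh(dose, mask, config$bin_width)
      h_bed <- dvh(bed, mask, config$bin_width)
      hists[[paste0(lab, "_dose")]] <- h_dose
      hists[[paste0(lab, "_bed")]] <- h_bed
      p_dose <- file.path(config$out_dir, sprintf("dvh_%s_dose.csv", lab))
      p_bed <- file.path(config$out_dir, sprintf("dvh_%s_bed.csv", lab))
      write_dvh(h_dose, p_dose); side(p_dose)
      write_dvh(h_bed, p_bed); side(p_bed)
      metrics[[lab]] <- list(
        volume_mm3 = mask_volume(mask),
        prescription_level_gy = level,
        conformity_index = paddick_ci(dose, mask, level),
        gradient_index = gradient_index(dose, level),
        percent_volume_at_prescription = percent_volume_at(dose, mask,
                                                           level),
        isolevel_volume_mm3 = isolevel_volume(dose, level),
        bed_isolevel_volume_mm3 = isolevel_volume(bed, level),
        percent_volume_bed_at_prescription = percent_volume_at(bed, mask,
                                                               level))
    }
  })
  metrics_path <- file.path(config$out_dir, "metrics.json")
  jsonlite::write_json(
    list(metrics = metrics,
         config = list(plan_file = config$plan_file,
                       model_file = config$model_file,
                       repair_file = config$repair_file,
                       grid = list(n_per_axis = config$grid$n_per_axis,
                                   spacing = config$grid$spacing),
                       bin_width = config$bin_width,
                       prescription_level = level,
                       seed = config$seed),
         config_hash = hash),
    metrics_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  side(metrics_path)
  invisible(list(dose = dose, bed = bed, histograms = hists,
                 metrics = metrics))
}

# deterministic md5 of the configuration + plan content
config_hash <- function(config, plan) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(
    list(plan = as.data.frame(plan),
         grid = list(n = config$grid$n_per_axis, s = config$grid$spacing),
         bin_width = config$bin_width,
         prescription_level = config$prescription_level,
         seed = config$seed,
         masks = lapply(config$masks, function(m)
           c(label = m$label, n = sum(m$voxels)))),
    tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
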