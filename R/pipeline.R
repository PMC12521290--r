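#' Pipeline run configuration
#'
#' Bundles every knob of a full generate / position / measure / analyze
#' run. Thresholds default to the protocol values (1 / 2 / 3 mm criteria,
#' 0.2 mm contact).
#'
#' @param seed integer seed driving all randomness.
#' @param out_dir output directory for run artifacts.
#' @param n optional cap on cohort size (first `n` subjects of the spec).
#' @param cohort_spec a cohort specification data frame.
#' @param plate a [plate_params()] family definition.
#' @param thresholds from [fit_thresholds()].
#' @param contact_tol contact distance, mm.
#' @param write_meshes write bone meshes + landmark sidecars (PLY/JSON).
#' @param mesh_format `"ply"` or `"stl"`.
#' @param resolution mesh resolution, mm.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = "platefit_run", n = NULL,
                       cohort_spec = default_cohort_spec(),
                       plate = plate_params(),
                       thresholds = fit_thresholds(), contact_tol = 0.2,
                       write_meshes = TRUE, mesh_format = c("ply", "stl"),
                       resolution = 1.0) {
  mesh_format <- match.arg(mesh_format)
  structure(list(seed = as.integer(seed), out_dir = out_dir, n = n,
                 cohort_spec = cohort_spec, plate = plate,
                 thresholds = thresholds, contact_tol = contact_tol,
                 write_meshes = write_meshes, mesh_format = mesh_format,
                 resolution = resolution),
            class = "run_config")
}

log_line <- function(path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", file = path, append = TRUE, sep = "")
  message(msg)
}

#' Run the full plate-fit pipeline
#'
#' Generates the synthetic cohort, measures every bone's bow radius,
#' selects and positions plates, measures fit, and writes all stage
#' artifacts (meshes, per-bone JSON reports, long-format distance CSV,
#' summary tables, manifest and log) under `config$out_dir`. Fully
#' deterministic under the configured seed. Bones that cannot be plated
#' are logged and excluded; the run continues.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `cohort`, `fit` (from
#'   [cohort_fit_run()]), `roc` (per-bone radii) and `tables`.
#' @export
run_pipeline <- function(config = run_config()) {
  out <- config$out_dir
  dir.create(file.path(out, "meshes"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "reports"), showWarnings = FALSE)
  dir.create(file.path(out, "tables"), showWarnings = FALSE)
  log <- file.path(out, "run.log")
  cat("", file = log)

  log_line(log, "sampling cohort (seed ", config$seed, ")")
  cohort <- sample_cohort(config$cohort_spec, seed = config$seed,
                          mesh = TRUE, resolution = config$resolution)
  if (!is.null(config$n)) {
    keep <- seq_len(min(config$n, nrow(cohort$metadata)))
    cohort$metadata <- cohort$metadata[keep, , drop = FALSE]
    cohort$params <- cohort$params[keep]
    cohort$femora <- cohort$femora[keep]
  }
  write.csv(cohort$metadata, file.path(out, "cohort.csv"), row.names = FALSE)

  if (config$write_meshes) {
    log_line(log, "writing ", length(cohort$femora), " bone meshes")
    for (bone in cohort$femora)
      write_femur(bone, file.path(out, "meshes"), format = config$mesh_format)
  }

  log_line(log, "measuring bow radii")
  roc <- do.call(rbind, lapply(cohort$femora, function(bone) {
    r <- measure_bone_roc(bone)
    data.frame(id = bone$id, radius_mm = r$radius, rms_mm = r$rms,
               stringsAsFactors = FALSE)
  }))
  rownames(roc) <- NULL
  write.csv(roc, file.path(out, "roc.csv"), row.names = FALSE)

  log_line(log, "positioning plates and measuring fit")
  fit <- cohort_fit_run(cohort, plate_base = config$plate,
                        config = position_config(contact_tol = config$contact_tol),
                        thresholds = config$thresholds)
  if (!is.null(fit$points))
    write.csv(fit$points, file.path(out, "distances.csv"), row.names = FALSE)
  if (nrow(fit$excluded) > 0) {
    write.csv(fit$excluded, file.path(out, "excluded.csv"), row.names = FALSE)
    for (k in seq_len(nrow(fit$excluded)))
      log_line(log, "excluded ", fit$excluded$id[k], ": ",
               fit$excluded$reason[k])
  }
  for (id in names(fit$reports))
    write_fit_report(fit$reports[[id]],
                     file.path(out, "reports", paste0("fit_", id, ".json")))

  log_line(log, "building tables")
  md <- merge(cohort$metadata, roc, by = "id", all.x = TRUE)
  md$roc_mm <- md$radius_mm
  tables <- make_tables(md, fit$summary)
  table_files <- c(descriptive = "table1_descriptive.csv",
                   descriptive_tests = "table2_descriptive_tests.csv",
                   fit = "table3_fit.csv",
                   fit_tests = "table4_fit_tests.csv")
  for (nm in names(tables))
    write.csv(tables[[nm]], file.path(out, "tables", table_files[[nm]]),
              row.names = FALSE)

  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(list(
    seed = config$seed, n = config$n, resolution = config$resolution,
    contact_tol = config$contact_tol,
    thresholds = as.list(config$thresholds),
    plate = list(holes = config$plate$holes, pitch = config$plate$pitch,
                 bow_radius = config$plate$bow_radius),
    cohort_spec = lapply(seq_len(nrow(config$cohort_spec)), function(i)
      as.list(config$cohort_spec[i, ]))), cfg_path)
  manifest <- list(
    package = "platefit",
    version = as.character(utils::packageVersion("platefit")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_bones = nrow(cohort$metadata),
    n_fitted = if (is.null(fit$summary)) 0L else nrow(fit$summary),
    n_excluded = nrow(fit$excluded),
    files = list.files(out, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line(log, "done: ", manifest$n_fitted, "/", manifest$n_bones,
           " bones fitted")
  invisible(list(cohort = cohort, fit = fit, roc = roc, tables = tables))
}
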