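#' Pipeline run configuration
#'
#' Bundles input paths, segmentation parameters, and output options for an
#' end-to-end run. All parameter defaults are the published workflow
#' values.
#'
#' @param volume_path Path to the attenuation volume (NIfTI file or TIFF
#'   stack directory).
#' @param contours_path Path to the outer-contour file
#'   (see [read_contours()]).
#' @param output_dir Directory for all outputs (created if missing).
#' @param params A [seg_params()].
#' @param units_scale,voxel_size_override Passed to [read_volume()].
#' @param lumen_add_path,lumen_remove_path Optional mask files with manual
#'   lumen edits (voxel patches to add/remove).
#' @param save_intermediates Write draft masks alongside the final ones.
#' @param slice_range Optional 1-based `c(first, last)` axial range for the
#'   per-slice metrics.
#' @return An object of class `run_config`.
#' @export
run_config <- function(volume_path, contours_path, output_dir,
                       params = seg_params(), units_scale = 1,
                       voxel_size_override = NULL,
                       lumen_add_path = NULL, lumen_remove_path = NULL,
                       save_intermediates = FALSE, slice_range = NULL) {
  structure(list(volume_path = volume_path, contours_path = contours_path,
                 output_dir = output_dir, params = params,
                 units_scale = units_scale,
                 voxel_size_override = voxel_size_override,
                 lumen_add_path = lumen_add_path,
                 lumen_remove_path = lumen_remove_path,
                 save_intermediates = isTRUE(save_intermediates),
                 slice_range = slice_range),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; segmentation
#' parameters live under `params` and default to the published values when
#' omitted.
#'
#' @param path YAML config path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    am_stop(sprintf("config file does not exist: %s", path), "am_io_error")
  y <- yaml::read_yaml(path)
  for (key in c("volume_path", "contours_path", "output_dir"))
    if (is.null(y[[key]]))
      am_stop(sprintf("config is missing required key '%s'", key),
              "am_config_error")
  params <- do.call(seg_params, if (is.null(y$params)) list() else y$params)
  run_config(volume_path = y$volume_path, contours_path = y$contours_path,
             output_dir = y$output_dir, params = params,
             units_scale = if (is.null(y$units_scale)) 1 else y$units_scale,
             voxel_size_override = y$voxel_size_override,
             lumen_add_path = y$lumen_add_path,
             lumen_remove_path = y$lumen_remove_path,
             save_intermediates = isTRUE(y$save_intermediates),
             slice_range = if (is.null(y$slice_range)) NULL
                           else as.numeric(y$slice_range))
}

#' Run the full segmentation and quantification pipeline
#'
#' Executes the five workflow steps end to end: ROI interpolation from the
#' manual contours, wall/lumen segmentation, optional manual lumen edits,
#' plaque/lesion segmentation, and quantification. Writes the masks, the
#' concatenated label volume, lumen/lesion meshes, the CSV report, and a
#' JSON run manifest recording every parameter and the MD5 checksums of the
#' inputs. The pipeline has no stochastic step: reruns on identical inputs
#' produce byte-identical reports.
#'
#' @param config A [run_config()] or path to a YAML config.
#' @return List with `wall_lumen`, `plaque`, `report` (invisibly also
#'   written to `output_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config"))
    am_stop("`config` must be a run_config or a YAML path", "am_value_error")

  # validate inputs before any computation
  if (!file.exists(config$volume_path))
    am_stop(sprintf("volume not found: %s", config$volume_path),
            "am_config_error")
  if (!file.exists(config$contours_path))
    am_stop(sprintf("contour file not found: %s", config$contours_path),
            "am_config_error")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      am_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              "am_stage_error"))
    message(sprintf("[aortamorph] %-14s %6.1f s", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  volume <- stage("read", read_volume(config$volume_path,
                                      units_scale = config$units_scale,
                                      voxel_size_override =
                                        config$voxel_size_override))
  contours <- read_contours(config$contours_path)
  roi <- stage("roi", interpolate_roi(contours, dim(volume$data),
                                      volume$voxel_size, volume$origin))

  edits <- NULL
  if (!is.null(config$lumen_add_path) || !is.null(config$lumen_remove_path)) {
    edits <- list()
    if (!is.null(config$lumen_add_path))
      edits$add <- read_mask(config$lumen_add_path, role = "lumen")
    if (!is.null(config$lumen_remove_path))
      edits$remove <- read_mask(config$lumen_remove_path, role = "lumen")
  }

  wl <- stage("wall-lumen", segment_wall_lumen(
    volume, roi, config$params, manual_lumen_edits = edits,
    keep_intermediates = config$save_intermediates))
  pr <- stage("plaque", segment_plaques(
    volume, wl, config$params,
    keep_intermediates = config$save_intermediates))
  report <- stage("quantify", quantify_specimen(wl, pr, config$slice_range))

  out <- function(f) file.path(config$output_dir, f)
  write_mask(roi, out("roi.nii.gz"))
  write_mask(wl$wall_mask, out("wall.nii.gz"))
  write_mask(wl$lumen_mask, out("lumen.nii.gz"))
  write_mask(wl$aorta_mask, out("aorta.nii.gz"))
  write_mask(pr$plaque_mask, out("plaque.nii.gz"))
  write_mask(pr$lesion_mask, out("lesion.nii.gz"))
  if (config$save_intermediates) {
    for (nm in names(wl$intermediate))
      write_mask(wl$intermediate[[nm]], out(sprintf("%s.nii.gz", nm)))
    for (nm in names(pr$intermediate))
      write_mask(pr$intermediate[[nm]], out(sprintf("%s.nii.gz", nm)))
  }
  lab <- label_volume(wl, pr)
  lab_img <- RNifti::asNifti(lab)
  RNifti::pixdim(lab_img) <- rep(volume$voxel_size, 3)
  RNifti::writeNifti(lab_img, out("labels.nii.gz"), datatype = "uint8")
  if (any(wl$lumen_mask$data))
    export_mesh(wl$lumen_mask, out("lumen.stl"))
  if (any(pr$lesion_mask$data))
    export_mesh(pr$lesion_mask, out("lesion.stl"))
  write_report(report, out("report.csv"))

  manifest <- list(
    package = "aortamorph",
    version = as.character(utils::packageVersion("aortamorph")),
    inputs = list(
      volume = config$volume_path,
      volume_md5 = unname(tools::md5sum(config$volume_path)),
      contours = config$contours_path,
      contours_md5 = unname(tools::md5sum(config$contours_path))),
    units_scale = config$units_scale,
    voxel_size = volume$voxel_size,
    params = unclass(config$params),
    slice_range = config$slice_range,
    save_intermediates = config$save_intermediates)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(wall_lumen = wl, plaque = pr, report = report))
}
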