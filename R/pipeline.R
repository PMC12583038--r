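# End-to-end workflows: morphology (frame -> VMI/TTI -> stratified stats)
# and motility (movie -> prep -> R(t) curves -> stratified stats), with a
# serializable config and a run manifest.

#' Run configuration with documented defaults
#'
#' @param rotation_angle_deg rotation applied to orient the root vertically
#'   (user-supplied; 0 = already vertical).
#' @param saturated_fraction total saturated-pixel fraction for contrast
#'   enhancement.
#' @param register logical: apply rigid-body drift registration before
#'   cropping (motility workflow).
#' @param window correlation window: `"full"` or an integer block size.
#' @param horizon_s motility endpoint horizon, seconds.
#' @param diagonal TTI transect mode, `"tl-br"` or `"both"`.
#' @param vmi_strategy `"feret"` or `"area"`.
#' @param min_area_px minimum lumen compartment area, pixels.
#' @param pixel_size_um micrometers per pixel.
#' @param frame_interval_s seconds between frames.
#' @param seed integer seed recorded in the manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(rotation_angle_deg = 0, saturated_fraction = 0.0035,
                       register = TRUE, window = "full", horizon_s = 120,
                       diagonal = "tl-br", vmi_strategy = "feret",
                       min_area_px = 9, pixel_size_um = 0.11,
                       frame_interval_s = 2, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Read / write a run configuration (YAML or JSON)
#'
#' Round-trips exactly: `read_run_config(write_run_config(cfg, path))` equals
#' `cfg`.
#'
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return `read_run_config`: a [run_config()]. `write_run_config`: the path,
#'   invisibly.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path),
    stop("unsupported config format: .", ext))
  cfg <- do.call(run_config, list())
  for (nm in intersect(names(lst), names(cfg))) cfg[[nm]] <- lst[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg$min_area_px <- as.integer(cfg$min_area_px)
  if (is.numeric(cfg$window)) cfg$window <- as.integer(cfg$window)
  cfg
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(unclass(config), path)
  } else if (ext == "json") {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA)
  } else stop("unsupported config format: .", ext)
  invisible(path)
}

#' MD5 hash of a configuration
#'
#' Canonical JSON serialization hashed with MD5; recorded in run manifests so
#' outputs are traceable to the exact configuration.
#'
#' @param config a [run_config()].
#' @return character MD5 digest.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, config, failures) {
  jsonlite::write_json(
    list(package = "tonodyn",
         version = as.character(utils::packageVersion("tonodyn")),
         config = unclass(config), config_hash = config_hash(config),
         failures = failures),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

resolve_movie <- function(movie, config) {
  if (is.character(movie))
    movie <- read_movie_tiff(movie, pixel_size_um = config$pixel_size_um,
                             frame_interval_s = config$frame_interval_s)
  movie
}

resolve_rois <- function(rois, config) {
  if (is.character(rois))
    rois <- read_rois(rois, pixel_size_um = config$pixel_size_um)
  rois
}

#' Morphology workflow: frame(s) -> VMI/TTI table -> stratified stats
#'
#' Computes the per-cell morphology table and the stratified Mann-Whitney
#' comparisons (one BH family per metric: `ln_vmi` and `tti_per_um`), and
#' writes `morphology.csv`, `stats_report.csv` and `manifest.json` when an
#' output directory is given.
#'
#' @param frames single matrix, list of matrices parallel to the ROIs, or a
#'   TIFF path (first page used for all ROIs).
#' @param rois list of [cell_roi()] or a ROI JSON/CSV path.
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list with `morphology` and `stats` data frames, invisibly when
#'   writing.
#' @export
run_morphology_pipeline <- function(frames, rois, config = run_config(),
                                    out_dir = NULL) {
  if (is.character(frames))
    frames <- read_movie_tiff(frames,
                              pixel_size_um = config$pixel_size_um)$frames[[1]]
  rois <- resolve_rois(rois, config)
  morph <- morphology_table(frames, rois,
                            pixel_size_um = config$pixel_size_um,
                            diagonal = config$diagonal,
                            vmi_strategy = config$vmi_strategy,
                            min_area_px = config$min_area_px)
  stats_out <- list()
  for (metric in c("ln_vmi", "tti_per_um")) {
    if (sum(is.finite(morph[[metric]])) >= 2 &&
        length(unique(morph$condition_label)) >= 2) {
      stats_out[[metric]] <- stratified_compare(morph, metric)
    }
  }
  stats_df <- if (length(stats_out)) do.call(rbind, stats_out) else NULL
  failures <- morph$cell_id[morph$flags != "" & grepl("error", morph$flags)]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(morph, file.path(out_dir, "morphology.csv"),
                     row.names = FALSE)
    if (!is.null(stats_df))
      utils::write.csv(stats_df, file.path(out_dir, "stats_report.csv"),
                       row.names = FALSE)
    write_manifest(out_dir, config, failures)
    return(invisible(list(morphology = morph, stats = stats_df)))
  }
  list(morphology = morph, stats = stats_df)
}

#' Motility workflow: movie -> prep -> R(t) curves -> stratified stats
#'
#' Stages in order: contrast enhancement + 8-bit conversion of the whole
#' movie, rigid-body registration to the first frame (optional), rotation to
#' vertical, per-ROI cropping, per-ROI contrast enhancement, and the
#' frame-to-first-frame correlation curve. Writes `motility.csv` (long
#' per-frame table), `motility_summary.csv` (group mean and SEM per time
#' point), `stats_report.csv` (stratified comparison of the 120-s endpoint)
#' and `manifest.json` when an output directory is given.
#'
#' @param movie a [tono_movie()] or TIFF path.
#' @param rois list of [cell_roi()] or a ROI JSON/CSV path.
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list with `curves` (list of `motility_curve`), `motility`,
#'   `summary`, `r_end`, `stats`, `transforms`.
#' @export
run_motility_pipeline <- function(movie, rois, config = run_config(),
                                  out_dir = NULL) {
  movie <- resolve_movie(movie, config)
  rois <- resolve_rois(rois, config)
  prep <- enhance_contrast(movie, config$saturated_fraction)
  transforms <- NULL
  if (isTRUE(config$register) && n_frames(prep) >= 2) {
    reg <- register_stack(prep)
    prep <- reg$movie
    transforms <- reg$transforms
  }
  if (config$rotation_angle_deg != 0)
    prep <- rotate_to_vertical(prep, config$rotation_angle_deg)
  curves <- list()
  failures <- character(0)
  for (roi in rois) {
    res <- tryCatch({
      cell <- crop_roi(prep, roi)
      cell <- enhance_contrast(cell, config$saturated_fraction)
      motility_curve(cell, window = config$window,
                     horizon_s = config$horizon_s, cell_id = roi$cell_id,
                     condition_label = roi$condition_label,
                     length_um = roi$length_um)
    }, error = function(e) {
      failures <<- c(failures,
                     paste0(roi$cell_id, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) curves[[length(curves) + 1]] <- res
  }
  if (length(curves) == 0) stop("motility pipeline: every ROI failed")
  long <- curves_table(curves)
  summ <- average_curves(curves)
  ends <- r_end_table(curves)
  stats_df <- NULL
  if (length(unique(ends$condition_label)) >= 2 && nrow(ends) >= 4) {
    stats_df <- stratified_compare(ends, "r_end")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(long, file.path(out_dir, "motility.csv"),
                     row.names = FALSE)
    utils::write.csv(summ, file.path(out_dir, "motility_summary.csv"),
                     row.names = FALSE)
    if (!is.null(stats_df))
      utils::write.csv(stats_df, file.path(out_dir, "stats_report.csv"),
                       row.names = FALSE)
    write_manifest(out_dir, config, failures)
  }
  list(curves = curves, motility = long, summary = summ, r_end = ends,
       stats = stats_df, transforms = transforms)
}
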