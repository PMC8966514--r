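#' Default pipeline configuration
#'
#' One structured list holding every tunable parameter of both analysis
#' branches and of the scene generators, with the package defaults. A YAML
#' file read with [read_run_config()] overrides any subset of fields.
#'
#' @return A nested named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    outdir = "fociquant-out",
    design = list(doses = c("0Gy", "2Gy", "5Gy"),
                  times = c("0.5h", "24h", "72h")),
    confocal = list(
      dapi_tiff = NULL, h2ax_tiff = NULL, scene_id = "scene",
      voxel_size = c(0.21, 0.21, 0.3),
      connectivity = 26L, min_voxels = 5L, threshold_bins = 256L,
      smooth_sigma = 2, bradley_window = NULL, bradley_offset = 0.1,
      dilate_radius = 2L, open_radius = 10L, watershed_h = 2,
      nucleus_volume_range = c(100, 10000), sv_max = 1.5,
      exclude_boundary = TRUE),
    dstorm = list(
      localizations_csv = NULL, widefield_tiff = NULL, scene_id = "scene",
      pixel_nm = 100,
      drift = list(enabled = TRUE, bin_frames = 2000L, render_pixel_nm = 10,
                   min_per_bin = 50L),
      dbscan = list(eps = 50, minPts = 10L),
      regions = list(h = 2, area_range = c(20, 10000),
                     exclude_boundary = FALSE),
      calibration = list(eps = 15, minPts = 5L, n_tiles = c(4L, 4L),
                         max_diameter_nm = 60, max_dyes = 3L,
                         min_sample = 100L)),
    synthesize = list(
      confocal = list(enabled = TRUE, shape = c(256L, 256L, 16L),
                      n_nuclei = 3L, foci_lambda = 50),
      storm = list(enabled = TRUE, n_clusters = 40L,
                   epitopes_per_cluster = 50L, drift = c(0, 0)))),
    class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [default_run_config()]; everything else keeps its default. The merged
#' configuration is validated before it is returned.
#'
#' @param path Path to a YAML configuration file, or `NULL` for defaults.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  validate_run_config(cfg)
  cfg
}

merge_config <- function(base, user) {
  out <- modifyList(base, user, keep.null = TRUE)
  class(out) <- "run_config"
  out
}

#' Validate a pipeline configuration
#'
#' Checks physical sizes, algorithm parameters and probability-scale
#' fields; errors name the offending field.
#'
#' @param cfg A `run_config` list.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_run_config <- function(cfg) {
  check_pos <- function(x, field) {
    if (is.null(x) || any(!is.finite(as.numeric(x))) || any(as.numeric(x) <= 0))
      abort(sprintf("config field `%s` must be positive.", field))
  }
  check_pos(cfg$confocal$voxel_size, "confocal.voxel_size")
  check_pos(cfg$confocal$min_voxels, "confocal.min_voxels")
  check_pos(cfg$dstorm$pixel_nm, "dstorm.pixel_nm")
  check_pos(cfg$dstorm$dbscan$eps, "dstorm.dbscan.eps")
  check_pos(cfg$dstorm$dbscan$minPts, "dstorm.dbscan.minPts")
  check_pos(cfg$dstorm$drift$bin_frames, "dstorm.drift.bin_frames")
  check_pos(cfg$dstorm$drift$render_pixel_nm, "dstorm.drift.render_pixel_nm")
  check_pos(cfg$confocal$nucleus_volume_range,
            "confocal.nucleus_volume_range")
  check_pos(cfg$confocal$sv_max, "confocal.sv_max")
  if (!cfg$confocal$connectivity %in% c(6L, 18L, 26L))
    abort("config field `confocal.connectivity` must be 6, 18 or 26.")
  if (length(cfg$seed) != 1L || !is.finite(cfg$seed))
    abort("config field `seed` must be a single integer.")
  invisible(cfg)
}

# provenance block written next to every output set; a run is
# reproducible from this block alone (config + seed + version)
write_provenance <- function(cfg, dir, stage) {
  prov <- list(package = "fociquant",
               version = as.character(utils::packageVersion("fociquant")),
               stage = stage,
               seed = cfg$seed,
               config = strip_class(cfg))
  path <- file.path(dir, paste0("provenance_", stage, ".json"))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

strip_class <- function(x) {
  if (is.list(x)) return(lapply(x, strip_class))
  x
}
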