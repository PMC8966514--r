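#' Generate synthetic scenes to disk
#'
#' Writes a confocal scene (two TIFF channels + JSON truth) and/or a
#' dSTORM scene (localization CSV + widefield TIFF + JSON truth) under
#' `outdir`, with a provenance block recording the configuration and seed.
#'
#' @param cfg A `run_config` list (see [read_run_config()]).
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a named list of written paths.
#' @export
run_synthesize <- function(cfg = default_run_config(), quiet = FALSE) {
  validate_run_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- make_logger(quiet)
  paths <- list()
  sy <- cfg$synthesize
  if (isTRUE(sy$confocal$enabled)) {
    p <- confocal_scene_params(
      shape = as.integer(sy$confocal$shape),
      voxel_size = cfg$confocal$voxel_size,
      n_nuclei = as.integer(sy$confocal$n_nuclei),
      foci_lambda = sy$confocal$foci_lambda)
    sc <- simulate_confocal_scene(p, seed = cfg$seed)
    paths$confocal <- write_confocal_scene(sc, cfg$outdir, id = "confocal")
    log_stage("synthesize/confocal", sprintf(
      "%d nuclei, %d true foci", nrow(sc$truth$nuclei), nrow(sc$truth$foci)))
  }
  if (isTRUE(sy$storm$enabled)) {
    p <- storm_scene_params(
      n_clusters = as.integer(sy$storm$n_clusters),
      epitopes_per_cluster = sy$storm$epitopes_per_cluster,
      drift = sy$storm$drift,
      widefield_pixel_nm = cfg$dstorm$pixel_nm)
    sc <- simulate_storm_scene(p, seed = cfg$seed)
    paths$storm <- write_storm_scene(sc, cfg$outdir, id = "storm")
    log_stage("synthesize/storm", sprintf(
      "%d clusters, %d localizations", nrow(sc$truth$clusters),
      nrow(sc$localizations)))
  }
  write_provenance(cfg, cfg$outdir, "synthesize")
  invisible(paths)
}

#' Run the 3D confocal quantification pipeline
#'
#' Threshold (maximum entropy) → connected-voxel clusters → noise filter →
#' nucleus segmentation → cluster-to-nucleus association → per-nucleus
#' metrics. Writes `confocal_nuclei.csv`, `confocal_clusters.csv`, a
#' 16-bit label TIFF and a provenance block to `cfg$outdir`.
#'
#' @param cfg A `run_config` with `confocal$dapi_tiff` and
#'   `confocal$h2ax_tiff` set (or a `scene` argument).
#' @param scene Optionally, an in-memory `confocal_scene`; overrides the
#'   TIFF paths.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the per-nucleus and per-cluster tibbles
#'   and the nucleus label map.
#' @export
run_confocal <- function(cfg = default_run_config(), scene = NULL,
                         quiet = FALSE) {
  validate_run_config(cfg)
  cc <- cfg$confocal
  if (is.null(scene)) {
    for (f in c("dapi_tiff", "h2ax_tiff"))
      if (is.null(cc[[f]]) || !file.exists(cc[[f]]))
        abort(sprintf("config field `confocal.%s` must name a readable TIFF.",
                      f))
    dapi <- read_image_stack(cc$dapi_tiff, cc$voxel_size, channel = "nucleus")
    h2ax <- read_image_stack(cc$h2ax_tiff, cc$voxel_size, channel = "foci")
  } else {
    dapi <- scene$dapi; h2ax <- scene$foci
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- make_logger(quiet)

  thr <- max_entropy_threshold(h2ax, n_bins = cc$threshold_bins)
  log_stage("confocal/threshold", sprintf("t = %.4g", thr))

  clusters <- extract_foci_clusters(h2ax, thr, connectivity = cc$connectivity)
  filtered <- filter_small_clusters(clusters, min_voxels = cc$min_voxels)
  log_stage("confocal/clusters", sprintf(
    "%d clusters, %d after >= %d voxel filter", nrow(clusters),
    nrow(filtered), cc$min_voxels))

  nuclei <- segment_nuclei(
    dapi, h = cc$watershed_h, volume_range = cc$nucleus_volume_range,
    sv_max = cc$sv_max, exclude_boundary = cc$exclude_boundary,
    smooth_sigma = cc$smooth_sigma, window = cc$bradley_window,
    offset = cc$bradley_offset, dilate_radius = cc$dilate_radius,
    open_radius = cc$open_radius)
  log_stage("confocal/nuclei", sprintf("%d nuclei kept", nrow(nuclei$nuclei)))

  assigned <- assign_clusters_to_nuclei(filtered, nuclei)
  metrics <- confocal_metrics(assigned, nuclei, scene_id = cc$scene_id)
  log_stage("confocal/assign", sprintf(
    "%d clusters assigned, %d unassigned", sum(!is.na(assigned$nucleus)),
    sum(is.na(assigned$nucleus))))

  cluster_csv <- as_tibble(assigned)[, c("cluster", "nucleus", "voxel_count",
                                         "volume_um3", "cx_um", "cy_um",
                                         "cz_um")]
  cluster_csv <- mutate(cluster_csv, scene_id = cc$scene_id, .before = 1)
  readr::write_csv(cluster_csv, file.path(cfg$outdir, "confocal_clusters.csv"))
  nuc_csv <- select(metrics, -"focus_volumes_um3")
  readr::write_csv(nuc_csv, file.path(cfg$outdir, "confocal_nuclei.csv"))
  write_image_stack(nuclei$labels / max(max(nuclei$labels), 1L),
                    file.path(cfg$outdir, "confocal_labels.tif"))
  write_provenance(cfg, cfg$outdir, "confocal")
  invisible(list(nuclei_metrics = metrics, clusters = assigned,
                 label_map = nuclei, threshold = thr))
}

#' Run the dSTORM quantification pipeline
#'
#' Drift correction → DBSCAN clustering → convex hulls → widefield nucleus
#' regions → densities, nearest-neighbor distances, radial profile and
#' coverage → per-tile blinking-model calibration and epitope counts.
#' Writes `dstorm_clusters.csv`, `dstorm_nuclei.csv`, `dstorm_fits.json`
#' and a provenance block to `cfg$outdir`.
#'
#' @param cfg A `run_config` with `dstorm$localizations_csv` and
#'   `dstorm$widefield_tiff` set (or a `scene` argument).
#' @param scene Optionally, an in-memory `storm_scene`.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the cluster table, per-nucleus table and
#'   the calibration object (`NULL` when no tile had enough calibration
#'   clusters).
#' @export
run_dstorm <- function(cfg = default_run_config(), scene = NULL,
                       quiet = FALSE) {
  validate_run_config(cfg)
  ds <- cfg$dstorm
  if (is.null(scene)) {
    if (is.null(ds$localizations_csv) || !file.exists(ds$localizations_csv))
      abort("config field `dstorm.localizations_csv` must name a readable CSV.")
    if (is.null(ds$widefield_tiff) || !file.exists(ds$widefield_tiff))
      abort("config field `dstorm.widefield_tiff` must name a readable TIFF.")
    loc <- read_localizations(ds$localizations_csv)
    wf <- read_image_stack(ds$widefield_tiff,
                           c(ds$pixel_nm / 1000, ds$pixel_nm / 1000, 1),
                           channel = "nucleus")
  } else {
    loc <- scene$localizations; wf <- scene$widefield
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- make_logger(quiet)

  if (isTRUE(ds$drift$enabled)) {
    loc <- drift_correct(loc, bin_frames = ds$drift$bin_frames,
                         pixel_nm = ds$drift$render_pixel_nm,
                         min_per_bin = ds$drift$min_per_bin)
    log_stage("dstorm/drift", sprintf(
      "total drift %.1f nm over %d bins", attr(loc, "total_drift_nm"),
      nrow(attr(loc, "bin_shifts"))))
  }
  clusters <- dbscan_clusters(loc, eps = ds$dbscan$eps,
                              minPts = ds$dbscan$minPts)
  clusters <- add_hull_areas(clusters)
  log_stage("dstorm/dbscan", sprintf(
    "%d clusters, %d noise localizations", nrow(clusters),
    length(attr(clusters, "noise"))))

  regions <- segment_nuclei_widefield(
    wf, pixel_nm = ds$pixel_nm, h = ds$regions$h,
    area_range = ds$regions$area_range,
    exclude_boundary = ds$regions$exclude_boundary)
  clusters <- assign_clusters_to_regions(clusters, regions)
  log_stage("dstorm/regions", sprintf(
    "%d nuclei, %d clusters inside", nrow(regions$regions),
    sum(!is.na(clusters$nucleus))))

  dens <- cluster_density(clusters, regions)
  nnd <- nearest_neighbor_distances(clusters)
  cov <- cluster_coverage(clusters, regions)
  zones <- NULL
  if (nrow(regions$regions) > 0L)
    zones <- tryCatch(
      radial_density_profile(clusters, regions,
                             nucleus = regions$regions$nucleus[1]),
      error = function(e) NULL)

  # calibration pass: subunit-level clustering isolates single-epitope
  # blink clusters; the fitted response function then converts foci-level
  # localization counts into epitope numbers
  cal <- ds$calibration
  cal_clusters <- dbscan_clusters(loc, eps = cal$eps, minPts = cal$minPts)
  fov <- c(range(localization_coords(loc)[, 1]),
           range(localization_coords(loc)[, 2]))
  calib <- tryCatch(
    fit_epitope_tiles(cal_clusters, n_tiles = cal$n_tiles, fov = fov,
                      max_diameter_nm = cal$max_diameter_nm,
                      max_dyes = cal$max_dyes,
                      min_sample = cal$min_sample),
    error = function(e) NULL)
  if (!is.null(calib) && all(calib$tiles$fitted)) {
    clusters <- estimate_epitopes(clusters, calib)
  } else {
    # fall back to one pooled fit when some tiles lack calibration data
    pooled <- pooled_calibration_fit(cal_clusters, cal)
    if (!is.null(pooled)) clusters <- estimate_epitopes(clusters, pooled)
    else warn("too few single-epitope calibration clusters: epitope numbers not estimated.")
  }
  log_stage("dstorm/epitopes", if ("epitope_estimate" %in% names(clusters))
    sprintf("median %d epitopes/cluster",
            as.integer(median(clusters$epitope_estimate)))
    else "skipped")

  cl_csv <- as_tibble(clusters)
  cl_csv$members <- NULL
  cl_csv <- mutate(cl_csv, scene_id = ds$scene_id, .before = 1)
  readr::write_csv(cl_csv, file.path(cfg$outdir, "dstorm_clusters.csv"))

  nuc <- left_join(dens, cov[, c("nucleus", "coverage")], by = "nucleus")
  nuc <- left_join(nuc, nnd$summary[, c("nucleus", "median_nnd_nm")],
                   by = "nucleus")
  if (!is.null(zones))
    for (z in zones$zone)
      nuc[[paste0("zone", z, "_density_per_um2")]] <-
        ifelse(nuc$nucleus == regions$regions$nucleus[1],
               zones$density_per_um2[z], NA_real_)
  nuc <- mutate(nuc, scene_id = ds$scene_id, .before = 1)
  readr::write_csv(nuc, file.path(cfg$outdir, "dstorm_nuclei.csv"))

  fits_json <- if (!is.null(calib)) calib$tiles else tibble()
  jsonlite::write_json(fits_json, file.path(cfg$outdir, "dstorm_fits.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write_provenance(cfg, cfg$outdir, "dstorm")
  invisible(list(clusters = clusters, nuclei = nuc, regions = regions,
                 calibration = calib))
}

pooled_calibration_fit <- function(clusters, cal) {
  co <- attr(clusters, "coords")
  diam <- apparent_diameter(clusters, co)
  cts <- clusters$n_loc[diam <= cal$max_diameter_nm]
  if (length(cts) < cal$min_sample) return(NULL)
  fit_epitope_model(cts, max_dyes = cal$max_dyes,
                    min_sample = cal$min_sample,
                    truncate_at = attr(clusters, "minPts") %||% 1L)
}

make_logger <- function(quiet) {
  if (quiet) return(function(...) invisible(NULL))
  function(stage, msg) inform(sprintf("[%s] %s", stage, msg))
}

#' @importFrom dplyr select
NULL
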