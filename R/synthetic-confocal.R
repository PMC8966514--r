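#' Parameters for a synthetic two-channel confocal scene
#'
#' Defines the generative model used to emulate a two-channel confocal
#' acquisition of γ-H2AX-stained nuclei: ellipsoidal nuclei filled with a
#' multiplicatively textured DAPI signal, repair foci as 3D Gaussian
#' intensity blobs inside the nuclei, and Poisson shot noise plus additive
#' Gaussian read noise on both channels.
#'
#' @param shape Stack dimensions `c(ny, nx, nz)` in voxels.
#' @param voxel_size `(dx, dy, dz)` in µm.
#' @param n_nuclei Number of non-overlapping nuclei to place.
#' @param nucleus_semiaxes Mean ellipsoid semi-axes `(ax, ay, az)` in µm.
#' @param nucleus_jitter Relative jitter of the semi-axes (uniform ±).
#' @param foci_lambda Mean of the Poisson distribution of foci per nucleus.
#' @param foci_per_nucleus Fixed foci count per nucleus; overrides
#'   `foci_lambda` when not `NULL`.
#' @param focus_sigma Gaussian focus widths `(sigma_xy, sigma_z)` in µm.
#' @param focus_amplitude Peak focus intensity above background (photons).
#' @param min_focus_separation_sigma Minimum center-to-center distance
#'   between foci of one nucleus, in units of the per-axis focus sigma
#'   (the anisotropy-aware distance
#'   `sqrt((dx^2 + dy^2) / sigma_xy^2 + dz^2 / sigma_z^2)`). The default
#'   of 5 keeps the intensity valley between neighboring foci below the
#'   maximum-entropy threshold, so foci stay resolvable by
#'   single-threshold connected-component analysis.
#' @param dapi_amplitude Mean DAPI fill intensity inside nuclei (photons).
#' @param texture_sd Standard deviation of the multiplicative DAPI texture.
#' @param background Per-channel mean background `(dapi, foci)` (photons).
#' @param read_noise_sd Additive Gaussian read noise SD (photons).
#' @param placement_attempts Rejection-sampling budget per placed object.
#'
#' @return A named list of class `confocal_scene_params`.
#' @export
confocal_scene_params <- function(shape = c(512L, 512L, 20L),
                                  voxel_size = c(0.21, 0.21, 0.3),
                                  n_nuclei = 10L,
                                  nucleus_semiaxes = c(6.5, 4.5, 2.2),
                                  nucleus_jitter = 0.1,
                                  foci_lambda = 50,
                                  foci_per_nucleus = NULL,
                                  focus_sigma = c(0.2, 0.25),
                                  focus_amplitude = 80,
                                  min_focus_separation_sigma = 5,
                                  dapi_amplitude = 100,
                                  texture_sd = 0.15,
                                  background = c(5, 10),
                                  read_noise_sd = 2,
                                  placement_attempts = 1000L) {
  p <- as.list(environment())
  if (any(p$shape < 1L)) abort("`shape` components must be >= 1.")
  if (any(p$voxel_size <= 0)) abort("`voxel_size` components must be > 0.")
  if (p$n_nuclei < 0L) abort("`n_nuclei` must be >= 0.")
  if (any(p$focus_sigma <= 0)) abort("`focus_sigma` components must be > 0.")
  class(p) <- "confocal_scene_params"
  p
}

#' Simulate a two-channel confocal stack with ground truth
#'
#' Places non-overlapping ellipsoidal nuclei in the field, draws a Poisson
#' number of repair foci inside each, renders the DAPI and γ-H2AX channels
#' and corrupts both with Poisson shot noise and Gaussian read noise.
#' Identical `(params, seed)` produce bit-identical stacks.
#'
#' @param params A [confocal_scene_params()] list.
#' @param seed Integer seed controlling all randomness.
#'
#' @return A list of class `confocal_scene` with elements `dapi` and
#'   `foci` ([image_stack()] objects) and `truth`, a list holding `nuclei`
#'   and `foci` tibbles, the voxel size, stack shape and seed.
#' @export
#' @examples
#' sc <- simulate_confocal_scene(
#'   confocal_scene_params(shape = c(96L, 96L, 8L), n_nuclei = 1L,
#'                         nucleus_semiaxes = c(4, 3, 1), foci_lambda = 5),
#'   seed = 1)
#' nrow(sc$truth$foci)
simulate_confocal_scene <- function(params = confocal_scene_params(),
                                    seed = 1L) {
  stopifnot(inherits(params, "confocal_scene_params"))
  p <- params
  set.seed(seed, kind = "Mersenne-Twister")
  ny <- p$shape[1]; nx <- p$shape[2]; nz <- p$shape[3]
  dx <- p$voxel_size[1]; dy <- p$voxel_size[2]; dz <- p$voxel_size[3]
  Lx <- (nx - 1) * dx; Ly <- (ny - 1) * dy; Lz <- (nz - 1) * dz

  nuclei <- place_nuclei(p, Lx, Ly, Lz)
  foci <- place_foci(p, nuclei)

  dapi_ideal <- render_nuclei(nuclei, p)
  # multiplicative large-scale texture, clipped away from zero
  if (p$texture_sd > 0 && p$n_nuclei > 0L) {
    tex <- array(rnorm(ny * nx * nz, 1, p$texture_sd), c(ny, nx, nz))
    for (k in seq_len(nz)) tex[, , k] <- EBImage::gblur(tex[, , k], sigma = 2)
    dapi_ideal <- dapi_ideal * pmax(tex, 0.2)
  }
  dapi_ideal <- dapi_ideal + p$background[1]
  foci_ideal <- render_foci(foci, p) + p$background[2]

  corrupt <- function(ideal) {
    noisy <- rpois(length(ideal), lambda = as.vector(ideal)) +
      rnorm(length(ideal), 0, p$read_noise_sd)
    array(pmax(noisy, 0), dim(ideal))
  }
  dapi <- image_stack(corrupt(dapi_ideal), p$voxel_size, channel = "nucleus")
  fstk <- image_stack(corrupt(foci_ideal), p$voxel_size, channel = "foci")

  structure(
    list(dapi = dapi, foci = fstk,
         truth = list(nuclei = nuclei, foci = foci,
                      voxel_size = p$voxel_size, shape = p$shape,
                      seed = as.integer(seed))),
    class = "confocal_scene")
}

# rejection placement of non-overlapping ellipsoids (bounding-sphere test)
place_nuclei <- function(p, Lx, Ly, Lz) {
  n <- p$n_nuclei
  out <- tibble(nucleus = integer(), cx_um = numeric(), cy_um = numeric(),
                cz_um = numeric(), ax_um = numeric(), ay_um = numeric(),
                az_um = numeric(), volume_um3 = numeric())
  if (n == 0L) return(out)
  centers <- matrix(NA_real_, n, 3)
  axes <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(p$placement_attempts)) {
      ax <- p$nucleus_semiaxes * runif(3, 1 - p$nucleus_jitter,
                                       1 + p$nucleus_jitter)
      ax[3] <- min(ax[3], 0.45 * Lz)  # keep the ellipsoid inside the stack
      if (ax[1] * 2 > Lx || ax[2] * 2 > Ly)
        abort("nucleus semi-axes exceed the field of view.")
      cx <- runif(1, ax[1], Lx - ax[1])
      cy <- runif(1, ax[2], Ly - ax[2])
      cz <- Lz / 2 + runif(1, -0.05, 0.05) * Lz
      ok <- TRUE
      if (i > 1L) {
        r <- max(ax[1:2])
        for (j in seq_len(i - 1L)) {
          d2 <- (cx - centers[j, 1])^2 + (cy - centers[j, 2])^2
          if (sqrt(d2) < r + max(axes[j, 1:2])) { ok <- FALSE; break }
        }
      }
      if (ok) {
        centers[i, ] <- c(cx, cy, cz); axes[i, ] <- ax
        placed <- TRUE
        break
      }
    }
    if (!placed)
      abort(sprintf(
        "could not place nucleus %d without overlap within %d attempts; reduce `n_nuclei` or the semi-axes.",
        i, p$placement_attempts))
  }
  tibble(nucleus = seq_len(n),
         cx_um = centers[, 1], cy_um = centers[, 2], cz_um = centers[, 3],
         ax_um = axes[, 1], ay_um = axes[, 2], az_um = axes[, 3],
         volume_um3 = 4 / 3 * pi * axes[, 1] * axes[, 2] * axes[, 3])
}

place_foci <- function(p, nuclei) {
  empty <- tibble(focus = integer(), nucleus = integer(), x_um = numeric(),
                  y_um = numeric(), z_um = numeric(), sigma_xy_um = numeric(),
                  sigma_z_um = numeric(), amplitude = numeric())
  if (nrow(nuclei) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(nuclei))) {
    nf <- if (!is.null(p$foci_per_nucleus)) p$foci_per_nucleus
          else rpois(1, p$foci_lambda)
    if (nf == 0L) next
    nuc <- nuclei[i, ]
    pts <- matrix(NA_real_, nf, 3)
    k <- 0L
    for (att in seq_len(p$placement_attempts * max(nf, 1L))) {
      if (k >= nf) break
      # uniform in the unit ball, scaled to 90% of the ellipsoid
      u <- rnorm(3); u <- u / sqrt(sum(u^2)) * runif(1)^(1 / 3)
      cand <- c(nuc$cx_um + 0.9 * nuc$ax_um * u[1],
                nuc$cy_um + 0.9 * nuc$ay_um * u[2],
                nuc$cz_um + 0.9 * nuc$az_um * u[3])
      if (k > 0L && p$min_focus_separation_sigma > 0) {
        dd <- t(pts[seq_len(k), , drop = FALSE]) - cand
        # per-axis sigma-normalized separation (z blobs are wider)
        d <- sqrt((dd[1, ]^2 + dd[2, ]^2) / p$focus_sigma[1]^2 +
                    dd[3, ]^2 / p$focus_sigma[2]^2)
        if (min(d) < p$min_focus_separation_sigma) next
      }
      k <- k + 1L
      pts[k, ] <- cand
    }
    if (k < nf)
      abort(sprintf(
        "could not place %d separated foci in nucleus %d within %d attempts.",
        nf, i, p$placement_attempts * nf))
    rows[[length(rows) + 1L]] <-
      tibble(nucleus = nuc$nucleus, x_um = pts[, 1], y_um = pts[, 2],
             z_um = pts[, 3], sigma_xy_um = p$focus_sigma[1],
             sigma_z_um = p$focus_sigma[2], amplitude = p$focus_amplitude)
  }
  if (length(rows) == 0L) return(empty)
  out <- bind_rows(rows)
  mutate(out, focus = row_number(), .before = 1)
}

render_nuclei <- function(nuclei, p) {
  ny <- p$shape[1]; nx <- p$shape[2]; nz <- p$shape[3]
  arr <- array(0, c(ny, nx, nz))
  if (nrow(nuclei) == 0L) return(arr)
  vs <- p$voxel_size
  xs <- (seq_len(nx) - 1) * vs[1]
  ys <- (seq_len(ny) - 1) * vs[2]
  zs <- (seq_len(nz) - 1) * vs[3]
  for (i in seq_len(nrow(nuclei))) {
    nu <- nuclei[i, ]
    ix <- which(abs(xs - nu$cx_um) <= nu$ax_um)
    iy <- which(abs(ys - nu$cy_um) <= nu$ay_um)
    iz <- which(abs(zs - nu$cz_um) <= nu$az_um)
    if (!length(ix) || !length(iy) || !length(iz)) next
    ex <- ((xs[ix] - nu$cx_um) / nu$ax_um)^2
    ey <- ((ys[iy] - nu$cy_um) / nu$ay_um)^2
    ez <- ((zs[iz] - nu$cz_um) / nu$az_um)^2
    q <- outer(ey, ex, `+`)
    for (k in seq_along(iz)) {
      inside <- q + ez[k] <= 1
      sl <- arr[iy, ix, iz[k]]
      sl[inside] <- sl[inside] + p$dapi_amplitude
      arr[iy, ix, iz[k]] <- sl
    }
  }
  arr
}

render_foci <- function(foci, p) {
  ny <- p$shape[1]; nx <- p$shape[2]; nz <- p$shape[3]
  arr <- array(0, c(ny, nx, nz))
  if (nrow(foci) == 0L) return(arr)
  vs <- p$voxel_size
  xs <- (seq_len(nx) - 1) * vs[1]
  ys <- (seq_len(ny) - 1) * vs[2]
  zs <- (seq_len(nz) - 1) * vs[3]
  for (i in seq_len(nrow(foci))) {
    fo <- foci[i, ]
    ix <- which(abs(xs - fo$x_um) <= 4 * fo$sigma_xy_um)
    iy <- which(abs(ys - fo$y_um) <= 4 * fo$sigma_xy_um)
    iz <- which(abs(zs - fo$z_um) <= 4 * fo$sigma_z_um)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(xs[ix] - fo$x_um)^2 / (2 * fo$sigma_xy_um^2))
    gy <- exp(-(ys[iy] - fo$y_um)^2 / (2 * fo$sigma_xy_um^2))
    gz <- exp(-(zs[iz] - fo$z_um)^2 / (2 * fo$sigma_z_um^2))
    blob <- fo$amplitude * outer(gy, gx)
    for (k in seq_along(iz))
      arr[iy, ix, iz[k]] <- arr[iy, ix, iz[k]] + blob * gz[k]
  }
  arr
}

#' Write a confocal scene to disk (TIFF channels + JSON truth sidecar)
#'
#' @param scene A `confocal_scene` from [simulate_confocal_scene()].
#' @param dir Output directory (created if missing).
#' @param id Scene identifier used as the file-name stem.
#' @return Invisibly, the paths written.
#' @export
write_confocal_scene <- function(scene, dir, id = "scene") {
  stopifnot(inherits(scene, "confocal_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    dapi = file.path(dir, paste0(id, "_dapi.tif")),
    foci = file.path(dir, paste0(id, "_h2ax.tif")),
    truth = file.path(dir, paste0(id, "_truth.json")))
  write_image_stack(scene$dapi, paths[["dapi"]])
  write_image_stack(scene$foci, paths[["foci"]])
  jsonlite::write_json(scene$truth, paths[["truth"]], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
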