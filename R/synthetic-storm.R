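#' Parameters for a synthetic dSTORM acquisition
#'
#' Generative model for a single-molecule localization dataset of γ-H2AX
#' clusters inside one nucleus. Each cluster holds a known number of
#' epitopes (antibody-binding sites); each epitope carries
#' `Binomial(max_dyes, labeling_efficiency)` detected dyes (possibly zero);
#' each dye blinks into `Geometric(q)` localizations on support
#' `{1, 2, ...}` (mean `1/q`); localization positions are the epitope
#' position jittered by an isotropic Gaussian of SD `precision_sigma` and
#' shifted by linear stage drift. Frames are assigned uniformly at random.
#'
#' @param nucleus_polygon Two-column matrix of polygon vertices (nm);
#'   default is a 64-gon ellipse of semi-axes 8 × 6 µm.
#' @param n_clusters Number of γ-H2AX clusters inside the nucleus.
#' @param epitopes_per_cluster Epitopes per cluster: a single count or a
#'   `c(min, max)` range sampled uniformly.
#' @param cluster_sigma Gaussian scatter of epitopes about the cluster
#'   center (nm).
#' @param labeling_efficiency Probability that a dye site is occupied,
#'   in `[0, 1]`.
#' @param q Per-dye geometric blink parameter in `(0, 1]`; the mean number
#'   of localizations per detected dye is `1/q`.
#' @param q_field Optional function `(x_nm, y_nm) -> q` modeling spatially
#'   inhomogeneous photophysics across the field of view (illumination
#'   intensity varies); overrides the scalar `q` where supplied.
#' @param max_dyes Maximum dyes per epitope (integer `>= 1`).
#' @param precision_sigma Localization precision SD (nm).
#' @param drift Linear stage drift `(vx, vy)` in nm per frame.
#' @param n_frames Number of camera frames in the acquisition.
#' @param widefield_pixel_nm Pixel size of the rendered widefield image.
#'
#' @return A named list of class `storm_scene_params`.
#' @export
storm_scene_params <- function(nucleus_polygon = NULL,
                               n_clusters = 40L,
                               epitopes_per_cluster = 50L,
                               cluster_sigma = 100,
                               labeling_efficiency = 0.6,
                               q = 0.2,
                               q_field = NULL,
                               max_dyes = 3L,
                               precision_sigma = 10,
                               drift = c(0, 0),
                               n_frames = 20000L,
                               widefield_pixel_nm = 100) {
  if (is.null(nucleus_polygon)) {
    th <- seq(0, 2 * pi, length.out = 65L)[-65L]
    nucleus_polygon <- cbind(x = 10000 + 8000 * cos(th),
                             y = 8000 + 6000 * sin(th))
  }
  p <- as.list(environment())
  if (p$q <= 0 || p$q > 1) abort("`q` must lie in (0, 1].")
  if (p$labeling_efficiency < 0 || p$labeling_efficiency > 1)
    abort("`labeling_efficiency` must lie in [0, 1].")
  if (p$max_dyes < 1L) abort("`max_dyes` must be >= 1.")
  if (p$n_frames < 1L) abort("`n_frames` must be >= 1.")
  if (p$precision_sigma < 0) abort("`precision_sigma` must be >= 0.")
  if (any(p$epitopes_per_cluster < 1L))
    abort("`epitopes_per_cluster` must be >= 1.")
  class(p) <- "storm_scene_params"
  p
}

#' Simulate a dSTORM localization table with ground truth
#'
#' @param params A [storm_scene_params()] list.
#' @param seed Integer seed controlling all randomness.
#'
#' @return A list of class `storm_scene` with elements `localizations`
#'   (tibble: `frame`, `x_nm`, `y_nm`, `sigma_nm`), `widefield` (a 2D
#'   [image_stack()] rendered at `widefield_pixel_nm`) and `truth` (cluster
#'   and epitope tibbles, the nucleus polygon and its area, blink
#'   parameters, drift, frames, seed).
#' @export
#' @examples
#' sc <- simulate_storm_scene(
#'   storm_scene_params(n_clusters = 5L, epitopes_per_cluster = 10L),
#'   seed = 1)
#' head(sc$localizations)
simulate_storm_scene <- function(params = storm_scene_params(), seed = 1L) {
  stopifnot(inherits(params, "storm_scene_params"))
  p <- params
  set.seed(seed, kind = "Mersenne-Twister")
  poly <- p$nucleus_polygon

  # cluster centers uniform inside the nucleus polygon
  centers <- sample_in_polygon(p$n_clusters, poly)
  n_epi <- if (length(p$epitopes_per_cluster) == 2L)
    sample(p$epitopes_per_cluster[1]:p$epitopes_per_cluster[2],
           p$n_clusters, replace = TRUE)
  else rep(as.integer(p$epitopes_per_cluster), p$n_clusters)

  # epitope positions: cluster center + truncated Gaussian scatter
  epi <- scatter_epitopes(centers, n_epi, p$cluster_sigma, poly)

  n_e <- nrow(epi)
  dyes <- if (n_e) rbinom(n_e, p$max_dyes, p$labeling_efficiency) else integer()
  q_e <- if (is.null(p$q_field)) rep(p$q, n_e)
         else p$q_field(epi$x_nm, epi$y_nm)
  if (n_e && (any(q_e <= 0) || any(q_e > 1)))
    abort("`q_field` must return values in (0, 1].")

  dye_epi <- rep(seq_len(n_e), dyes)
  n_d <- length(dye_epi)
  nloc_dye <- if (n_d) rgeom(n_d, q_e[dye_epi]) + 1L else integer()
  loc_epi <- rep(dye_epi, nloc_dye)
  n_l <- length(loc_epi)

  frames <- if (n_l) sample.int(p$n_frames, n_l, replace = TRUE) - 1L
            else integer()
  x <- epi$x_nm[loc_epi] + rnorm(n_l, 0, p$precision_sigma) +
    p$drift[1] * frames
  y <- epi$y_nm[loc_epi] + rnorm(n_l, 0, p$precision_sigma) +
    p$drift[2] * frames
  loc <- tibble(frame = as.integer(frames), x_nm = x, y_nm = y,
                sigma_nm = rep(p$precision_sigma, n_l))

  epi$n_dyes <- dyes
  epi$n_loc <- as.integer(tabulate(loc_epi, nbins = n_e))

  wf <- render_widefield(loc, poly, p$widefield_pixel_nm)
  truth <- list(
    clusters = tibble(cluster = seq_len(p$n_clusters),
                      cx_nm = centers[, 1], cy_nm = centers[, 2],
                      n_epitopes = as.integer(n_epi)),
    epitopes = epi,
    nucleus_polygon = poly,
    nucleus_area_um2 = polygon_area(poly) / 1e6,
    loc_epitope = loc_epi,
    loc_cluster = if (n_l) epi$cluster[loc_epi] else integer(),
    labeling_efficiency = p$labeling_efficiency, q = p$q,
    max_dyes = p$max_dyes, precision_sigma = p$precision_sigma,
    drift = p$drift, n_frames = as.integer(p$n_frames),
    seed = as.integer(seed))
  structure(list(localizations = loc, widefield = wf, truth = truth),
            class = "storm_scene")
}

scatter_epitopes <- function(centers, n_epi, sigma, poly) {
  empty <- tibble(epitope = integer(), cluster = integer(),
                  x_nm = numeric(), y_nm = numeric())
  if (nrow(centers) == 0L || sum(n_epi) == 0L) return(empty)
  rows <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    need <- n_epi[i]
    xs <- numeric(0); ys <- numeric(0)
    guard <- 0L
    while (length(xs) < need && guard < 200L) {
      m <- (need - length(xs)) * 2L + 8L
      cx <- centers[i, 1] + rnorm(m, 0, sigma)
      cy <- centers[i, 2] + rnorm(m, 0, sigma)
      keep <- point_in_polygon(cx, cy, poly)
      xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
      guard <- guard + 1L
    }
    if (length(xs) < need)
      abort(sprintf("could not scatter %d epitopes inside the nucleus for cluster %d.",
                    need, i))
    rows[[i]] <- tibble(cluster = i, x_nm = xs[seq_len(need)],
                        y_nm = ys[seq_len(need)])
  }
  out <- bind_rows(rows)
  mutate(out, epitope = row_number(), .before = 1)
}

sample_in_polygon <- function(n, poly, attempts = NULL) {
  if (is.null(attempts)) attempts <- max(10000L, 30L * n)
  if (n == 0L)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out <- matrix(NA_real_, n, 2)
  k <- 0L
  for (i in seq_len(attempts)) {
    if (k >= n) break
    cx <- runif(1, xr[1], xr[2]); cy <- runif(1, yr[1], yr[2])
    if (point_in_polygon(cx, cy, poly)) { k <- k + 1L; out[k, ] <- c(cx, cy) }
  }
  if (k < n)
    abort(sprintf("could not place %d points inside the polygon within %d attempts.",
                  n, attempts))
  colnames(out) <- c("x", "y")
  out
}

# even-odd ray casting, vectorized over query points
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# shoelace area (nm^2), orientation-independent
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Gaussian-rendered localization density plus nucleus fill, Poisson noise
render_widefield <- function(loc, poly, pixel_nm) {
  xmax <- max(poly[, 1]) + 2000
  ymax <- max(poly[, 2]) + 2000
  nx <- max(2L, ceiling(xmax / pixel_nm))
  ny <- max(2L, ceiling(ymax / pixel_nm))
  img <- matrix(0, ny, nx)
  # nucleus autofluorescence fill
  pcx <- rep((seq_len(nx) - 0.5) * pixel_nm, each = ny)
  pcy <- rep((seq_len(ny) - 0.5) * pixel_nm, times = nx)
  img[matrix(point_in_polygon(pcx, pcy, poly), ny, nx)] <- 60
  if (nrow(loc) > 0L) {
    ix <- pmin(pmax(floor(loc$x_nm / pixel_nm) + 1L, 1L), nx)
    iy <- pmin(pmax(floor(loc$y_nm / pixel_nm) + 1L, 1L), ny)
    cnt <- tabulate(iy + (ix - 1L) * ny, nbins = ny * nx)
    img <- img + matrix(cnt, ny, nx) * 5
  }
  img <- EBImage::gblur(img, sigma = 2) + 5
  noisy <- matrix(pmax(rpois(length(img), as.vector(img)) +
                         rnorm(length(img), 0, 1), 0), ny, nx)
  image_stack(noisy, voxel_size = c(pixel_nm / 1000, pixel_nm / 1000, 1),
              channel = "nucleus")
}

#' Write a dSTORM scene to disk (CSV + widefield TIFF + JSON truth sidecar)
#'
#' @param scene A `storm_scene` from [simulate_storm_scene()].
#' @param dir Output directory (created if missing).
#' @param id Scene identifier used as the file-name stem.
#' @return Invisibly, the paths written.
#' @export
write_storm_scene <- function(scene, dir, id = "scene") {
  stopifnot(inherits(scene, "storm_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    localizations = file.path(dir, paste0(id, "_localizations.csv")),
    widefield = file.path(dir, paste0(id, "_widefield.tif")),
    truth = file.path(dir, paste0(id, "_truth.json")))
  readr::write_csv(scene$localizations, paths[["localizations"]])
  write_image_stack(scene$widefield, paths[["widefield"]])
  truth <- scene$truth
  truth$nucleus_polygon <- as.data.frame(truth$nucleus_polygon)
  truth$loc_epitope <- NULL   # per-localization maps stay in memory only
  truth$loc_cluster <- NULL
  jsonlite::write_json(truth, paths[["truth"]], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a localization table from CSV
#'
#' Expects a header with columns `frame`, `x_nm`, `y_nm`, `sigma_nm`
#' (comma-separated, decimal point), the output format of upstream
#' localization software exports.
#'
#' @param path CSV file path.
#' @return A tibble with the four required columns.
#' @export
read_localizations <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("frame", "x_nm", "y_nm", "sigma_nm")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    abort(paste0("localization table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  if (any(!is.finite(tab$x_nm)) || any(!is.finite(tab$y_nm)))
    abort("localization coordinates must be finite.")
  if (any(tab$sigma_nm <= 0)) abort("`sigma_nm` must be > 0.")
  tab[need]
}
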