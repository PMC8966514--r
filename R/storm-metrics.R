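#' Convex-hull area of a point set
#'
#' Area of the convex hull by the shoelace formula on the hull vertices,
#' reported in µm² (input coordinates in nm). Degenerate sets — fewer than
#' three points, or all collinear — get area 0 and the `degenerate` flag.
#'
#' @param coords Two-column matrix of point coordinates (nm).
#' @return Scalar area (µm²) with attribute `degenerate`.
#' @export
#' @examples
#' sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
#' hull_area(sq)  # 1 um^2
hull_area <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3L)
    return(structure(0, degenerate = TRUE))
  h <- grDevices::chull(coords)
  if (length(h) < 3L)
    return(structure(0, degenerate = TRUE))
  x <- coords[h, 1]; y <- coords[h, 2]
  n <- length(h)
  j <- c(n, seq_len(n - 1L))
  a_nm2 <- abs(sum(x[j] * y - x * y[j])) / 2
  structure(a_nm2 / 1e6, degenerate = a_nm2 <= 0)
}

#' Add convex-hull areas to a cluster table
#'
#' @param clusters A `storm_clusters` tibble from [dbscan_clusters()].
#' @return `clusters` with `hull_area_um2` and `degenerate` columns.
#' @export
add_hull_areas <- function(clusters) {
  stopifnot(inherits(clusters, "storm_clusters"))
  co <- attr(clusters, "coords")
  areas <- lapply(clusters$members, function(i) hull_area(co[i, , drop = FALSE]))
  out <- clusters
  out$hull_area_um2 <- vapply(areas, as.numeric, numeric(1))
  out$degenerate <- vapply(areas, function(a) attr(a, "degenerate"),
                           logical(1))
  out
}

#' Segment nucleus regions in a conventional widefield image
#'
#' Applies the slice-segmentation recipe ([binarize_nuclei_slices()]) and
#' the 2D marker-controlled watershed to the single widefield image taken
#' alongside a dSTORM acquisition, yielding labeled nucleus regions with
#' areas in µm².
#'
#' @param image A 2D [image_stack()] (one slice), or a matrix plus
#'   `pixel_nm`.
#' @param pixel_nm Pixel size in nm (required when `image` is a matrix).
#' @param h Watershed extended-maxima depth (pixels).
#' @param area_range Retained region areas `c(min, max)` in µm².
#' @param exclude_boundary Drop regions touching the image border.
#' @param ... Passed to [binarize_nuclei_slices()].
#'
#' @return A list of class `nucleus_regions`: `labels` (integer matrix),
#'   `pixel_nm`, and `regions`, a tibble with `nucleus`, `area_um2`,
#'   `cx_nm`, `cy_nm`, `touches_boundary`.
#' @export
segment_nuclei_widefield <- function(image, pixel_nm = NULL, h = 2,
                                     area_range = c(20, 10000),
                                     exclude_boundary = FALSE, ...) {
  if (inherits(image, "image_stack")) {
    if (is.null(pixel_nm)) pixel_nm <- image$voxel_size[1] * 1000
    stack <- image
  } else {
    if (is.null(pixel_nm)) abort("`pixel_nm` is required for matrix input.")
    stack <- image_stack(as.matrix(image),
                         voxel_size = c(pixel_nm / 1000, pixel_nm / 1000, 1),
                         channel = "nucleus")
  }
  bin <- binarize_nuclei_slices(stack, ...)
  map <- split_nuclei_watershed(bin, voxel_size = stack$voxel_size, h = h,
                                per_slice = FALSE)
  lab <- map$labels[, , 1]
  px_um2 <- (pixel_nm / 1000)^2
  k <- max(lab, 0L)
  if (k > 0L) {
    cnt <- tabulate(lab[lab > 0L], nbins = k)
    idx <- which(lab > 0L)
    co <- arrayInd(idx, dim(lab))
    li <- lab[idx]
    grp <- factor(li, levels = seq_len(k))
    bdry <- co[, 1] == 1L | co[, 1] == nrow(lab) |
      co[, 2] == 1L | co[, 2] == ncol(lab)
    tab <- tibble(
      nucleus = seq_len(k),
      area_um2 = cnt * px_um2,
      cx_nm = as.numeric(tapply((co[, 2] - 0.5) * pixel_nm, grp, mean)),
      cy_nm = as.numeric(tapply((co[, 1] - 0.5) * pixel_nm, grp, mean)),
      touches_boundary = as.logical(tapply(bdry, grp, any)))
    keep <- tab$area_um2 >= area_range[1] & tab$area_um2 <= area_range[2]
    if (exclude_boundary) keep <- keep & !tab$touches_boundary
    kept <- tab$nucleus[keep]
    relab <- integer(k)
    relab[kept] <- seq_along(kept)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
    tab <- tab[keep, ]
    tab$nucleus <- seq_len(nrow(tab))
  } else {
    tab <- tibble(nucleus = integer(), area_um2 = numeric(),
                  cx_nm = numeric(), cy_nm = numeric(),
                  touches_boundary = logical())
  }
  structure(list(labels = lab, pixel_nm = pixel_nm, regions = tab),
            class = "nucleus_regions")
}

#' Assign clusters to nucleus regions by center-in-region
#'
#' @param clusters A `storm_clusters` tibble.
#' @param regions A `nucleus_regions` object.
#' @return `clusters` with the `nucleus` column filled (`NA` outside all
#'   regions).
#' @export
assign_clusters_to_regions <- function(clusters, regions) {
  stopifnot(inherits(clusters, "storm_clusters"),
            inherits(regions, "nucleus_regions"))
  if (nrow(clusters) == 0L) return(clusters)
  lab <- regions$labels
  px <- regions$pixel_nm
  ix <- pmin(pmax(floor(clusters$cx_nm / px) + 1L, 1L), ncol(lab))
  iy <- pmin(pmax(floor(clusters$cy_nm / px) + 1L, 1L), nrow(lab))
  l <- lab[cbind(iy, ix)]
  out <- clusters
  out$nucleus <- ifelse(l > 0L, l, NA_integer_)
  out
}

#' Per-nucleus cluster density
#'
#' Number of non-noise clusters whose geometric center lies inside the
#' nucleus, divided by the nucleus area.
#'
#' @param clusters An assigned `storm_clusters` tibble.
#' @param regions A `nucleus_regions` object.
#' @return Tibble with `nucleus`, `area_um2`, `n_clusters`,
#'   `density_per_um2`.
#' @export
cluster_density <- function(clusters, regions) {
  stopifnot(inherits(regions, "nucleus_regions"))
  counts <- tabulate(clusters$nucleus[!is.na(clusters$nucleus)],
                     nbins = max(regions$regions$nucleus, 0L))
  tab <- regions$regions
  tibble(nucleus = tab$nucleus,
         area_um2 = tab$area_um2,
         n_clusters = as.integer(counts[tab$nucleus]),
         density_per_um2 = counts[tab$nucleus] / tab$area_um2)
}

#' Radial cluster-density profile in five equal-area zones
#'
#' Partitions a nucleus region into concentric zones of equal area using
#' quantiles of the normalized interior distance transform (1 at the
#' center, 0 at the envelope) and reports the cluster-center density in
#' each zone. Zone 1 is the innermost, zone `n_zones` touches the
#' envelope.
#'
#' @param clusters An assigned `storm_clusters` tibble.
#' @param regions A `nucleus_regions` object.
#' @param nucleus Which nucleus label to profile.
#' @param n_zones Number of zones (default 5).
#' @return Tibble with `zone`, `area_um2`, `n_clusters`,
#'   `density_per_um2`.
#' @export
radial_density_profile <- function(clusters, regions, nucleus = 1L,
                                   n_zones = 5L) {
  stopifnot(inherits(regions, "nucleus_regions"))
  lab <- regions$labels
  mask <- lab == nucleus
  npix <- sum(mask)
  if (npix < n_zones)
    abort(sprintf("nucleus %d has %d pixels; cannot form %d zones.",
                  nucleus, npix, n_zones))
  d <- c(dim(mask), 1L)
  dist <- .edt3d(as.vector(mask), d[1], d[2], 1L, 1, 1, 1)
  dist <- matrix(dist, d[1], d[2])
  nd <- dist / max(dist)
  # empirical-quantile (rank) construction: zones are equal-area to within
  # one pixel even when distance values tie; zone 1 = innermost
  vals <- nd[mask]
  ord <- order(vals, decreasing = TRUE)
  zones_px <- integer(npix)
  zones_px[ord] <- ceiling(seq_len(npix) / npix * n_zones)
  zone_map <- matrix(NA_integer_, d[1], d[2])
  zone_map[mask] <- zones_px
  area_px <- tabulate(zones_px, nbins = n_zones)
  if (any(area_px == 0L))
    abort(sprintf("nucleus %d is too small to form %d non-empty zones.",
                  nucleus, n_zones))
  px <- regions$pixel_nm
  cl <- clusters[!is.na(clusters$nucleus) & clusters$nucleus == nucleus, ]
  n_cl <- integer(n_zones)
  if (nrow(cl)) {
    ix <- pmin(pmax(floor(cl$cx_nm / px) + 1L, 1L), ncol(lab))
    iy <- pmin(pmax(floor(cl$cy_nm / px) + 1L, 1L), nrow(lab))
    zc <- zone_map[cbind(iy, ix)]
    n_cl <- tabulate(zc[!is.na(zc)], nbins = n_zones)
  }
  area_um2 <- area_px * (px / 1000)^2
  tibble(zone = seq_len(n_zones), area_um2 = area_um2,
         n_clusters = as.integer(n_cl),
         density_per_um2 = n_cl / area_um2)
}

#' Nearest-neighbor distances between cluster centers
#'
#' Euclidean distance from each cluster center to the closest other
#' center within the same nucleus, with the per-nucleus median.
#'
#' @param clusters An assigned `storm_clusters` tibble (unassigned
#'   clusters are ignored; pass `by_nucleus = FALSE` to pool all centers).
#' @param by_nucleus Compute within nuclei (default) or over all centers.
#' @return A list with `distances` (tibble: `cluster`, `nucleus`,
#'   `nnd_nm`) and `summary` (tibble: `nucleus`, `n`, `median_nnd_nm`).
#'   With fewer than two centers the tibbles are empty and a warning is
#'   raised.
#' @export
nearest_neighbor_distances <- function(clusters, by_nucleus = TRUE) {
  tab <- as_tibble(clusters)[, c("cluster", "nucleus", "cx_nm", "cy_nm")]
  if (!by_nucleus) tab$nucleus <- 1L
  tab <- tab[!is.na(tab$nucleus), ]
  res <- list()
  for (nuc in unique(tab$nucleus)) {
    g <- tab[tab$nucleus == nuc, ]
    if (nrow(g) < 2L) next
    res[[length(res) + 1L]] <-
      tibble(cluster = g$cluster, nucleus = nuc,
             nnd_nm = .nnd2d(g$cx_nm, g$cy_nm))
  }
  if (!length(res)) {
    warn("fewer than two cluster centers per nucleus: no distances computed.")
    return(list(distances = tibble(cluster = integer(), nucleus = integer(),
                                   nnd_nm = numeric()),
                summary = tibble(nucleus = integer(), n = integer(),
                                 median_nnd_nm = numeric())))
  }
  distances <- bind_rows(res)
  summary <- summarise(group_by(distances, .data$nucleus),
                       n = n(), median_nnd_nm = median(.data$nnd_nm),
                       .groups = "drop")
  list(distances = distances, summary = summary)
}

#' Cluster coverage of the nucleus area
#'
#' Sum of the convex-hull areas of a nucleus's clusters divided by the
#' nucleus area (dimensionless).
#'
#' @param clusters An assigned `storm_clusters` tibble with hull areas
#'   (see [add_hull_areas()]).
#' @param regions A `nucleus_regions` object.
#' @return Tibble with `nucleus`, `sum_hull_um2`, `area_um2`, `coverage`.
#' @export
cluster_coverage <- function(clusters, regions) {
  stopifnot(inherits(regions, "nucleus_regions"))
  if (!"hull_area_um2" %in% names(clusters))
    abort("run `add_hull_areas()` before computing coverage.")
  tab <- regions$regions
  cl <- clusters[!is.na(clusters$nucleus), ]
  sums <- tapply(cl$hull_area_um2, factor(cl$nucleus, levels = tab$nucleus),
                 sum)
  sums[is.na(sums)] <- 0
  tibble(nucleus = tab$nucleus,
         sum_hull_um2 = as.numeric(sums),
         area_um2 = tab$area_um2,
         coverage = as.numeric(sums) / tab$area_um2)
}
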