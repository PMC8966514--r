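#' Slice-wise binarization of the DAPI nucleus channel
#'
#' The slice-segmentation recipe applied to every z-slice: linear contrast
#' stretch between the 1st and 99th stack-intensity percentiles, Gaussian
#' smoothing (σ = 2 px), binarization of all slices with one global
#' threshold — the mean of the Bradley local adaptive threshold surface
#' computed on the single slice with the highest summed intensity — then
#' dilation (disk r = 2 px), hole filling by flood fill, and a
#' morphological opening (erosion + dilation, disk r = 10 px) that removes
#' small blobs.
#'
#' @param stack An [image_stack()] (nucleus channel); a single-slice stack
#'   is valid and covers the widefield case.
#' @param smooth_sigma Gaussian smoothing SD in pixels.
#' @param window Bradley averaging window in pixels (odd); default is
#'   1/8 of the slice width.
#' @param offset Bradley sensitivity offset as a fraction of the stretched
#'   dynamic range.
#' @param dilate_radius,open_radius Disk radii (pixels) of the dilation
#'   and the opening structuring elements.
#'
#' @return A logical array of the same shape as the stack.
#' @export
binarize_nuclei_slices <- function(stack, smooth_sigma = 2, window = NULL,
                                   offset = 0.1, dilate_radius = 2L,
                                   open_radius = 10L) {
  stopifnot(inherits(stack, "image_stack"))
  arr <- stack$intensities
  d <- dim(arr)
  if (min(d[1:2]) < 2L * open_radius + 1L)
    abort(sprintf(
      "slices (%d x %d px) are smaller than the opening structuring element (disk r = %d px).",
      d[1], d[2], open_radius))
  q <- quantile(arr, c(0.01, 0.99), names = FALSE)
  if (q[2] <= q[1])
    abort("cannot binarize: the intensity histogram is degenerate (near-constant image).")
  stretched <- array(pmin(pmax((arr - q[1]) / (q[2] - q[1]), 0), 1), d)

  smoothed <- stretched
  for (k in seq_len(d[3]))
    smoothed[, , k] <- EBImage::gblur(stretched[, , k], sigma = smooth_sigma)

  ref <- which.max(vapply(seq_len(d[3]),
                          function(k) sum(smoothed[, , k]), numeric(1)))
  thr <- mean(bradley_thresholds(smoothed[, , ref], window = window,
                                 offset = offset))

  bin <- smoothed > thr
  disk2 <- EBImage::makeBrush(2L * dilate_radius + 1L, shape = "disc")
  disk10 <- EBImage::makeBrush(2L * open_radius + 1L, shape = "disc")
  for (k in seq_len(d[3])) {
    sl <- bin[, , k]
    if (!any(sl)) next
    sl <- EBImage::dilate(sl, disk2)
    sl <- EBImage::fillHull(sl) > 0
    sl <- EBImage::dilate(EBImage::erode(sl, disk10), disk10)
    bin[, , k] <- sl > 0
  }
  bin
}

# Bradley local adaptive threshold surface: the local box mean plus a
# sensitivity offset expressed in units of the (stretched) dynamic range.
bradley_thresholds <- function(slice, window = NULL, offset = 0.1) {
  d <- dim(slice)
  if (is.null(window)) window <- max(3L, floor(d[2] / 8))
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  window <- min(window, 2L * floor((min(d) - 1L) / 2L) + 1L)
  brush <- matrix(1 / window^2, window, window)
  local_mean <- EBImage::filter2(slice, brush)
  local_mean + offset * (max(slice) - min(slice))
}

#' Split touching nuclei by marker-controlled watershed
#'
#' Runs the anti-oversegmentation watershed recipe: Euclidean distance
#' transform of the foreground, suppression of shallow maxima with an
#' extended-maxima (depth `h`) transform whose plateaus become the only
#' seeds, then marker-controlled watershed flooding; ridge voxels separate
#' the labels. The recipe runs on every slice separately first and is then
#' repeated on the compiled 3D binary volume, as single-slice distance
#' maps split touching nuclei more reliably than the anisotropic volume.
#'
#' @param binary Logical array from [binarize_nuclei_slices()] (or any
#'   binary stack of the same shape).
#' @param voxel_size `(dx, dy, dz)` in µm, attached to the result.
#' @param h Extended-maxima depth in distance-transform units (voxels).
#' @param connectivity Voxel connectivity (6, 18 or 26).
#' @param per_slice Run the per-slice pass before the 3D pass.
#'
#' @return A `nucleus_label_map`: a list with the integer label array
#'   (`0` = background/ridge) and a per-nucleus tibble of voxel counts,
#'   volumes (µm³), face-count surface-area estimates (µm²),
#'   surface/volume ratios (µm⁻¹) and boundary-contact flags.
#' @export
split_nuclei_watershed <- function(binary, voxel_size = c(0.21, 0.21, 0.3),
                                   h = 2, connectivity = 26L,
                                   per_slice = TRUE) {
  if (is.matrix(binary)) dim(binary) <- c(dim(binary), 1L)
  d <- dim(binary)
  if (!any(binary))
    return(new_nucleus_map(array(0L, d), voxel_size))
  work <- binary
  if (per_slice && d[3] > 1L) {
    for (k in seq_len(d[3])) {
      sl <- work[, , k, drop = FALSE]
      if (!any(sl)) next
      lab <- watershed_pass(as.vector(sl), c(d[1:2], 1L), h, connectivity)
      work[, , k] <- array(lab > 0L, d[1:2])
    }
  }
  lab3 <- watershed_pass(as.vector(work), d, h, connectivity)
  new_nucleus_map(array(lab3, d), voxel_size)
}

watershed_pass <- function(mask_vec, d, h, connectivity) {
  dist <- .edt3d(mask_vec, d[1], d[2], d[3], 1, 1, 1)
  rec <- .reconstruct_dilation(pmax(dist - h, 0), dist, mask_vec,
                               d[1], d[2], d[3], as.integer(connectivity))
  markers <- .regional_maxima(rec, mask_vec, d[1], d[2], d[3],
                              as.integer(connectivity))
  .marker_watershed(dist, markers, mask_vec, d[1], d[2], d[3],
                    as.integer(connectivity))
}

new_nucleus_map <- function(labels, voxel_size) {
  d <- dim(labels)
  vs <- as.numeric(voxel_size)
  k <- max(labels, 0L)
  if (k == 0L) {
    tab <- tibble(nucleus = integer(), voxel_count = integer(),
                  volume_um3 = numeric(), surface_um2 = numeric(),
                  sv_ratio = numeric(), touches_boundary = logical(),
                  cx_um = numeric(), cy_um = numeric(), cz_um = numeric())
  } else {
    idx <- which(labels > 0L)
    li <- labels[idx]
    co <- arrayInd(idx, d)
    cnt <- tabulate(li, nbins = k)
    surf <- surface_faces(labels, vs)
    bdry <- co[, 1] == 1L | co[, 1] == d[1] | co[, 2] == 1L | co[, 2] == d[2] |
      co[, 3] == 1L | co[, 3] == d[3]
    touches <- vapply(seq_len(k), function(l) any(bdry[li == l]), logical(1))
    grp <- factor(li, levels = seq_len(k))
    vol <- cnt * prod(vs)
    tab <- tibble(
      nucleus = seq_len(k),
      voxel_count = as.integer(cnt),
      volume_um3 = vol,
      surface_um2 = surf,
      sv_ratio = ifelse(vol > 0, surf / vol, NA_real_),
      touches_boundary = touches,
      cx_um = as.numeric(tapply((co[, 2] - 1) * vs[1], grp, mean)),
      cy_um = as.numeric(tapply((co[, 1] - 1) * vs[2], grp, mean)),
      cz_um = as.numeric(tapply((co[, 3] - 1) * vs[3], grp, mean)))
    tab <- tab[tab$voxel_count > 0L, ]
  }
  structure(list(labels = labels, voxel_size = vs, nuclei = tab),
            class = "nucleus_label_map")
}

#' @export
print.nucleus_label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<nucleus_label_map> %d nuclei on a %d x %d x %d grid\n",
              nrow(x$nuclei), d[1], d[2], d[3]))
  print(x$nuclei, ...)
  invisible(x)
}

# surface-area estimate per label: exposed voxel faces x face area.
# A face is exposed when the neighbor across it has a different label
# (or lies outside the array).
surface_faces <- function(labels, vs) {
  d <- dim(labels)
  k <- max(labels)
  face_area <- c(y = vs[1] * vs[3], x = vs[2] * vs[3], z = vs[1] * vs[2])
  surf <- numeric(k)
  count_dir <- function(shifted_ok, area) {
    # shifted_ok: logical array, TRUE where the neighbor exists and matches
    idx <- which(labels > 0L & !shifted_ok)
    if (length(idx)) {
      add <- tabulate(labels[idx], nbins = k) * area
      surf <<- surf + add
    }
  }
  same <- function(a, b) a > 0L & a == b
  pad <- -1L
  # +y / -y neighbors (first dim)
  nb <- labels[c(2:d[1], NA), , , drop = FALSE]; nb[is.na(nb)] <- pad
  count_dir(same(labels, nb), face_area["y"])
  nb <- labels[c(NA, 1:(d[1] - 1)), , , drop = FALSE]; nb[is.na(nb)] <- pad
  count_dir(same(labels, nb), face_area["y"])
  # +x / -x neighbors (second dim)
  nb <- labels[, c(2:d[2], NA), , drop = FALSE]; nb[is.na(nb)] <- pad
  count_dir(same(labels, nb), face_area["x"])
  nb <- labels[, c(NA, 1:(d[2] - 1)), , drop = FALSE]; nb[is.na(nb)] <- pad
  count_dir(same(labels, nb), face_area["x"])
  # +z / -z neighbors (third dim)
  if (d[3] > 1L) {
    nb <- labels[, , c(2:d[3], NA), drop = FALSE]; nb[is.na(nb)] <- pad
    count_dir(same(labels, nb), face_area["z"])
    nb <- labels[, , c(NA, 1:(d[3] - 1)), drop = FALSE]; nb[is.na(nb)] <- pad
    count_dir(same(labels, nb), face_area["z"])
  } else {
    surf <- surf + 2 * tabulate(labels[labels > 0L], nbins = k) *
      face_area["z"]
  }
  surf
}

#' Filter segmented nuclei by volume, shape and position
#'
#' Removes labels outside the volume bounds, labels whose surface/volume
#' ratio exceeds `sv_max` (thin or ragged objects), and — when
#' `exclude_boundary` is set — labels protruding from the image volume.
#' Surviving labels are renumbered contiguously.
#'
#' @param map A `nucleus_label_map`.
#' @param volume_range `c(v_min, v_max)` in µm³.
#' @param sv_max Maximum allowed surface/volume ratio (µm⁻¹).
#' @param exclude_boundary Drop nuclei touching any stack face.
#' @return The filtered, renumbered `nucleus_label_map`.
#' @export
filter_nucleus_objects <- function(map, volume_range = c(100, 10000),
                                   sv_max = 1.5, exclude_boundary = TRUE) {
  stopifnot(inherits(map, "nucleus_label_map"))
  if (any(volume_range <= 0) || sv_max <= 0)
    abort("volume bounds and `sv_max` must be positive.")
  tab <- map$nuclei
  keep <- tab$volume_um3 >= volume_range[1] &
    tab$volume_um3 <= volume_range[2] & tab$sv_ratio <= sv_max
  if (exclude_boundary) keep <- keep & !tab$touches_boundary
  kept <- tab$nucleus[keep]
  relab <- integer(max(map$labels, 1L))
  relab[kept] <- seq_along(kept)
  labels <- map$labels
  pos <- labels > 0L
  labels[pos] <- relab[labels[pos]]
  out_tab <- tab[keep, ]
  out_tab$nucleus <- seq_len(nrow(out_tab))
  structure(list(labels = labels, voxel_size = map$voxel_size,
                 nuclei = out_tab),
            class = "nucleus_label_map")
}

#' Segment nuclei in a DAPI stack end to end
#'
#' Convenience wrapper chaining [binarize_nuclei_slices()],
#' [split_nuclei_watershed()] and [filter_nucleus_objects()].
#'
#' @param stack An [image_stack()] (nucleus channel).
#' @param h Extended-maxima depth passed to [split_nuclei_watershed()].
#' @param volume_range,sv_max,exclude_boundary Passed to
#'   [filter_nucleus_objects()].
#' @param ... Passed to [binarize_nuclei_slices()].
#' @return A filtered `nucleus_label_map`.
#' @export
segment_nuclei <- function(stack, h = 2, volume_range = c(100, 10000),
                           sv_max = 1.5, exclude_boundary = TRUE, ...) {
  bin <- binarize_nuclei_slices(stack, ...)
  map <- split_nuclei_watershed(bin, voxel_size = stack$voxel_size, h = h)
  filter_nucleus_objects(map, volume_range = volume_range, sv_max = sv_max,
                         exclude_boundary = exclude_boundary)
}
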