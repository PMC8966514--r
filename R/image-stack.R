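#' 3D image stack with physical voxel dimensions
#'
#' Container for a single-channel confocal z-stack (or a single widefield
#' image, `nz = 1`). Intensities are stored as a numeric array with
#' dimensions `(ny, nx, nz)` — rows are y, columns are x, slices are z —
#' and the physical voxel size is carried in micrometres. Voxel centers sit
#' at integer 0-based indices, so the physical position of voxel
#' `(vz, vy, vx)` is `(vz * dz, vy * dy, vx * dx)` µm.
#'
#' @param intensities Numeric array, non-negative, `dim = c(ny, nx, nz)`.
#'   A plain matrix is treated as a single slice.
#' @param voxel_size Numeric length 3, `(dx, dy, dz)` in µm, all `> 0`.
#' @param channel Channel role, `"nucleus"` (DAPI) or `"foci"` (γ-H2AX).
#'
#' @return An `image_stack` object.
#' @export
#' @examples
#' st <- image_stack(array(rpois(8 * 8 * 3, 5), c(8, 8, 3)),
#'                   voxel_size = c(0.21, 0.21, 0.3), channel = "foci")
#' st
image_stack <- function(intensities, voxel_size = c(0.21, 0.21, 0.3),
                        channel = c("foci", "nucleus")) {
  channel <- match.arg(channel)
  if (is.matrix(intensities)) dim(intensities) <- c(dim(intensities), 1L)
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    abort("`intensities` must be a 3D array (ny, nx, nz) or a matrix.")
  if (any(dim(intensities) < 1L)) abort("all stack dimensions must be >= 1.")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    abort("`voxel_size` must be three positive values (dx, dy, dz) in um.")
  if (any(intensities < 0)) abort("intensities must be non-negative.")
  structure(
    list(intensities = intensities,
         voxel_size = as.numeric(voxel_size),
         channel = channel),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<image_stack> %s channel, %d x %d x %d (y,x,z), voxel %.3g x %.3g x %.3g um\n",
    x$channel, d[1], d[2], d[3],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$intensities)

#' Physical voxel volume of a stack in cubic micrometres
#' @param stack An [image_stack()].
#' @return Scalar volume of one voxel (µm³).
#' @export
voxel_volume <- function(stack) prod(stack$voxel_size)

#' Read / write a stack as multi-page TIFF
#'
#' One TIFF file per channel, one page per z-slice. Intensities are scaled
#' to `[0, 1]` on write (TIFF stores normalized floats/ints); the scale
#' factor is not preserved, so round-trips retain relative intensities.
#'
#' @param path TIFF file path.
#' @param voxel_size,channel Passed to [image_stack()].
#' @return `read_image_stack()` returns an [image_stack()];
#'   `write_image_stack()` returns `path` invisibly.
#' @export
read_image_stack <- function(path, voxel_size = c(0.21, 0.21, 0.3),
                             channel = c("foci", "nucleus")) {
  channel <- match.arg(channel)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # drop extra samples
    arr[, , k] <- pg
  }
  image_stack(arr, voxel_size = voxel_size, channel = channel)
}

#' @param stack An [image_stack()] (or, for label maps, an integer array).
#' @param bits Bits per sample on disk (8 or 16).
#' @rdname read_image_stack
#' @export
write_image_stack <- function(stack, path, bits = 16L) {
  arr <- if (inherits(stack, "image_stack")) stack$intensities else stack
  if (is.matrix(arr)) dim(arr) <- c(dim(arr), 1L)
  hi <- max(arr, 1e-12)
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / hi)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}
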