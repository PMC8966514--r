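#' Autocorrelation-based blind drift correction
#'
#' Estimates lateral stage drift from the localization data alone: the
#' acquisition is cut into temporal bins of `bin_frames` frames, each bin
#' is rendered as a 2D position histogram, and the shift of every bin
#' relative to the first is found at the image cross-correlation peak with
#' parabolic sub-pixel refinement. Per-bin shifts are interpolated
#' linearly to individual frames (extrapolating the end segments) and
#' subtracted.
#'
#' @param table Localization tibble with `frame`, `x_nm`, `y_nm`.
#' @param bin_frames Frames per temporal bin.
#' @param pixel_nm Rendering pixel size of the correlation histograms.
#' @param min_per_bin Minimum localizations required in every bin.
#'
#' @return The table with added `x_corr_nm`, `y_corr_nm` columns.
#'   Attribute `bin_shifts` holds the per-bin shift estimates (nm) and
#'   attribute `total_drift_nm` the span of the interpolated per-frame
#'   drift over the acquisition.
#' @export
drift_correct <- function(table, bin_frames = 2000L, pixel_nm = 10,
                          min_per_bin = 50L) {
  stopifnot(all(c("frame", "x_nm", "y_nm") %in% names(table)))
  if (nrow(table) == 0L) abort("empty localization table.")
  bin <- floor(table$frame / bin_frames)
  bins <- sort(unique(bin))
  if (length(bins) < 2L) {
    out <- mutate(table, x_corr_nm = .data$x_nm, y_corr_nm = .data$y_nm)
    attr(out, "bin_shifts") <-
      tibble(bin = bins, frame_center = mean(range(table$frame)),
             dx_nm = 0, dy_nm = 0)
    attr(out, "total_drift_nm") <- 0
    return(out)
  }
  counts <- tabulate(match(bin, bins))
  if (any(counts < min_per_bin))
    abort(sprintf(
      "temporal bin with only %d localizations (need >= %d); increase `bin_frames`.",
      min(counts), min_per_bin))

  xr <- range(table$x_nm); yr <- range(table$y_nm)
  nx <- next_even(ceiling((xr[2] - xr[1]) / pixel_nm) + 4L)
  ny <- next_even(ceiling((yr[2] - yr[1]) / pixel_nm) + 4L)
  render <- function(i) {
    ix <- pmin(floor((table$x_nm[i] - xr[1]) / pixel_nm) + 1L, nx)
    iy <- pmin(floor((table$y_nm[i] - yr[1]) / pixel_nm) + 1L, ny)
    matrix(tabulate(iy + (ix - 1L) * ny, nbins = ny * nx), ny, nx)
  }
  ref <- render(which(bin == bins[1]))
  fref <- fft(ref)
  shifts <- matrix(0, length(bins), 2)
  for (k in seq_along(bins)[-1]) {
    img <- render(which(bin == bins[k]))
    cc <- Re(fft(Conj(fref) * fft(img), inverse = TRUE))
    pk <- arrayInd(which.max(cc), dim(cc))
    dyp <- refine_peak(cc, pk, ny, nx, axis = 1)
    dxp <- refine_peak(cc, pk, ny, nx, axis = 2)
    shifts[k, ] <- c(wrap_shift(pk[2] - 1 + dxp, nx),
                     wrap_shift(pk[1] - 1 + dyp, ny)) * pixel_nm
  }
  centers <- (bins + 0.5) * bin_frames
  fr <- table$frame
  sx <- interp_extrap(centers, shifts[, 1], fr)
  sy <- interp_extrap(centers, shifts[, 2], fr)
  out <- mutate(table, x_corr_nm = .data$x_nm - sx,
                y_corr_nm = .data$y_nm - sy)
  attr(out, "bin_shifts") <- tibble(bin = bins, frame_center = centers,
                                    dx_nm = shifts[, 1], dy_nm = shifts[, 2])
  attr(out, "total_drift_nm") <-
    sqrt((max(sx) - min(sx))^2 + (max(sy) - min(sy))^2)
  out
}

next_even <- function(n) if (n %% 2L == 0L) n else n + 1L

# wrap an FFT-periodic shift into (-n/2, n/2]
wrap_shift <- function(s, n) ifelse(s > n / 2, s - n, s)

# parabolic sub-pixel refinement of the correlation peak along one axis
refine_peak <- function(cc, pk, ny, nx, axis) {
  i <- pk[1]; j <- pk[2]
  get <- function(di, dj) {
    cc[(i - 1 + di) %% ny + 1, (j - 1 + dj) %% nx + 1]
  }
  cm <- if (axis == 1) get(-1, 0) else get(0, -1)
  c0 <- get(0, 0)
  cp <- if (axis == 1) get(1, 0) else get(0, 1)
  den <- cm - 2 * c0 + cp
  if (abs(den) < 1e-12) return(0)
  d <- 0.5 * (cm - cp) / den
  max(min(d, 0.5), -0.5)
}

# linear interpolation with linear end-segment extrapolation
interp_extrap <- function(x, y, xout) {
  if (length(x) == 1L) return(rep(y, length(xout)))
  out <- approx(x, y, xout, rule = 2)$y
  n <- length(x)
  lo <- xout < x[1]
  hi <- xout > x[n]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  if (any(hi)) {
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  out
}
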