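#' Density-based clustering (DBSCAN) of localizations
#'
#' Standard DBSCAN on the lateral coordinates: a point with at least
#' `minPts` neighbors within `eps` (itself included) is a core point;
#' clusters are the connected sets of core points plus their border
#' points; everything else is noise. Drift-corrected coordinates
#' (`x_corr_nm`, `y_corr_nm`) are used when present.
#'
#' @param table Localization tibble (`x_nm`, `y_nm`, optionally the
#'   corrected columns).
#' @param eps Neighborhood radius in nm.
#' @param minPts Minimum neighborhood size of a core point.
#'
#' @return A tibble of class `storm_clusters`, one row per cluster:
#'   `cluster`, `n_loc`, `cx_nm`, `cy_nm` (geometric center of member
#'   coordinates), `nucleus` (`NA` until assigned) and list-column
#'   `members` (row indices into `table`). Attributes: `noise` (indices of
#'   noise points), `coords` (the coordinate matrix used), `eps`, `minPts`.
#' @export
dbscan_clusters <- function(table, eps = 50, minPts = 10L) {
  if (eps <= 0) abort("`eps` must be > 0.")
  if (minPts < 1L) abort("`minPts` must be >= 1.")
  co <- localization_coords(table)
  cl <- if (nrow(co)) .dbscan2d(co[, 1], co[, 2], eps, as.integer(minPts))
        else integer()
  k <- max(cl, 0L)
  if (k == 0L) {
    out <- tibble(cluster = integer(), n_loc = integer(), cx_nm = numeric(),
                  cy_nm = numeric(), nucleus = integer(), members = list())
  } else {
    members <- unname(split(seq_len(nrow(co)), factor(cl, levels = seq_len(k))))
    out <- tibble(
      cluster = seq_len(k),
      n_loc = vapply(members, length, integer(1)),
      cx_nm = vapply(members, function(i) mean(co[i, 1]), numeric(1)),
      cy_nm = vapply(members, function(i) mean(co[i, 2]), numeric(1)),
      nucleus = NA_integer_,
      members = members)
  }
  structure(out,
            noise = which(cl == 0L), coords = co,
            eps = eps, minPts = as.integer(minPts),
            class = c("storm_clusters", class(tibble())))
}

localization_coords <- function(table) {
  if (all(c("x_corr_nm", "y_corr_nm") %in% names(table)))
    cbind(x = table$x_corr_nm, y = table$y_corr_nm)
  else if (all(c("x_nm", "y_nm") %in% names(table)))
    cbind(x = table$x_nm, y = table$y_nm)
  else abort("table must carry `x_nm`/`y_nm` (or corrected) coordinates.")
}
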