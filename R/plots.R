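#' @export
tidy.foci_clusters <- function(x, ...) {
  out <- as_tibble(x)
  out$voxels <- NULL
  out
}

#' @export
tidy.storm_clusters <- function(x, ...) {
  out <- as_tibble(x)
  out$members <- NULL
  out
}

#' @export
tidy.nucleus_label_map <- function(x, ...) x$nuclei

#' @export
glance.nucleus_label_map <- function(x, ...) {
  tibble(n_nuclei = nrow(x$nuclei),
         total_volume_um3 = sum(x$nuclei$volume_um3),
         mean_sv_ratio = mean(x$nuclei$sv_ratio))
}

#' Plot foci cluster centroids sized by volume
#'
#' Lateral (x, y) positions of the detected γ-H2AX clusters, point size
#' proportional to cluster volume, colored by assigned nucleus.
#'
#' @param object A `foci_clusters` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.foci_clusters <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(.data$cx_um, .data$cy_um,
                                    size = .data$volume_um3,
                                    colour = factor(.data$nucleus))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  size = expression(volume ~ (mu * m^3)),
                  colour = "nucleus") +
    ggplot2::theme_minimal()
}

#' Plot dSTORM clusters over their localizations
#'
#' @param object A `storm_clusters` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.storm_clusters <- function(object, ...) {
  co <- attr(object, "coords")
  pts <- tibble(x = co[, 1], y = co[, 2], cluster = NA_integer_)
  for (i in seq_len(nrow(object)))
    pts$cluster[object$members[[i]]] <- object$cluster[i]
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y,
                                    colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted blinking model over the count histogram
#'
#' @param object An `epitope_fit`.
#' @param counts The localization-count sample the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epitope_fit <- function(object, counts, ...) {
  kmax <- max(counts)
  obs <- tabulate(counts, nbins = kmax) / length(counts)
  fitted <- blink_pmf(seq_len(kmax), object$max_dyes, object$efficiency,
                      object$q)
  tab <- tibble(k = rep(seq_len(kmax), 2),
                p = c(obs, fitted),
                what = rep(c("observed", "fitted"), each = kmax))
  ggplot2::ggplot(tab, ggplot2::aes(.data$k, .data$p, fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "localizations per cluster", y = "probability",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of a five-zone radial density profile
#'
#' @param zones The tibble returned by [radial_density_profile()].
#' @return A ggplot object.
#' @export
plot_radial_profile <- function(zones) {
  ggplot2::ggplot(zones, ggplot2::aes(factor(.data$zone),
                                      .data$density_per_um2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "zone (1 = center, 5 = envelope)",
                  y = expression(clusters ~ per ~ mu * m^2)) +
    ggplot2::theme_minimal()
}
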