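#' Fit the fluorophore blinking model to single-epitope counts
#'
#' Maximum-likelihood fit of the compound blinking model used to convert
#' localization counts into epitope numbers: the number of detected dyes
#' on one epitope follows `Binomial(max_dyes, efficiency)` truncated to
#' `>= 1` (an undetected epitope produces no cluster), and each dye yields
#' `Geometric(q)` localizations on support `{1, 2, ...}`. The fitted mean
#' localizations per detected epitope is
#' `mu = E[dyes | dyes >= 1] / q`.
#'
#' Photophysics varies across the field of view with illumination
#' intensity, so one fit is made per field tile (see
#' [fit_epitope_tiles()]).
#'
#' When the calibration sample comes from a density-based cluster
#' detection, clusters with fewer than `minPts` localizations are never
#' observed; passing that detection floor as `truncate_at` conditions the
#' likelihood on `N >= truncate_at` and removes the selection bias.
#'
#' @param counts Integer localization counts of clusters attributed to
#'   single epitopes; all `>= 1`, at least `min_sample` of them.
#' @param max_dyes Maximum dyes per epitope, `M` (fixed, not fitted).
#' @param tile Optional tile bounds `c(xmin, xmax, ymin, ymax)` in nm,
#'   recorded in the fit.
#' @param min_sample Minimum sample size.
#' @param truncate_at Left-truncation point of the observed counts (the
#'   cluster-detection `minPts`); 1 means no truncation.
#'
#' @return An object of class `epitope_fit` with elements `q`,
#'   `efficiency`, `mu`, `max_dyes`, `loglik`, `gof_stat`, `gof_df`,
#'   `gof_p`, `n`, `tile`.
#' @export
#' @examples
#' cts <- rgeom(500, 0.2) + 1
#' fit <- fit_epitope_model(cts, max_dyes = 1)
#' fit$mu
fit_epitope_model <- function(counts, max_dyes = 3L, tile = NULL,
                              min_sample = 100L, truncate_at = 1L) {
  counts <- as.integer(counts)
  if (length(counts) < min_sample)
    abort(sprintf("sample too small: %d single-epitope counts (need >= %d).",
                  length(counts), min_sample))
  if (any(counts < 1L)) abort("all localization counts must be >= 1.")
  M <- as.integer(max_dyes)
  if (M < 1L) abort("`max_dyes` must be >= 1.")
  trunc <- max(as.integer(truncate_at), 1L)
  if (any(counts < trunc)) {
    # clusters can fall below the detection floor when border points were
    # claimed by a neighbor; they sit outside the truncated model
    counts <- counts[counts >= trunc]
    if (length(counts) < min_sample)
      abort(sprintf(
        "sample too small after truncation at %d: %d counts (need >= %d).",
        trunc, length(counts), min_sample))
  }

  if (M == 1L && trunc == 1L) {
    q <- 1 / mean(counts)
    eta <- 1
    ll <- sum(log(blink_pmf(counts, M, eta, q)))
  } else {
    nll <- function(par) {
      eta <- if (M == 1L) 1 else plogis(par[1])
      q <- plogis(par[length(par)])
      p <- blink_pmf(counts, M, eta, q, truncate_at = trunc)
      if (any(p <= 0) || any(!is.finite(p))) return(1e12)
      -sum(log(p))
    }
    q0 <- min(0.9, max(0.02, 1 / mean(counts)))
    if (M == 1L) {
      opt <- optim(qlogis(q0), nll, method = "Brent", lower = -12, upper = 12)
    } else {
      # the (efficiency, q) surface has ridges: take the best of a small
      # grid of starts
      starts <- expand.grid(eta = c(0.3, 0.6, 0.9),
                            q = unique(pmin(c(q0, 2 * q0), 0.95)))
      opt <- NULL
      for (s in seq_len(nrow(starts))) {
        o <- optim(c(qlogis(starts$eta[s]), qlogis(starts$q[s])), nll,
                   method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10))
        if (is.null(opt) || o$value < opt$value) opt <- o
      }
    }
    eta <- if (M == 1L) 1 else plogis(opt$par[1])
    q <- plogis(opt$par[length(opt$par)])
    if (opt$convergence != 0)
      abort(
        sprintf("blinking-model fit did not converge (code %d); best-so-far efficiency = %.4f, q = %.4f.",
                opt$convergence, eta, q),
        class = "fociquant_fit_error", efficiency = eta, q = q)
    ll <- -opt$value
  }
  mu <- mean_dyes_detected(M, eta) / q
  gof <- blink_gof(counts, M, eta, q, n_par = if (M == 1L) 1L else 2L,
                   truncate_at = trunc)
  structure(list(q = q, efficiency = eta, mu = mu, max_dyes = M,
                 loglik = ll, gof_stat = gof$stat, gof_df = gof$df,
                 gof_p = gof$p, n = length(counts), tile = tile),
            class = "epitope_fit")
}

# E[D | D >= 1], D ~ Binomial(M, eta)
mean_dyes_detected <- function(M, eta) {
  p0 <- (1 - eta)^M
  if (p0 >= 1) return(NaN)
  M * eta / (1 - p0)
}

# P(N = n) for N = sum of D geometric(q) variables (support >= 1 each),
# D ~ Binomial(M, eta) truncated >= 1. The sum of d such geometrics is
# d + NegBinomial(d, q). With `truncate_at` > 1 the pmf is conditioned on
# N >= truncate_at (detection floor of the clustering step).
blink_pmf <- function(n, M, eta, q, truncate_at = 1L) {
  p0 <- (1 - eta)^M
  wd <- dbinom(seq_len(M), M, eta) / (1 - p0)
  pm <- function(k) {
    out <- numeric(length(k))
    for (d in seq_len(M))
      out <- out + wd[d] * stats::dnbinom(k - d, size = d, prob = q)
    out
  }
  out <- pm(n)
  if (truncate_at > 1L) {
    below <- sum(pm(seq_len(truncate_at - 1L)))
    out <- ifelse(n >= truncate_at, out / max(1 - below, 1e-12), 0)
  }
  out
}

# chi-square goodness of fit on the count histogram, pooling the tail so
# every expected cell count is >= 5
blink_gof <- function(counts, M, eta, q, n_par, truncate_at = 1L) {
  n <- length(counts)
  kmax <- max(counts)
  obs <- tabulate(counts, nbins = kmax)
  exp_p <- blink_pmf(seq_len(kmax), M, eta, q, truncate_at = truncate_at)
  exp_p <- c(exp_p, max(1 - sum(exp_p), 0))  # tail mass
  obs <- c(obs, 0)
  expd <- exp_p * n
  # pool from the right until all cells reach expected >= 5
  while (length(expd) > 2L && min(expd) < 5) {
    i <- which.min(expd)
    j <- if (i == length(expd)) i - 1L else i + 1L
    expd[j] <- expd[j] + expd[i]; obs[j] <- obs[j] + obs[i]
    expd <- expd[-i]; obs <- obs[-i]
  }
  stat <- sum((obs - expd)^2 / expd)
  df <- max(length(expd) - 1L - n_par, 1L)
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' @export
print.epitope_fit <- function(x, ...) {
  cat(sprintf(
    "<epitope_fit> q = %.4f, efficiency = %.3f (M = %d), mu = %.2f loc/epitope, n = %d\n",
    x$q, x$efficiency, x$max_dyes, x$mu, x$n))
  cat(sprintf("  GoF chi-square %.2f on %d df (p = %.3g)\n",
              x$gof_stat, x$gof_df, x$gof_p))
  invisible(x)
}

#' @export
tidy.epitope_fit <- function(x, ...) {
  tibble(term = c("q", "efficiency", "mu"),
         estimate = c(x$q, x$efficiency, x$mu))
}

#' @export
glance.epitope_fit <- function(x, ...) {
  tibble(q = x$q, efficiency = x$efficiency, mu = x$mu,
         max_dyes = x$max_dyes, logLik = x$loglik, gof_stat = x$gof_stat,
         gof_df = x$gof_df, gof_p = x$gof_p, nobs = x$n)
}

#' Per-tile blinking-model calibration
#'
#' Cuts the field of view into a grid of tiles and fits the blinking model
#' separately in each, using the localization counts of calibration
#' clusters: isolated clusters small enough (hull diameter below
#' `max_diameter_nm`) to be attributed to a single labeled epitope.
#' Regional fits absorb the spatial variation of dye photophysics with
#' illumination intensity.
#'
#' Calibration clusters are selected by apparent size: the Gaussian FWHM
#' implied by the RMS radial scatter of the member localizations. Unlike a
#' convex-hull extent, this measure does not grow with the localization
#' count, so bright single epitopes are not excluded (which would
#' right-truncate the count histogram and bias the fitted mean).
#'
#' @param clusters A `storm_clusters` tibble with hull areas
#'   ([add_hull_areas()]).
#' @param n_tiles `c(nx, ny)` grid of tiles.
#' @param fov Field bounds `c(xmin, xmax, ymin, ymax)` nm; default is the
#'   bounding box of the cluster centers.
#' @param max_diameter_nm Apparent-size cutoff (nm) selecting
#'   single-epitope calibration clusters; labeled structures image at
#'   about 40-50 nm.
#' @param max_dyes,min_sample Passed to [fit_epitope_model()].
#'
#' @return A list of class `epitope_calibration`: `fits` (list indexed by
#'   tile, `NULL` where too few calibration clusters), `tiles` (tibble of
#'   tile bounds and sample sizes), `n_tiles`, `fov`.
#' @export
fit_epitope_tiles <- function(clusters, n_tiles = c(4L, 4L), fov = NULL,
                              max_diameter_nm = 60, max_dyes = 3L,
                              min_sample = 100L,
                              truncate_at = attr(clusters, "minPts")) {
  stopifnot(inherits(clusters, "storm_clusters"))
  truncate_at <- truncate_at %||% 1L
  if (!"hull_area_um2" %in% names(clusters))
    clusters <- add_hull_areas(clusters)
  if (is.null(fov))
    fov <- c(min(clusters$cx_nm), max(clusters$cx_nm),
             min(clusters$cy_nm), max(clusters$cy_nm))
  co <- attr(clusters, "coords")
  calib <- apparent_diameter(clusters, co) <= max_diameter_nm

  tx <- tile_index(clusters$cx_nm, fov[1], fov[2], n_tiles[1])
  ty <- tile_index(clusters$cy_nm, fov[3], fov[4], n_tiles[2])
  tid <- (ty - 1L) * n_tiles[1] + tx

  fits <- vector("list", prod(n_tiles))
  rows <- vector("list", prod(n_tiles))
  for (t in seq_len(prod(n_tiles))) {
    ix <- (t - 1L) %% n_tiles[1] + 1L
    iy <- (t - 1L) %/% n_tiles[1] + 1L
    bounds <- c(fov[1] + (ix - 1L) * (fov[2] - fov[1]) / n_tiles[1],
                fov[1] + ix * (fov[2] - fov[1]) / n_tiles[1],
                fov[3] + (iy - 1L) * (fov[4] - fov[3]) / n_tiles[2],
                fov[3] + iy * (fov[4] - fov[3]) / n_tiles[2])
    cts <- clusters$n_loc[calib & tid == t]
    fit <- NULL
    if (length(cts) >= min_sample)
      fit <- fit_epitope_model(cts, max_dyes = max_dyes, tile = bounds,
                               min_sample = min_sample,
                               truncate_at = truncate_at)
    fits[t] <- list(fit)  # keep NULL slots (([[<- NULL)) would drop them)
    rows[[t]] <- tibble(tile = t, xmin = bounds[1], xmax = bounds[2],
                        ymin = bounds[3], ymax = bounds[4],
                        n_calibration = length(cts),
                        fitted = !is.null(fit),
                        mu = if (is.null(fit)) NA_real_ else fit$mu)
  }
  structure(list(fits = fits, tiles = bind_rows(rows),
                 n_tiles = as.integer(n_tiles), fov = fov),
            class = "epitope_calibration")
}

tile_index <- function(x, lo, hi, n) {
  pmin(pmax(floor((x - lo) / max(hi - lo, 1e-9) * n) + 1L, 1L), n)
}

# apparent size of each cluster: Gaussian FWHM implied by the RMS radial
# scatter of its member localizations (count-independent, unlike a hull
# extent). Single-point clusters get size 0.
apparent_diameter <- function(clusters, coords) {
  vapply(seq_len(nrow(clusters)), function(k) {
    i <- clusters$members[[k]]
    if (length(i) < 2L) return(0)
    dx <- coords[i, 1] - clusters$cx_nm[k]
    dy <- coords[i, 2] - clusters$cy_nm[k]
    sigma <- sqrt(mean(dx^2 + dy^2) / 2)   # per-axis SD
    2.355 * sigma                          # FWHM
  }, numeric(1))
}

#' Estimate epitope numbers per cluster
#'
#' Divides each cluster's localization count by the calibrated mean
#' localizations per epitope of its field tile (or of a single global
#' fit) and rounds; non-noise clusters get at least one epitope.
#'
#' @param clusters A `storm_clusters` tibble.
#' @param fit An `epitope_fit` (global) or `epitope_calibration`
#'   (per-tile) object.
#' @return `clusters` with an `epitope_estimate` integer column.
#' @export
estimate_epitopes <- function(clusters, fit) {
  stopifnot(inherits(clusters, "storm_clusters"))
  if (inherits(fit, "epitope_fit")) {
    mu <- rep(fit$mu, nrow(clusters))
  } else if (inherits(fit, "epitope_calibration")) {
    tx <- tile_index(clusters$cx_nm, fit$fov[1], fit$fov[2], fit$n_tiles[1])
    ty <- tile_index(clusters$cy_nm, fit$fov[3], fit$fov[4], fit$n_tiles[2])
    tid <- (ty - 1L) * fit$n_tiles[1] + tx
    mu <- vapply(tid, function(t) {
      f <- fit$fits[[t]]
      if (is.null(f)) NA_real_ else f$mu
    }, numeric(1))
    if (any(is.na(mu))) {
      bad <- sort(unique(tid[is.na(mu)]))
      abort(sprintf(
        "no blinking-model fit available for tile(s) %s; supply more calibration clusters or fewer tiles.",
        paste(bad, collapse = ", ")))
    }
  } else {
    abort("`fit` must be an `epitope_fit` or `epitope_calibration`.")
  }
  out <- clusters
  out$epitope_estimate <- pmax(as.integer(round(out$n_loc / mu)), 1L)
  out
}
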