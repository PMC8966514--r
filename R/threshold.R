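#' Maximum-entropy (Kapur) intensity threshold
#'
#' Picks the threshold `t` maximizing the sum of the Shannon entropies of
#' the background (`intensity <= t`) and foreground (`intensity > t`)
#' partitions of the intensity histogram. Images with few distinct values
#' are thresholded over those exact values; continuous images are first
#' binned into `n_bins` equal-width levels. Ties are broken toward the
#' smallest threshold.
#'
#' @param stack An [image_stack()], or a numeric array/vector of
#'   intensities.
#' @param n_bins Number of histogram bins used when the image has more
#'   distinct values than `n_bins`.
#'
#' @return The scalar threshold, on the intensity scale of the input;
#'   foreground is `intensity > t`.
#' @export
#' @examples
#' x <- c(rep(10, 50), rep(200, 50))
#' max_entropy_threshold(x)  # 10
max_entropy_threshold <- function(stack, n_bins = 256L) {
  v <- if (inherits(stack, "image_stack")) as.vector(stack$intensities)
       else as.vector(stack)
  v <- v[is.finite(v)]
  if (length(v) == 0L) abort("no finite intensities to threshold.")
  lev <- sort(unique(v))
  if (length(lev) < 2L)
    abort("cannot threshold a constant image: the intensity histogram is degenerate.")
  if (length(lev) <= n_bins) {
    counts <- tabulate(match(v, lev))
    values <- lev
  } else {
    br <- seq(lev[1], lev[length(lev)], length.out = n_bins + 1L)
    idx <- pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L), n_bins)
    counts <- tabulate(idx, nbins = n_bins)
    values <- br[-1L]  # bin upper edges: "> t" keeps strictly higher bins
  }
  k <- kapur_argmax(counts)
  values[k]
}

# index of the Kapur-criterion argmax over cut positions 1..(K-1);
# cut k puts bins 1..k in the background. Ties -> smallest k.
kapur_argmax <- function(counts) {
  p <- counts / sum(counts)
  K <- length(p)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P0 <- cumsum(p)[-K]
  S0 <- cumsum(plogp)[-K]
  P1 <- 1 - P0
  S1 <- sum(plogp) - S0
  crit <- rep(-Inf, K - 1L)
  ok <- P0 > 0 & P1 > 0
  # H_b + H_f = log(P0) - S0/P0 + log(P1) - S1/P1
  crit[ok] <- log(P0[ok]) - S0[ok] / P0[ok] + log(P1[ok]) - S1[ok] / P1[ok]
  if (!any(is.finite(crit)))
    abort("cannot threshold: the intensity histogram is degenerate.")
  which.max(crit)
}
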