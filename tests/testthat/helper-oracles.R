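# Independent oracles used to cross-check the package implementations.
# These deliberately take the slow, direct route.

# breadth-first flood fill over a binary 3D mask; labels in scan order
bfs_flood_fill <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  off <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  off <- off[!(off$dy == 0 & off$dx == 0 & off$dz == 0), ]
  m <- abs(off$dy) + abs(off$dx) + abs(off$dz)
  if (connectivity == 6L) off <- off[m == 1, ]
  if (connectivity == 18L) off <- off[m <= 2, ]
  lab <- array(0L, d)
  nxt <- 0L
  for (i0 in which(mask & lab == 0L)) {
    if (lab[i0] != 0L) next
    nxt <- nxt + 1L
    queue <- i0
    lab[i0] <- nxt
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pc <- arrayInd(p, d)
      for (r in seq_len(nrow(off))) {
        q <- pc + c(off$dy[r], off$dx[r], off$dz[r])
        if (any(q < 1L) || any(q > d)) next
        qi <- q[1] + d[1] * (q[2] - 1L + d[2] * (q[3] - 1L))
        if (mask[qi] && lab[qi] == 0L) {
          lab[qi] <- nxt
          queue <- c(queue, qi)
        }
      }
    }
  }
  lab
}

# two labelings agree up to renaming iff the label-pair mapping is 1:1
same_partition <- function(a, b) {
  av <- as.vector(a); bv <- as.vector(b)
  if (!identical(av > 0L, bv > 0L)) return(FALSE)
  pos <- av > 0L
  pairs <- unique(cbind(av[pos], bv[pos]))
  !anyDuplicated(pairs[, 1]) && !anyDuplicated(pairs[, 2])
}

# exhaustive maximum-entropy threshold search over all candidate cuts
kapur_oracle <- function(values, counts) {
  n <- sum(counts)
  best <- -Inf; best_t <- NA
  for (k in seq_len(length(values) - 1L)) {
    p0 <- counts[1:k] / n
    p1 <- counts[(k + 1):length(counts)] / n
    P0 <- sum(p0); P1 <- sum(p1)
    if (P0 == 0 || P1 == 0) next
    hb <- -sum(ifelse(p0 > 0, p0 / P0 * log(p0 / P0), 0))
    hf <- -sum(ifelse(p1 > 0, p1 / P1 * log(p1 / P1), 0))
    if (hb + hf > best + 1e-12) { best <- hb + hf; best_t <- values[k] }
  }
  best_t
}

# textbook DBSCAN by neighbor-graph expansion on the full distance matrix
dbscan_oracle <- function(x, y, eps, minPts) {
  n <- length(x)
  if (n == 0L) return(integer())
  D <- as.matrix(dist(cbind(x, y)))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))  # includes self
  core <- vapply(nb, length, integer(1)) >= minPts
  cl <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (cl[i] != 0L || !core[i]) next
    nxt <- nxt + 1L
    queue <- i
    cl[i] <- nxt
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      if (!core[p]) next
      for (q in nb[[p]]) {
        if (cl[q] == 0L) {
          cl[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  cl
}

# greedy matching of detected cluster centroids to ground-truth foci
match_foci <- function(clusters, truth, tol_um = 0.5) {
  if (nrow(clusters) == 0L || nrow(truth) == 0L)
    return(c(recall = 0, precision = 0))
  D <- sqrt(outer(clusters$cx_um, truth$x_um, "-")^2 +
              outer(clusters$cy_um, truth$y_um, "-")^2 +
              outer(clusters$cz_um, truth$z_um, "-")^2)
  used <- rep(FALSE, nrow(truth))
  matched <- 0L
  for (i in order(apply(D, 1, min))) {
    j <- which.min(ifelse(used, Inf, D[i, ]))
    if (length(j) && D[i, j] < tol_um) { matched <- matched + 1L; used[j] <- TRUE }
  }
  c(recall = matched / nrow(truth), precision = matched / nrow(clusters))
}

# minimal nucleus_regions object with a disk-shaped region of known size
disk_region <- function(radius_px = 50L, pixel_nm = 100, pad = 5L) {
  n <- 2L * (radius_px + pad) + 1L
  ctr <- radius_px + pad + 1L
  lab <- matrix(0L, n, n)
  for (i in seq_len(n))
    lab[i, which((i - ctr)^2 + (seq_len(n) - ctr)^2 <= radius_px^2)] <- 1L
  structure(list(
    labels = lab, pixel_nm = pixel_nm,
    regions = tibble::tibble(
      nucleus = 1L, area_um2 = sum(lab) * (pixel_nm / 1000)^2,
      cx_nm = ctr * pixel_nm, cy_nm = ctr * pixel_nm,
      touches_boundary = FALSE)),
    class = "nucleus_regions")
}

# uniform points inside a labeled region (complete spatial randomness)
csr_in_region <- function(region, n) {
  px <- region$pixel_nm
  idx <- which(region$labels == 1L)
  pick <- sample(idx, n, replace = TRUE)
  co <- arrayInd(pick, dim(region$labels))
  tibble::tibble(
    cluster = seq_len(n), nucleus = 1L,
    cx_nm = (co[, 2] - 1L + runif(n)) * px,
    cy_nm = (co[, 1] - 1L + runif(n)) * px)
}
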