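make_disk_stack <- function(n = 64L, r = 20L, nz = 1L, amp = 100) {
  a <- array(0, c(n, n, nz))
  ctr <- n / 2
  for (i in seq_len(n))
    a[i, which((i - ctr)^2 + (seq_len(n) - ctr)^2 <= r^2), ] <- amp
  a
}

test_that("all-zero stack raises a degenerate-threshold error", {
  st <- image_stack(array(0, c(64, 64, 2)), channel = "nucleus")
  expect_error(binarize_nuclei_slices(st), "degenerate")
})

test_that("slices smaller than the opening element are rejected", {
  st <- image_stack(array(runif(10 * 10 * 2), c(10, 10, 2)),
                    channel = "nucleus")
  expect_error(binarize_nuclei_slices(st), "structuring element")
})

test_that("a bright disk yields one hole-free mask containing the disk", {
  set.seed(31)
  a <- make_disk_stack(n = 96L, r = 25L) + rnorm(96 * 96, 0, 2)
  st <- image_stack(array(pmax(a, 0), c(96, 96, 1)), channel = "nucleus")
  bin <- binarize_nuclei_slices(st)
  disk <- make_disk_stack(n = 96L, r = 22L) > 0  # interior, off the rim
  expect_true(all(bin[disk]))
  lab <- bfs_flood_fill(bin, 26L)
  expect_equal(max(lab), 1L)
  filled <- EBImage::fillHull(bin[, , 1])
  expect_equal(sum(filled > 0), sum(bin))     # no holes
})

test_that("watershed labels isolated blobs separately", {
  m <- array(FALSE, c(40, 40, 1))
  m[5:15, 5:15, 1] <- TRUE
  expect_equal(nrow(split_nuclei_watershed(m, c(1, 1, 1))$nuclei), 1L)
  m[25:35, 25:35, 1] <- TRUE
  expect_equal(nrow(split_nuclei_watershed(m, c(1, 1, 1))$nuclei), 2L)
})

test_that("watershed splits two overlapping spheres near their true centers", {
  # centers 1.5 radii apart
  r <- 10; c1 <- c(20, 20); c2 <- c(20, 35)
  m <- array(FALSE, c(40, 56, 1))
  for (i in 1:40) for (j in 1:56)
    m[i, j, 1] <- (i - c1[1])^2 + (j - c1[2])^2 <= r^2 ||
      (i - c2[1])^2 + (j - c2[2])^2 <= r^2
  map <- split_nuclei_watershed(m, c(1, 1, 1), h = 2)
  expect_equal(nrow(map$nuclei), 2L)
  got <- map$nuclei[order(map$nuclei$cx_um), ]
  expect_lt(abs(got$cx_um[1] - (c1[2] - 1)), 2)
  expect_lt(abs(got$cy_um[1] - (c1[1] - 1)), 2)
  expect_lt(abs(got$cx_um[2] - (c2[2] - 1)), 2)
  expect_lt(abs(got$cy_um[2] - (c2[1] - 1)), 2)
})

test_that("watershed output partitions the foreground", {
  set.seed(404)
  # blobs drawn as unions of random spheres in 3D
  m <- array(FALSE, c(30, 30, 10))
  for (b in 1:4) {
    ctr <- c(sample(8:22, 2), sample(3:8, 1))
    r <- sample(4:7, 1)
    for (i in 1:30) for (j in 1:30) for (k in 1:10)
      if ((i - ctr[1])^2 + (j - ctr[2])^2 + ((k - ctr[3]) * 2)^2 <= r^2)
        m[i, j, k] <- TRUE
  }
  map <- split_nuclei_watershed(m, c(1, 1, 1))
  lab <- map$labels
  # labels only on foreground; every foreground voxel is label or ridge
  expect_true(all(lab[!m] == 0L))
  expect_true(all(lab[m] >= 0L))
  expect_equal(sum(map$nuclei$voxel_count) + sum(lab[m] == 0L), sum(m))
  # each label is connected under 26-connectivity
  for (l in map$nuclei$nucleus)
    expect_equal(max(bfs_flood_fill(lab == l, 26L)), 1L)
})

test_that("empty foreground gives an empty label map", {
  map <- split_nuclei_watershed(array(FALSE, c(10, 10, 2)), c(1, 1, 1))
  expect_equal(nrow(map$nuclei), 0L)
})

test_that("boundary-protruding nuclei are filtered out", {
  labels <- array(0L, c(20, 20, 6))
  labels[1:6, 5:10, 2:5] <- 1L        # touches y = 0 face
  labels[10:15, 5:10, 2:5] <- 2L      # interior
  map <- fociquant:::new_nucleus_map(labels, c(1, 1, 1))
  filt <- filter_nucleus_objects(map, volume_range = c(1, 1e5), sv_max = 10,
                                 exclude_boundary = TRUE)
  expect_equal(nrow(filt$nuclei), 1L)
  expect_equal(sort(unique(as.vector(filt$labels))), c(0L, 1L))
  expect_false(filt$nuclei$touches_boundary)
})

test_that("surface/volume ratio separates a sphere from a filament", {
  labels <- array(0L, c(24, 24, 24))
  r <- 8; ctr <- 12
  for (i in 1:24) for (j in 1:24) for (k in 1:24)
    if ((i - ctr)^2 + (j - ctr)^2 + (k - ctr)^2 <= r^2) labels[i, j, k] <- 1L
  vol_sphere <- sum(labels == 1L)
  filament <- array(0L, c(4, vol_sphere + 4, 4))
  filament[2, 2:(vol_sphere + 1), 2] <- 1L     # same volume, 1 voxel thick
  map_s <- fociquant:::new_nucleus_map(labels, c(1, 1, 1))
  map_f <- fociquant:::new_nucleus_map(filament, c(1, 1, 1))
  sv_sphere <- map_s$nuclei$sv_ratio
  sv_fil <- map_f$nuclei$sv_ratio
  expect_lt(sv_sphere, sv_fil)
  thr <- (sv_sphere + sv_fil) / 2
  expect_equal(nrow(filter_nucleus_objects(
    map_s, c(1, 1e6), thr, exclude_boundary = FALSE)$nuclei), 1L)
  expect_equal(nrow(filter_nucleus_objects(
    map_f, c(1, 1e6), thr, exclude_boundary = FALSE)$nuclei), 0L)
})

test_that("filtering an empty label map is a no-op", {
  map <- fociquant:::new_nucleus_map(array(0L, c(8, 8, 2)), c(1, 1, 1))
  expect_equal(nrow(filter_nucleus_objects(map)$nuclei), 0L)
})

test_that("segmentation overlaps ground-truth nuclei (Dice >= 0.85)", {
  # Large, well-sampled nuclei: the recipe's smoothing + prescribed r = 2
  # dilation put a few-pixel halo on every mask, so the overlap target is
  # meaningful where the cross-section dwarfs the halo — equatorial
  # slices — and not in polar caps a few pixels across.
  p <- confocal_scene_params(shape = c(256L, 256L, 12L), n_nuclei = 2L,
                             nucleus_semiaxes = c(9, 7, 2.2),
                             foci_lambda = 10)
  sc <- simulate_confocal_scene(p, seed = 21)
  bin <- binarize_nuclei_slices(sc$dapi)
  # ground-truth voxel mask from the ellipsoid parameters
  vs <- p$voxel_size
  truth <- array(FALSE, dim(bin))
  xs <- (seq_len(dim(bin)[2]) - 1) * vs[1]
  ys <- (seq_len(dim(bin)[1]) - 1) * vs[2]
  zs <- (seq_len(dim(bin)[3]) - 1) * vs[3]
  for (i in seq_len(nrow(sc$truth$nuclei))) {
    nu <- sc$truth$nuclei[i, ]
    q <- outer(((ys - nu$cy_um) / nu$ay_um)^2,
               ((xs - nu$cx_um) / nu$ax_um)^2, "+")
    for (k in seq_along(zs))
      truth[, , k] <- truth[, , k] | (q + ((zs[k] - nu$cz_um) / nu$az_um)^2 <= 1)
  }
  cross <- vapply(seq_len(dim(bin)[3]), function(k) sum(truth[, , k]),
                  numeric(1))
  equatorial <- which(cross >= 0.5 * max(cross))
  expect_gte(length(equatorial), 4L)
  for (k in equatorial) {
    dice <- 2 * sum(bin[, , k] & truth[, , k]) /
      (sum(bin[, , k]) + sum(truth[, , k]))
    expect_gte(dice, 0.85)
  }
})

test_that("per-nucleus counts match ground truth on a clean synthetic scene", {
  p <- confocal_scene_params(shape = c(256L, 256L, 16L), n_nuclei = 3L,
                             foci_lambda = 30)
  sc <- simulate_confocal_scene(p, seed = 7)
  thr <- max_entropy_threshold(sc$foci)
  cl <- filter_small_clusters(extract_foci_clusters(sc$foci, thr))
  nuc <- segment_nuclei(sc$dapi)
  met <- confocal_metrics(assign_clusters_to_nuclei(cl, nuc), nuc)
  truth_counts <- table(sc$truth$foci$nucleus)
  # match segmented to true nuclei by centroid
  for (i in seq_len(nrow(met))) {
    seg <- nuc$nuclei[i, ]
    j <- which.min((sc$truth$nuclei$cx_um - seg$cx_um)^2 +
                     (sc$truth$nuclei$cy_um - seg$cy_um)^2)
    expect_equal(met$foci_count[i], as.integer(truth_counts[as.character(j)]))
  }
})
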