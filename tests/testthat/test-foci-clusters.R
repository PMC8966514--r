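test_that("a single super-threshold voxel forms one one-voxel cluster", {
  a <- array(0, c(5, 5, 3)); a[3, 3, 2] <- 10
  cl <- extract_foci_clusters(image_stack(a), threshold = 1)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$voxel_count, 1L)
  expect_equal(cl$voxels[[1]][1, ], c(vz = 1L, vy = 2L, vx = 2L))  # 0-based
})

test_that("corner-touching voxels connect under 26- but not 6-connectivity", {
  a <- array(0, c(4, 4, 4)); a[1, 1, 1] <- 5; a[2, 2, 2] <- 5
  st <- image_stack(a)
  expect_equal(nrow(extract_foci_clusters(st, 1, connectivity = 26L)), 1L)
  expect_equal(nrow(extract_foci_clusters(st, 1, connectivity = 6L)), 2L)
})

test_that("component partition matches BFS flood fill on random sparse masks", {
  set.seed(202)
  for (i in 1:8) {
    d <- c(sample(8:16, 1), sample(8:16, 1), sample(3:8, 1))
    conn <- sample(c(6L, 26L), 1)
    a <- array(as.numeric(runif(prod(d)) < 0.25), d)
    st <- image_stack(a)
    cl <- extract_foci_clusters(st, 0.5, connectivity = conn)
    lab_pkg <- array(0L, d)
    for (k in seq_len(nrow(cl))) {
      v <- cl$voxels[[k]]
      lab_pkg[cbind(v[, "vy"] + 1L, v[, "vx"] + 1L, v[, "vz"] + 1L)] <- k
    }
    lab_bfs <- bfs_flood_fill(a > 0.5, connectivity = conn)
    expect_true(same_partition(lab_pkg, lab_bfs))
  }
})

test_that("foreground mass is conserved across components", {
  set.seed(7)
  a <- array(as.numeric(runif(12 * 12 * 5) < 0.3), c(12, 12, 5))
  cl <- extract_foci_clusters(image_stack(a), 0.5)
  expect_equal(sum(cl$voxel_count), sum(a > 0.5))
})

test_that("empty foreground yields a valid empty cluster set", {
  a <- array(1, c(4, 4, 2))
  expect_warning(cl <- extract_foci_clusters(image_stack(a), 5),
                 "outside the intensity range")
  expect_s3_class(cl, "foci_clusters")
  expect_equal(nrow(cl), 0L)
  expect_equal(nrow(filter_small_clusters(cl)), 0L)
})

test_that("the noise filter drops 4-voxel and keeps 5-voxel clusters", {
  a <- array(0, c(10, 10, 3))
  a[1:4, 1, 1] <- 10        # 4 voxels: noise
  a[1:5, 5, 1] <- 10        # 5 voxels: kept
  st <- image_stack(a, voxel_size = c(0.21, 0.21, 0.3))
  cl <- filter_small_clusters(extract_foci_clusters(st, 1))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$voxel_count, 5L)
  expect_equal(cl$volume_um3, 0.06615)
})

test_that("raising min_voxels never increases counts and filtering is idempotent", {
  set.seed(99)
  a <- array(as.numeric(runif(20 * 20 * 4) < 0.3) * 10, c(20, 20, 4))
  cl <- extract_foci_clusters(image_stack(a), 1)
  sizes <- c(1L, 2L, 3L, 5L, 8L)
  counts <- vapply(sizes, function(m)
    nrow(filter_small_clusters(cl, m)), integer(1))
  expect_true(all(diff(counts) <= 0))
  f5 <- filter_small_clusters(cl, 5L)
  expect_identical(nrow(filter_small_clusters(f5, 5L)), nrow(f5))
  expect_true(all(filter_small_clusters(cl, 5L)$cluster %in% cl$cluster))
})

test_that("clusters inherit the nucleus label under their centroid", {
  a <- array(0, c(12, 12, 3))
  a[5:7, 5:7, 2] <- 10          # cluster inside nucleus
  a[1, 12, 1] <- 10             # cluster over background
  st <- image_stack(a, voxel_size = c(1, 1, 1))
  cl <- extract_foci_clusters(st, 1)
  labels <- array(0L, c(12, 12, 3)); labels[3:9, 3:9, ] <- 3L
  map <- fociquant:::new_nucleus_map(labels, c(1, 1, 1))
  # keep original label numbering for the assignment check
  map$labels <- labels
  asg <- assign_clusters_to_nuclei(cl, map)
  inside <- which(asg$voxel_count > 1L)
  expect_equal(asg$nucleus[inside], 3L)
  expect_true(is.na(asg$nucleus[asg$voxel_count == 1L]))
})

test_that("geometry mismatch between grids is an error", {
  a <- array(10, c(6, 6, 2))
  cl <- suppressWarnings(extract_foci_clusters(image_stack(a, c(1, 1, 1)), 5))
  map <- fociquant:::new_nucleus_map(array(1L, c(5, 5, 2)), c(1, 1, 1))
  expect_error(assign_clusters_to_nuclei(cl, map), "shape|voxel")
})

test_that("per-nucleus metrics give count, density and volumes", {
  labels <- array(0L, c(10, 10, 10))
  labels[1:10, 1:10, 1:5] <- 1L     # 500 voxels at 1 um^3 each
  map <- fociquant:::new_nucleus_map(labels, c(1, 1, 1))
  a <- array(0, c(10, 10, 10))
  a[2, 2, 2] <- 10; a[8, 8, 3] <- 10; a[5, 5, 9] <- 10  # third is outside
  cl <- extract_foci_clusters(image_stack(a, c(1, 1, 1)), 1)
  asg <- assign_clusters_to_nuclei(cl, map)
  met <- confocal_metrics(asg, map)
  expect_equal(met$foci_count, 2L)
  expect_equal(met$foci_density_per_um3, 2 / 500)
  expect_equal(attr(met, "unassigned_clusters"), 1L)
  # a nucleus with no foci reports zero count and density
  empty <- confocal_metrics(filter_small_clusters(asg, 100L), map)
  expect_equal(empty$foci_count, 0L)
  expect_equal(empty$foci_density_per_um3, 0)
})
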