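test_that("hull area of a 1 um square is 1 um^2", {
  sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  a <- hull_area(sq)
  expect_equal(as.numeric(a), 1)
  expect_false(attr(a, "degenerate"))
})

test_that("degenerate point sets get zero area and a flag", {
  expect_true(attr(hull_area(cbind(1, 2)), "degenerate"))
  col3 <- cbind(c(0, 50, 100), c(0, 50, 100))
  a <- hull_area(col3)
  expect_equal(as.numeric(a), 0)
  expect_true(attr(a, "degenerate"))
})

test_that("hull area is rigid-motion invariant and bounds member triangles", {
  set.seed(33)
  pts <- cbind(rnorm(50, 0, 120), rnorm(50, 0, 80))
  a0 <- as.numeric(hull_area(pts))
  for (th in runif(5, 0, 2 * pi)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    moved <- pts %*% R + matrix(runif(2, -1e4, 1e4), 50, 2, byrow = TRUE)
    expect_equal(as.numeric(hull_area(moved)), a0, tolerance = 1e-9)
  }
  for (i in 1:20) {
    tri <- pts[sample(50, 3), ]
    ta <- abs((tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
                (tri[3, 1] - tri[1, 1]) * (tri[2, 2] - tri[1, 2])) / 2 / 1e6
    expect_gte(a0 + 1e-12, ta)
  }
})

test_that("nearest-neighbor distances match the exhaustive oracle", {
  set.seed(44)
  tab <- tibble::tibble(cluster = 1:200, nucleus = 1L,
                        cx_nm = runif(200, 0, 2e4),
                        cy_nm = runif(200, 0, 1.5e4))
  got <- nearest_neighbor_distances(tab)$distances
  D <- as.matrix(dist(cbind(tab$cx_nm, tab$cy_nm)))
  diag(D) <- Inf
  expect_equal(got$nnd_nm, unname(apply(D, 1, min)))
})

test_that("two centers at 170 nm both report 170; singletons warn empty", {
  tab <- tibble::tibble(cluster = 1:2, nucleus = 1L,
                        cx_nm = c(0, 170), cy_nm = c(0, 0))
  got <- nearest_neighbor_distances(tab)
  expect_equal(got$distances$nnd_nm, c(170, 170))
  expect_equal(got$summary$median_nnd_nm, 170)
  single <- tab[1, ]
  expect_warning(res <- nearest_neighbor_distances(single), "fewer than two")
  expect_equal(nrow(res$distances), 0L)
})

test_that("cluster density is count over nucleus area", {
  reg <- disk_region(radius_px = 56L, pixel_nm = 100)   # ~100 um^2
  expect_equal(reg$regions$area_um2, 100, tolerance = 0.02)
  set.seed(9)
  cl <- csr_in_region(reg, 35L)
  dens <- cluster_density(cl, reg)
  expect_equal(dens$n_clusters, 35L)
  expect_equal(dens$density_per_um2, 35 / reg$regions$area_um2)
  empty <- cl[0, ]
  expect_equal(cluster_density(empty, reg)$density_per_um2, 0)
})

test_that("coverage is the hull-area sum over the nucleus area", {
  reg <- disk_region(radius_px = 56L, pixel_nm = 100)
  cl <- tibble::tibble(cluster = 1L, nucleus = 1L, cx_nm = 5000, cy_nm = 5000,
                       hull_area_um2 = 2)
  cov <- cluster_coverage(cl, reg)
  expect_equal(cov$coverage, 2 / reg$regions$area_um2)
  cov0 <- cluster_coverage(cl[0, ], reg)
  expect_equal(cov0$coverage, 0)
})

test_that("five radial zones have equal areas on a disk (within 2%)", {
  reg <- disk_region(radius_px = 60L, pixel_nm = 100)
  set.seed(2)
  z <- radial_density_profile(csr_in_region(reg, 50L), reg, 1L)
  expect_equal(nrow(z), 5L)
  expect_lt(max(abs(z$area_um2 - mean(z$area_um2))) / mean(z$area_um2), 0.02)
})

test_that("centers at the centroid populate only the innermost zone", {
  reg <- disk_region(radius_px = 40L, pixel_nm = 100)
  ctr <- reg$regions
  cl <- tibble::tibble(cluster = 1:3, nucleus = 1L,
                       cx_nm = ctr$cx_nm + c(0, 30, -30),
                       cy_nm = ctr$cy_nm + c(0, -30, 30))
  z <- radial_density_profile(cl, reg, 1L)
  expect_equal(z$n_clusters, c(3L, 0L, 0L, 0L, 0L))
})

test_that("a nucleus with fewer pixels than zones is rejected", {
  lab <- matrix(0L, 5, 5)
  lab[2, 2:4] <- 1L    # 3-pixel region
  reg <- structure(list(labels = lab, pixel_nm = 100,
                        regions = tibble::tibble(
                          nucleus = 1L, area_um2 = 3 * 0.01,
                          cx_nm = 300, cy_nm = 200,
                          touches_boundary = FALSE)),
                   class = "nucleus_regions")
  cl <- tibble::tibble(cluster = 1L, nucleus = 1L, cx_nm = 250, cy_nm = 150)
  expect_error(radial_density_profile(cl, reg, 1L), "zones")
})

test_that("radial densities are flat under complete spatial randomness", {
  reg <- disk_region(radius_px = 60L, pixel_nm = 100)
  set.seed(77)
  rejected <- 0L
  n_sim <- 30L
  for (s in seq_len(n_sim)) {
    z <- radial_density_profile(csr_in_region(reg, 80L), reg, 1L)
    p <- chisq.test(z$n_clusters, p = z$area_um2 / sum(z$area_um2))$p.value
    if (p < 0.01) rejected <- rejected + 1L
  }
  expect_lte(rejected / n_sim, 0.05)
})

test_that("widefield segmentation recovers the nucleus polygon area", {
  p <- storm_scene_params(n_clusters = 20L, epitopes_per_cluster = 30L)
  sc <- simulate_storm_scene(p, seed = 2)
  reg <- segment_nuclei_widefield(sc$widefield)
  expect_equal(nrow(reg$regions), 1L)
  expect_lt(abs(reg$regions$area_um2 - sc$truth$nucleus_area_um2) /
              sc$truth$nucleus_area_um2, 0.1)
  expect_error(segment_nuclei_widefield(
    image_stack(matrix(0, 64, 64), channel = "nucleus")), "degenerate")
})

test_that("two separated nuclei give two widefield regions", {
  img <- matrix(2, 140, 140)
  ctr <- expand.grid(i = 1:140, j = 1:140)
  d1 <- (ctr$i - 40)^2 + (ctr$j - 40)^2 <= 25^2
  d2 <- (ctr$i - 100)^2 + (ctr$j - 100)^2 <= 25^2
  img[d1 | d2] <- 100
  set.seed(3)
  img <- img + matrix(rnorm(140 * 140, 0, 1), 140, 140)
  reg <- segment_nuclei_widefield(pmax(img, 0), pixel_nm = 100,
                                  area_range = c(1, 1e4))
  expect_equal(nrow(reg$regions), 2L)
})

test_that("detected cluster density matches the generated cluster count", {
  # compact, well-separated clusters: all recovered
  p <- storm_scene_params(n_clusters = 40L, epitopes_per_cluster = 30L,
                          cluster_sigma = 50)
  sc <- simulate_storm_scene(p, seed = 14)
  cl <- add_hull_areas(dbscan_clusters(sc$localizations, eps = 50,
                                       minPts = 10L))
  reg <- segment_nuclei_widefield(sc$widefield)
  cl <- assign_clusters_to_regions(cl, reg)
  dens <- cluster_density(cl, reg)
  truth_dens <- 40 / sc$truth$nucleus_area_um2
  expect_lt(abs(dens$density_per_um2 - truth_dens) / truth_dens, 0.10)
})

test_that("coverage of non-overlapping clusters tracks the truth hulls", {
  p <- storm_scene_params(n_clusters = 30L, epitopes_per_cluster = 40L,
                          cluster_sigma = 60)
  sc <- simulate_storm_scene(p, seed = 25)
  cl <- add_hull_areas(dbscan_clusters(sc$localizations, eps = 50,
                                       minPts = 10L))
  reg <- segment_nuclei_widefield(sc$widefield)
  cl <- assign_clusters_to_regions(cl, reg)
  cov <- cluster_coverage(cl, reg)
  # oracle: hulls computed from the ground-truth localization grouping
  loc <- sc$localizations
  truth_hulls <- sum(vapply(split(seq_len(nrow(loc)), sc$truth$loc_cluster),
                            function(i)
    as.numeric(hull_area(cbind(loc$x_nm[i], loc$y_nm[i]))), numeric(1)))
  truth_cov <- truth_hulls / sc$truth$nucleus_area_um2
  expect_lte(cov$coverage, 1)
  expect_lt(abs(cov$coverage - truth_cov) / truth_cov, 0.15)
})
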