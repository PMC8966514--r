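test_that("constant counts with one dye give the point-mass limit", {
  fit <- fit_epitope_model(rep(4L, 200), max_dyes = 1L)
  expect_equal(fit$q, 1 / 4)
  expect_equal(fit$mu, 4)
  expect_equal(fit$efficiency, 1)
})

test_that("geometric blink parameter is recovered within 5% at n = 1e4", {
  set.seed(55)
  cts <- rgeom(10000, 0.2) + 1L
  fit <- fit_epitope_model(cts, max_dyes = 1L)
  expect_lt(abs(fit$q - 0.2) / 0.2, 0.05)
  expect_lt(abs(fit$mu - mean(cts)), 1e-6)
})

test_that("compound-model mu matches the empirical mean within 10%", {
  set.seed(56)
  d <- rbinom(20000, 3, 0.6); d <- d[d >= 1][1:10000]
  cts <- vapply(d, function(k) sum(rgeom(k, 0.25) + 1L), integer(1))
  fit <- fit_epitope_model(cts, max_dyes = 3L)
  expect_lt(abs(fit$mu - mean(cts)) / mean(cts), 0.10)
  expect_gt(fit$gof_p, 1e-4)   # the true model should not be firmly rejected
})

test_that("left-truncated samples are fitted without selection bias", {
  set.seed(57)
  d <- rbinom(60000, 3, 0.6); d <- d[d >= 1]
  cts <- vapply(d, function(k) sum(rgeom(k, 0.2) + 1L), integer(1))
  mu_true <- (3 * 0.6 / (1 - 0.4^3)) / 0.2
  obs <- cts[cts >= 10L]
  naive <- fit_epitope_model(obs, max_dyes = 3L)
  trunc <- fit_epitope_model(obs, max_dyes = 3L, truncate_at = 10L)
  expect_gt(abs(naive$mu - mu_true), abs(trunc$mu - mu_true))
  expect_lt(abs(trunc$mu - mu_true) / mu_true, 0.10)
})

test_that("small samples and invalid counts are rejected", {
  expect_error(fit_epitope_model(rep(3L, 50)), "sample too small")
  expect_error(fit_epitope_model(c(rep(2L, 200), 0L)), ">= 1")
})

test_that("tidy and glance expose the fit in broom form", {
  fit <- fit_epitope_model(rep(5L, 150), max_dyes = 1L)
  td <- tidy(fit)
  expect_equal(td$term, c("q", "efficiency", "mu"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 150L)
  expect_equal(gl$mu, 5)
})

test_that("epitope estimates divide counts by mu with a floor of one", {
  fit <- fit_epitope_model(rep(5L, 150), max_dyes = 1L)  # mu = 5
  cl <- structure(
    tibble::tibble(cluster = 1:3, n_loc = c(5L, 50L, 1L),
                   cx_nm = c(0, 0, 0), cy_nm = c(0, 0, 0),
                   nucleus = 1L, members = list(1L, 2L, 3L)),
    coords = cbind(x = c(0, 0, 0), y = c(0, 0, 0)),
    minPts = 1L, eps = 50,
    class = c("storm_clusters", class(tibble::tibble())))
  est <- estimate_epitopes(cl, fit)
  expect_equal(est$epitope_estimate, c(1L, 10L, 1L))
})

test_that("a cluster in an uncalibrated tile raises an error naming it", {
  set.seed(58)
  # calibration clusters only in the left half of the field
  p <- storm_scene_params(n_clusters = 600L, epitopes_per_cluster = 1L,
                          cluster_sigma = 5)
  sc <- simulate_storm_scene(p, seed = 16)
  cl <- add_hull_areas(dbscan_clusters(sc$localizations, eps = 50,
                                       minPts = 10L))
  left <- cl[cl$cx_nm < stats::median(cl$cx_nm), ]
  attr(left, "coords") <- attr(cl, "coords")
  attr(left, "minPts") <- attr(cl, "minPts")
  class(left) <- class(cl)
  calib <- fit_epitope_tiles(left, n_tiles = c(2L, 1L),
                             fov = c(min(cl$cx_nm), max(cl$cx_nm),
                                     min(cl$cy_nm), max(cl$cy_nm)),
                             min_sample = 100L)
  expect_false(all(calib$tiles$fitted))
  expect_error(estimate_epitopes(cl, calib), "tile")
})

test_that("known epitope numbers are recovered with small median error", {
  # calibrate on an isolated single-epitope field, then count 5-500
  pc <- storm_scene_params(n_clusters = 2400L, epitopes_per_cluster = 1L,
                           cluster_sigma = 5)
  cal_sc <- simulate_storm_scene(pc, seed = 11)
  # subunit-level preset isolates the single-epitope blink clusters
  cl_cal <- add_hull_areas(dbscan_clusters(cal_sc$localizations, eps = 15,
                                           minPts = 5L))
  calib <- fit_epitope_tiles(cl_cal, n_tiles = c(1L, 1L))
  fit <- calib$fits[[1]]
  expect_lt(abs(fit$mu - 9.615) / 9.615, 0.10)

  pe <- storm_scene_params(n_clusters = 30L,
                           epitopes_per_cluster = c(5L, 500L),
                           cluster_sigma = 80)
  sc <- simulate_storm_scene(pe, seed = 12)
  cl <- estimate_epitopes(add_hull_areas(
    dbscan_clusters(sc$localizations, eps = 50, minPts = 10L)), fit)
  tr <- sc$truth$clusters
  D <- sqrt(outer(cl$cx_nm, tr$cx_nm, "-")^2 +
              outer(cl$cy_nm, tr$cy_nm, "-")^2)
  j <- apply(D, 2, which.min)
  ok <- D[cbind(j, seq_len(nrow(tr)))] < 200
  relerr <- abs(cl$epitope_estimate[j[ok]] - tr$n_epitopes[ok]) /
    tr$n_epitopes[ok]
  expect_gte(sum(ok), 25L)
  expect_lte(median(relerr), 0.2)
})

test_that("per-tile calibration beats a global fit under varying photophysics", {
  qf <- function(x, y) 0.12 + 0.2 * (x - 2000) / 16000
  pc <- storm_scene_params(n_clusters = 2400L, epitopes_per_cluster = 1L,
                           cluster_sigma = 5, q_field = qf)
  cal_sc <- simulate_storm_scene(pc, seed = 31)
  cl_cal <- add_hull_areas(dbscan_clusters(cal_sc$localizations, eps = 15,
                                           minPts = 5L))
  fov <- c(2000, 18000, 2000, 14000)
  tiles <- fit_epitope_tiles(cl_cal, n_tiles = c(4L, 1L), fov = fov,
                             min_sample = 50L)
  glob <- fit_epitope_tiles(cl_cal, n_tiles = c(1L, 1L), fov = fov)

  pe <- storm_scene_params(n_clusters = 40L, epitopes_per_cluster = 60L,
                           cluster_sigma = 60, q_field = qf)
  sc <- simulate_storm_scene(pe, seed = 32)
  cl <- add_hull_areas(dbscan_clusters(sc$localizations, eps = 50,
                                       minPts = 10L))
  err <- function(est) {
    tr <- sc$truth$clusters
    D <- sqrt(outer(est$cx_nm, tr$cx_nm, "-")^2 +
                outer(est$cy_nm, tr$cy_nm, "-")^2)
    j <- apply(D, 2, which.min)
    ok <- D[cbind(j, seq_len(nrow(tr)))] < 200
    median(abs(est$epitope_estimate[j[ok]] - tr$n_epitopes[ok]) /
             tr$n_epitopes[ok])
  }
  expect_true(all(tiles$tiles$fitted))
  e_tiles <- err(estimate_epitopes(cl, tiles))
  e_glob <- err(estimate_epitopes(cl, glob$fits[[1]]))
  expect_lt(e_tiles, e_glob)
})
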