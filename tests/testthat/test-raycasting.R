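concentric <- phantom_spec()         # 5 mm condyle, 7 mm fossa, 2 mm gap
concentric_vol <- rasterize_phantom(concentric)
voxdiag <- sqrt(3) * concentric$spacing_mm

test_that("concentric phantom yields a 2 mm gap along any superior direction", {
  for (u in list(c(0, 0, 1), c(1, 1, 2) / sqrt(6), c(-0.5, 0.3, 0.9))) {
    u <- u / sqrt(sum(u^2))
    hit <- cast_ray(concentric_vol, c(0, 0, 0), u)
    expect_equal(hit$status, "ok")
    expect_equal(hit$gap_mm, 2, tolerance = voxdiag / 2)
    # crossing points lie on the ray and reconstruct the gap
    expect_equal(hit$gap_mm, sqrt(sum((hit$fossa_entry - hit$condyle_exit)^2)))
    cross_dir <- (hit$fossa_entry - hit$condyle_exit) / hit$gap_mm
    expect_equal(cross_dir, u, tolerance = 1e-9)
  }
})

test_that("a ray into an erased fossa octant reports no_fossa", {
  v <- concentric_vol
  pos <- voxel_to_world(v, which(array(TRUE, dim(v$voxels)), arr.ind = TRUE) - 1)
  octant <- pos[, 1] > 0 & pos[, 2] > 0 & pos[, 3] > 0
  vox <- v$voxels
  vox[octant & vox == 2L] <- 0L
  v$voxels <- vox
  u <- c(1, 1, 1) / sqrt(3)
  expect_equal(cast_ray(v, c(0, 0, 0), u)$status, "no_fossa")
  # other octants still intersect
  expect_equal(cast_ray(v, c(0, 0, 0), c(-1, -1, 1) / sqrt(3))$status, "ok")
})

test_that("ray argument errors are raised", {
  expect_error(cast_ray(concentric_vol, c(100, 0, 0), c(0, 0, 1)), "outside")
  expect_error(cast_ray(concentric_vol, c(0, 0, 0), c(0, 0, 0)), "zero")
  expect_error(cast_ray(concentric_vol, c(0, 0, 0), c(0, 0, 2)), "unit")
})

test_that("displaced-sphere gaps match the closed-form solution for 50 random directions", {
  spec <- phantom_spec(displacement_mm = c(0.6, -0.4, -1.1))
  vol <- rasterize_phantom(spec)
  set.seed(17)
  margin <- cap_margin_deg(spec)
  n_checked <- 0
  for (i in 1:50) {
    z <- runif(1); phi <- runif(1, 0, 2 * pi)   # area-uniform on hemisphere
    u <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
    ag <- analytic_gap_interior(spec, u, margin)
    hit <- cast_ray(vol, spec$displacement_mm, u)
    if (!is.na(ag) && hit$status == "ok") {
      expect_lt(abs(hit$gap_mm - ag), voxdiag)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 25)
})

test_that("traversal agrees with dense brute-force sampling along the ray", {
  spec <- phantom_spec(displacement_mm = c(-0.8, 0.5, -0.9))
  vol <- rasterize_phantom(spec)
  set.seed(23)
  for (i in 1:20) {
    u <- rnorm(3); u[3] <- abs(u[3]); u <- u / sqrt(sum(u^2))
    hit <- cast_ray(vol, spec$displacement_mm, u)
    bf <- brute_force_gap(vol, spec$displacement_mm, u)
    if (hit$status == "ok" && !is.na(bf))
      expect_equal(hit$gap_mm, bf, tolerance = voxdiag)
    else
      expect_true(hit$status != "ok" && is.na(bf))
  }
})

test_that("imputation follows the min/max contract", {
  expect_equal(impute(c(1, 3), c(TRUE, TRUE), "midpoint"), c(1, 3))
  expect_equal(impute(c(1, NA, 3), c(TRUE, FALSE, TRUE), "midpoint"),
               c(1, 2, 3))
  draws <- impute(c(1, 3, rep(NA, 10000)),
                  c(TRUE, TRUE, rep(FALSE, 10000)), "uniform", rng_seed = 4)
  expect_true(all(draws >= 1 & draws <= 3))
  expect_equal(mean(draws[-(1:2)]), 2, tolerance = 0.05)
  expect_identical(draws, impute(c(1, 3, rep(NA, 10000)),
                                 c(TRUE, TRUE, rep(FALSE, 10000)),
                                 "uniform", rng_seed = 4))
  expect_error(impute(c(NA, NA), c(FALSE, FALSE), "midpoint"), "zero")
})

test_that("extract_features on the concentric phantom is uniform at 2 mm", {
  # full-hemisphere coverage: every ray hits the fossa radially, so the
  # whole 198-vector sits at the analytic 2 mm gap with nothing imputed
  ds <- build_direction_set(198)
  spec90 <- phantom_spec(fossa_coverage_deg = 90)
  vol <- rasterize_phantom(spec90)
  f <- extract_features(vol, ds)
  # rays more than the rasterization's angular jitter away from the cap
  # edge (here the equator) all hit, radially, at the analytic gap
  interior <- ds$directions[, 3] >= sin(cap_margin_deg(spec90) * pi / 180)
  expect_gt(sum(interior), 185)
  expect_equal(sum(f$imputed[interior]), 0L)
  expect_true(all(abs(f$distances[interior] - 2) < voxdiag))
  # with the default 80-degree cap, rim rays are imputed within the
  # observed min/max range
  f80 <- extract_features(concentric_vol, ds)
  ok <- !f80$imputed
  expect_equal(f80$n_imputed, sum(f80$imputed))
  expect_gt(f80$n_imputed, 0L)
  expect_true(all(f80$distances[f80$imputed] >= min(f80$distances[ok])))
  expect_true(all(f80$distances[f80$imputed] <= max(f80$distances[ok])))
})

test_that("a half-coverage fossa imputes about half the rays, within the observed range", {
  spec <- phantom_spec(fossa_coverage_deg = 60)
  vol <- rasterize_phantom(spec)
  ds <- build_direction_set(198)
  f <- extract_features(vol, ds, imputation = "uniform", rng_seed = 5)
  # cap of 60 deg covers 1 - cos(60) = 1/2 of the hemisphere area
  expect_equal(f$n_imputed / ds$n, 0.5, tolerance = 0.1)
  ok <- !f$imputed
  expect_true(all(f$distances[f$imputed] >= min(f$distances[ok])))
  expect_true(all(f$distances[f$imputed] <= max(f$distances[ok])))
})

test_that("extraction is deterministic for a fixed seed", {
  ds <- test_directions()
  spec <- phantom_spec(fossa_coverage_deg = 60)
  vol <- rasterize_phantom(spec)
  f1 <- extract_features(vol, ds, imputation = "uniform", rng_seed = 9)
  f2 <- extract_features(vol, ds, imputation = "uniform", rng_seed = 9)
  expect_identical(f1$distances, f2$distances)
})

test_that("error paths: centroid outside condyle and no fossa coverage", {
  # hollow condyle shell -> centroid falls in the hole
  a <- array(0L, dim = c(21, 21, 21))
  idx <- which(array(TRUE, dim(a)), arr.ind = TRUE) - 11
  r <- sqrt(rowSums(idx^2))
  a[r >= 6 & r <= 8] <- 1L
  v <- label_volume(a, spacing = c(1, 1, 1), origin = c(-10, -10, -10))
  expect_error(extract_features(v, test_directions()), "centroid not inside")
  # condyle with no fossa anywhere
  b <- array(0L, dim = c(11, 11, 11))
  b[4:8, 4:8, 4:8] <- 1L
  vb <- label_volume(b, spacing = c(1, 1, 1), origin = c(-5, -5, -5))
  expect_error(extract_features(vb, test_directions()), "no fossa coverage")
})

test_that("gaps are invariant under a common world translation", {
  spec <- phantom_spec(displacement_mm = c(0.3, 0.2, -0.8))
  vol <- rasterize_phantom(spec)
  shift <- c(13.7, -4.2, 8.9)
  vol2 <- vol
  vol2$origin <- vol$origin + shift
  ds <- test_directions()
  f1 <- extract_features(vol, ds)
  f2 <- extract_features(vol2, ds)
  expect_identical(f1$distances, f2$distances)
})

test_that("gap vectors are voxel-size independent within the coarser diagonal", {
  ds <- test_directions()
  spec4 <- phantom_spec(spacing_mm = 0.4)
  f4 <- extract_features(rasterize_phantom(spec4), ds)
  f2 <- extract_features(rasterize_phantom(phantom_spec(spacing_mm = 0.2)), ds)
  # compare away from the cap rim, where the voxel-limit gap is continuous
  interior <- vapply(seq_len(ds$n), function(i)
    !is.na(analytic_gap_interior(spec4, ds$directions[i, ],
                                 cap_margin_deg(spec4))), logical(1))
  both <- interior & !f4$imputed & !f2$imputed
  expect_gt(sum(both), 20)
  expect_true(all(abs(f4$distances[both] - f2$distances[both]) < sqrt(3) * 0.4))
})

test_that("mirrored volume with mirrored directions reproduces the features", {
  spec <- phantom_spec(displacement_mm = c(0.9, -0.5, -1.0))
  vol <- rasterize_phantom(spec)
  ds <- test_directions()
  f <- extract_features(vol, ds)
  fm <- extract_features(mirror_pair(vol), mirror_direction_set(ds))
  expect_equal(fm$distances, f$distances, tolerance = 1e-9)
  expect_identical(fm$imputed, f$imputed)
})
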