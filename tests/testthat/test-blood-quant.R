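test_that("sphere VOI rasterization matches a brute-force distance check", {
  grid <- volume(array(0, c(12, 12, 12)), 0.5, "Bq/mL")
  v <- sphere_voi(c(2.5, 2.5, 2.5), 2.0, grid)
  # exhaustive oracle over all voxels
  cnt <- 0L
  inside <- matrix(0L, 0, 3)
  for (i in 1:12) for (j in 1:12) for (k in 1:12) {
    w <- (c(i, j, k) - 1) * 0.5
    if (sum((w - 2.5)^2) <= 4) inside <- rbind(inside, c(i, j, k))
  }
  expect_identical(nrow(v$voxels), nrow(inside))
  got <- unname(v$voxels[order(v$voxels[, 1], v$voxels[, 2], v$voxels[, 3]), ])
  expect_equal(got, unname(inside))
  # sub-voxel radius centered on a voxel center -> exactly 1 voxel
  v1 <- sphere_voi(c(2.0, 2.0, 2.0), 0.2, grid)
  expect_identical(nrow(v1$voxels), 1L)
  expect_identical(as.integer(v1$voxels), c(5L, 5L, 5L))
  # radius spanning the whole grid -> every voxel
  vall <- sphere_voi(c(2.75, 2.75, 2.75), 100, grid)
  expect_identical(nrow(vall$voxels), 1728L)
  expect_error(sphere_voi(c(100, 100, 100), 0.1, grid), "zero voxels")
})

test_that("cylinder VOI rasterizes within radius and z-range only", {
  grid <- volume(array(0, c(10, 10, 20)), 1, "Bq/mL")
  v <- cylinder_voi(c(4, 4), 1.5, c(5, 9), grid)
  w <- (v$voxels - 1)
  expect_true(all((w[, 1] - 4)^2 + (w[, 2] - 4)^2 <= 1.5^2 + 1e-12))
  expect_true(all(w[, 3] >= 5 & w[, 3] <= 9))
})

test_that("blood level extraction applies the 1.057 density correction exactly once", {
  grid <- volume(array(1057, c(8, 8, 8)), 1, "Bq/mL")
  scan <- subject_scan("s1", "g", 1e6, grid)
  voi <- sphere_voi(c(3.5, 3.5, 3.5), 2, grid)
  est <- extract_blood_level(scan, voi)
  expect_equal(est$image_blood_Bq_per_g, 1000, tolerance = 1e-12)
  # identity density
  est1 <- extract_blood_level(scan, voi, density_g_per_mL = 1)
  expect_equal(est1$image_blood_Bq_per_g, 1057, tolerance = 1e-12)
  # nonuniform VOI equals an explicit sum/count loop
  set.seed(12)
  scan$vol$values <- array(stats::runif(8^3, 100, 200), c(8, 8, 8))
  est2 <- extract_blood_level(scan, voi)
  tot <- 0; cnt <- 0
  for (r in seq_len(nrow(voi$voxels))) {
    ijk <- voi$voxels[r, ]
    tot <- tot + scan$vol$values[ijk[1], ijk[2], ijk[3]]
    cnt <- cnt + 1
  }
  expect_equal(est2$image_blood_Bq_per_g, tot / cnt / 1.057, tolerance = 1e-12)
  # unit mismatch is refused
  bad <- scan; bad$vol$units <- "ratio"
  expect_error(extract_blood_level(bad, voi), "Bq/mL")
})

test_that("blood normalization averages exactly 1 over its defining VOI and is scale invariant", {
  set.seed(5)
  grid <- volume(array(stats::runif(8^3, 500, 1500), c(8, 8, 8)), 1, "Bq/mL")
  scan <- subject_scan("s1", "g", 1e6, grid)
  voi <- sphere_voi(c(3.5, 3.5, 3.5), 2.2, grid)
  est <- extract_blood_level(scan, voi)
  norm <- normalize_to_blood(scan, est)
  expect_identical(norm$units, "ratio")
  expect_equal(mean(norm$values[voi$voxels]), 1, tolerance = 1e-12)
  # a voxel at twice the blood concentration maps to ratio 2
  scan2 <- scan
  scan2$vol$values[1, 1, 1] <- est$image_blood_Bq_per_g * 1.057 * 2
  norm2 <- normalize_to_blood(scan2, est)
  expect_equal(norm2$values[1, 1, 1], 2, tolerance = 1e-12)
  # scaling volume and blood estimate by k leaves output unchanged
  scan_k <- scan; scan_k$vol$values <- scan$vol$values * 3
  est_k <- extract_blood_level(scan_k, voi)
  expect_equal(normalize_to_blood(scan_k, est_k)$values, norm$values,
               tolerance = 1e-12)
  expect_error(normalize_to_blood(scan, 0), "> 0")
})

test_that("%ID/g normalization is (Bq/mL / density) / dose * 100 and halves when dose doubles", {
  grid <- volume(array(1057, c(6, 6, 6)), 1, "Bq/mL")
  scan <- subject_scan("s1", "g", 1e6, grid)
  pid <- normalize_to_pid(scan)
  expect_identical(pid$units, "%ID/g")
  expect_equal(unique(as.vector(pid$values)), 0.1, tolerance = 1e-12)
  scan2 <- subject_scan("s1", "g", 2e6, grid)
  expect_equal(normalize_to_pid(scan2)$values, pid$values / 2, tolerance = 1e-12)
})

test_that("data-driven blood VOI recovers blood-pool voxels and records its parameters", {
  atlas <- tiny_atlas()
  sim <- simulate_cohort(atlas, cohort_spec(
    n_per_group = 6, seed = 21, psf_sigma_mm = 0, noise_scale = 0,
    blood_assay_cv = 0))
  mask <- build_analysis_mask(sim$scans)
  bv <- derive_blood_voi(sim$scans, mask, min_size = 10L)
  expect_identical(bv$params$p, 0.005)
  expect_identical(bv$params$min_size, 10L)
  # the union VOI contains the heart blood pool core
  hb <- which(atlas_region_mask(atlas, "heart_blood_pool")$values == 1L)
  lin <- bv$voi$voxels[, 1] +
    (bv$voi$voxels[, 2] - 1L) * 24L + (bv$voi$voxels[, 3] - 1L) * 24L * 24L
  expect_true(all(hb %in% lin))
  # seed restriction at the carotid yields exactly the pure-blood carotid
  bvc <- derive_blood_voi(sim$scans, mask, min_size = 4L,
                          seed_point_mm = region_centroid_mm(atlas, "carotid"))
  car <- which(atlas_region_mask(atlas, "carotid")$values == 1L)
  linc <- bvc$voi$voxels[, 1] +
    (bvc$voi$voxels[, 2] - 1L) * 24L + (bvc$voi$voxels[, 3] - 1L) * 24L * 24L
  expect_setequal(linc, car)
})

test_that("shuffled covariate destroys the blood VOI (error path exercised)", {
  atlas <- tiny_atlas()
  sim <- simulate_cohort(atlas, cohort_spec(n_per_group = 6, seed = 22))
  mask <- build_analysis_mask(sim$scans)
  exv <- vapply(sim$scans, `[[`, 0, "exvivo_blood_Bq_per_g")
  set.seed(1)
  shuffled <- sample(exv)
  expect_error(
    derive_blood_voi(sim$scans, mask, exvivo_blood = shuffled),
    "no cluster survived")
})

test_that("blood VOI derivation is fully deterministic given its inputs", {
  atlas <- tiny_atlas()
  sim <- simulate_cohort(atlas, cohort_spec(n_per_group = 4, seed = 31))
  mask <- build_analysis_mask(sim$scans)
  b1 <- derive_blood_voi(sim$scans, mask, min_size = 10L)
  b2 <- derive_blood_voi(sim$scans, mask, min_size = 10L)
  expect_identical(b1, b2)
})
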