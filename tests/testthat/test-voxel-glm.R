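full_mask <- function(d) volume(array(1L, d), 1, "label")

vols_from_matrix <- function(Y, d) {
  # row i of Y = subject i's values over the flattened grid
  lapply(seq_len(nrow(Y)), function(i) volume(array(Y[i, ], d), 1, "Bq/mL"))
}

test_that("regression t-map matches the closed-form per-voxel OLS oracle", {
  d <- c(5, 4, 3)
  n <- 5L
  set.seed(101)
  Y <- matrix(stats::rnorm(n * prod(d), 10, 2), n)
  x <- c(1, 2, 3, 4, 5)
  tm <- regression_tmap(vols_from_matrix(Y, d), x, full_mask(d))
  expect_identical(tm$dof, n - 2L)
  for (v in seq_len(prod(d)))
    expect_equal(tm$t$values[v], ols_t_oracle(Y[, v], x), tolerance = 1e-12)
  # worked case: approximately linear uptake
  y1 <- c(1.0, 2.1, 2.9, 4.2, 4.8)
  Y[, 1] <- y1
  tm2 <- regression_tmap(vols_from_matrix(Y, d), x, full_mask(d))
  expect_equal(tm2$t$values[1], ols_t_oracle(y1, x), tolerance = 1e-12)
  # and the correlation identity t = r sqrt((n-2)/(1-r^2))
  r <- stats::cor(y1, x)
  expect_equal(tm2$t$values[1], r * sqrt((n - 2) / (1 - r^2)), tolerance = 1e-10)
})

test_that("regression t-map degenerate cases: symmetry, zero variance, errors", {
  d <- c(2, 2, 2)
  Y <- matrix(1, 3, prod(d))
  Y[, 1] <- c(1, 0, 1)            # symmetric around center covariate
  Y[, 2] <- c(7, 7, 7)            # constant voxel -> zero variance flag
  tm <- regression_tmap(vols_from_matrix(Y, d), c(-1, 0, 1), full_mask(d))
  expect_equal(tm$t$values[1], 0)
  expect_equal(tm$t$values[2], 0)
  expect_true(2L %in% tm$zero_variance)
  expect_error(regression_tmap(vols_from_matrix(Y, d), c(2, 2, 2), full_mask(d)),
               "zero variance")
  expect_error(regression_tmap(vols_from_matrix(Y[1:2, , drop = FALSE], d),
                               c(1, 2), full_mask(d)), "3 subjects")
})

test_that("perfect-fit voxels are clamped finite and flagged", {
  d <- c(2, 2, 2)
  x <- c(1, 2, 3, 4)
  Y <- matrix(stats::rnorm(4 * prod(d)), 4)
  Y[, 3] <- 2 * x + 1             # exact linear relation
  tm <- regression_tmap(vols_from_matrix(Y, d), x, full_mask(d))
  expect_true(is.finite(tm$t$values[3]))
  expect_gt(tm$t$values[3], 1e9)
  expect_true(3L %in% tm$perfect_fit)
})

test_that("two-sample t-map matches the pooled-t closed form and is antisymmetric", {
  d <- c(3, 3, 3)
  set.seed(7)
  A <- matrix(stats::rnorm(3 * prod(d), 5), 3)
  B <- matrix(stats::rnorm(3 * prod(d), 6), 3)
  A[, 1] <- c(1, 2, 3); B[, 1] <- c(4, 5, 6)
  tm <- two_sample_tmap(vols_from_matrix(A, d), vols_from_matrix(B, d), full_mask(d))
  expect_identical(tm$dof, 4L)
  for (v in seq_len(prod(d)))
    expect_equal(tm$t$values[v], pooled_t_oracle(A[, v], B[, v]), tolerance = 1e-12)
  expect_equal(tm$t$values[1], -3 / sqrt(1 * (2 / 3)), tolerance = 1e-12)
  # swapping groups negates the map exactly
  tm_sw <- two_sample_tmap(vols_from_matrix(B, d), vols_from_matrix(A, d), full_mask(d))
  expect_equal(tm_sw$t$values, -tm$t$values, tolerance = 1e-14)
  # identical groups give t = 0 everywhere
  tm0 <- two_sample_tmap(vols_from_matrix(A, d), vols_from_matrix(A, d), full_mask(d))
  expect_true(all(tm0$t$values == 0))
  # zero pooled variance -> flagged 0
  Az <- A; Az[, 2] <- 2; Bz <- B; Bz[, 2] <- 5
  tmz <- two_sample_tmap(vols_from_matrix(Az, d), vols_from_matrix(Bz, d), full_mask(d))
  expect_equal(tmz$t$values[2], 0)
  expect_true(2L %in% tmz$zero_variance)
  expect_error(two_sample_tmap(vols_from_matrix(A[1, , drop = FALSE], d),
                               vols_from_matrix(B, d), full_mask(d)),
               "at least 2")
})

test_that("t thresholds invert the t CDF (numerical inversion oracle)", {
  expect_equal(t_threshold(0.5, 17, "one"), 0, tolerance = 1e-12)
  # independent oracle: bisection on pt()
  invert_pt <- function(p, dof) {
    stats::uniroot(function(t) stats::pt(t, dof, lower.tail = FALSE) - p,
                   c(0, 100), tol = 1e-12)$root
  }
  expect_equal(t_threshold(0.005, 20, "one"), invert_pt(0.005, 20), tolerance = 1e-8)
  expect_equal(t_threshold(0.005, 20, "one"), 2.845, tolerance = 1e-3)
  expect_equal(t_threshold(0.05, 10, "two"), t_threshold(0.025, 10, "one"),
               tolerance = 1e-12)
  expect_error(t_threshold(0, 10), "in \\(0, 1\\)")
  expect_error(t_threshold(0.05, 0), ">= 1")
})

test_that("cluster extraction matches the flood-fill oracle at all connectivities", {
  for (seed in 1:25) {
    set.seed(seed)
    arr <- array(stats::runif(8^3), c(8, 8, 8))
    bin <- arr > 0.7
    tm <- tmap_from_array(array(as.numeric(bin), dim(bin)))
    for (conn in c(6L, 18L, 26L)) {
      cl <- extract_clusters(tm, t_crit = 0.5, min_size = 0L, connectivity = conn)
      lab <- flood_fill_oracle(bin, conn)
      expect_identical(cluster_sets_from(cl, dim(bin)),
                       oracle_cluster_sets(lab, 0L))
    }
  }
})

test_that("extent threshold is strict (more than min_size voxels)", {
  arr <- array(0, c(10, 10, 10))
  arr[1:50] <- 5                       # 50-voxel bar along first axis columns
  tm <- tmap_from_array(arr)
  expect_length(extract_clusters(tm, 1, min_size = 50L, connectivity = 26L), 0)
  arr[51] <- 5                         # 51 voxels -> retained
  tm <- tmap_from_array(arr)
  cl <- extract_clusters(tm, 1, min_size = 50L, connectivity = 26L)
  expect_length(cl, 1)
  expect_identical(cl[[1]]$size_voxels, 51L)
})

test_that("clusters partition the suprathreshold set and are ordered by peak then size", {
  set.seed(33)
  arr <- array(stats::rnorm(12^3), c(12, 12, 12))
  tm <- tmap_from_array(arr)
  cl <- extract_clusters(tm, 1.2, min_size = 1L, connectivity = 18L)
  all_vox <- do.call(rbind, lapply(cl, `[[`, "voxels"))
  expect_identical(nrow(all_vox), nrow(unique(all_vox)))  # no voxel twice
  supra <- which(arr > 1.2)
  lin <- sort(unlist(cluster_sets_from(cl, dim(arr))))
  expect_true(all(lin %in% supra))
  peaks <- vapply(cl, `[[`, 0, "peak_t")
  expect_true(all(diff(peaks) <= 1e-12))
  # empty result on an all-zero map
  expect_length(extract_clusters(tmap_from_array(array(0, c(6, 6, 6))), 0.1), 0)
})

test_that("raising the cluster-forming threshold only shrinks clusters", {
  set.seed(44)
  arr <- array(stats::rnorm(10^3, sd = 1.5), c(10, 10, 10))
  tm <- tmap_from_array(arr)
  lo <- extract_clusters(tm, 0.8, min_size = 0L)
  hi <- extract_clusters(tm, 1.6, min_size = 0L)
  lo_set <- unlist(cluster_sets_from(lo, dim(arr)))
  hi_set <- unlist(cluster_sets_from(hi, dim(arr)))
  expect_true(all(hi_set %in% lo_set))
})
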