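test_that("null contrast (identical cohorts relabeled) yields no surviving clusters", {
  atlas <- tiny_atlas()
  sim <- simulate_cohort(atlas, cohort_spec(n_per_group = 4, seed = 13))
  mask <- build_analysis_mask(sim$scans)
  g <- vapply(sim$scans, `[[`, "", "group")
  ko <- sim$scans[g == "trem2_ko"]
  # split the knockout group against itself: same data-generating law
  koA <- lapply(ko[1:2], function(s) { s$subject_id <- paste0(s$subject_id, "_a"); s })
  cr <- run_contrast(koA, ko[3:4], normalization = "pid", mask = mask,
                     p = 0.005, min_size = 50L)
  expect_length(cr$clusters, 0)
  # literally identical groups are refused (non-disjoint ids)
  expect_error(run_contrast(ko[1:2], ko[1:2], normalization = "pid", mask = mask),
               "disjoint")
})

test_that("WT vs KO contrast under blood normalization hits the high-expression organs", {
  atlas <- tiny_atlas()
  sim <- simulate_cohort(atlas, cohort_spec(n_per_group = 6, seed = 17))
  mask <- build_analysis_mask(sim$scans)
  g <- vapply(sim$scans, `[[`, "", "group")
  bv <- derive_blood_voi(sim$scans, mask, min_size = 10L,
                         seed_point_mm = region_centroid_mm(atlas, "heart_blood_pool"))
  lv <- extract_blood_levels(sim$scans, bv$voi)
  cr <- run_contrast(sim$scans[g == "wt"], sim$scans[g == "trem2_ko"],
                     normalization = "blood", mask = mask, blood = lv,
                     min_size = 10L)
  expect_gt(length(cr$clusters), 0)
  cl_lin <- unlist(lapply(cr$clusters, function(cl)
    cl$voxels[, 1] + (cl$voxels[, 2] - 1L) * 24L + (cl$voxels[, 3] - 1L) * 576L))
  liver <- which(atlas_region_mask(atlas, "liver")$values == 1L)
  marrow <- which(atlas_region_mask(atlas, "bone_marrow")$values == 1L)
  expect_gt(length(intersect(cl_lin, liver)), 0)
  expect_gt(length(intersect(cl_lin, marrow)), 0)
  # determinism: identical inputs give bit-identical results
  cr2 <- run_contrast(sim$scans[g == "wt"], sim$scans[g == "trem2_ko"],
                      normalization = "blood", mask = mask, blood = lv,
                      min_size = 10L)
  expect_identical(cr, cr2)
})

test_that("organ T summary equals a per-voxel loop oracle and flags empty organs", {
  set.seed(55)
  d <- c(10, 10, 10)
  arr <- array(stats::rnorm(prod(d)), d)
  tm <- tmap_from_array(arr)
  m1 <- array(0L, d); m1[2:4, 2:4, 2:4] <- 1L
  m2 <- array(0L, d)  # empty organ
  masks <- list(roi = volume(m1, 1, "label"), empty = volume(m2, 1, "label"))
  os <- organ_t_summary(tm, masks)
  idx <- which(m1 == 1L)
  # loop oracle
  tot <- 0; mx <- -Inf
  for (v in idx) { tot <- tot + arr[v]; mx <- max(mx, arr[v]) }
  expect_equal(os$mean_t[os$organ == "roi"], tot / length(idx), tolerance = 1e-12)
  expect_equal(os$peak_t[os$organ == "roi"], mx, tolerance = 1e-12)
  expect_identical(os$n_voxels[os$organ == "roi"], length(idx))
  expect_identical(os$n_voxels[os$organ == "empty"], 0L)
  expect_true(os$flagged[os$organ == "empty"])
  expect_true(is.na(os$mean_t[os$organ == "empty"]))
  # uniform t inside the mask
  tm3 <- tmap_from_array(array(3, d))
  os3 <- organ_t_summary(tm3, masks["roi"])
  expect_equal(os3$mean_t, 3)
  expect_equal(os3$peak_t, 3)
})

test_that("organ mean-t ordering tracks phantom expression for the reporting organs", {
  atlas <- tiny_atlas()
  sim <- simulate_cohort(atlas, cohort_spec(n_per_group = 8, seed = 71))
  mask <- build_analysis_mask(sim$scans)
  g <- vapply(sim$scans, `[[`, "", "group")
  cr <- run_contrast(sim$scans[g == "wt"], sim$scans[g == "trem2_ko"],
                     normalization = "pid", mask = mask, min_size = 10L)
  os <- organ_t_summary(cr$tmap, atlas)
  expr <- atlas$regions$trem2_expression[match(os$organ, atlas$regions$region)]
  # high-expression organs (liver, bone marrow) outrank low-expression ones
  expect_gt(min(os$mean_t[os$organ %in% c("liver", "bone_marrow")]),
            max(os$mean_t[os$organ %in% c("lung", "spleen")]))
  expect_gt(stats::cor(os$mean_t, expr, method = "spearman"), 0)
})

test_that("regional fold change matches its closed form and handles degenerate groups", {
  grid <- volume(array(1, c(8, 8, 8)), 1, "Bq/mL")
  mk <- function(id, val, dose = 1e6) {
    v <- grid; v$values[] <- val * 1.057
    subject_scan(id, "g", dose, v)
  }
  voi <- sphere_voi(c(3.5, 3.5, 3.5), 2, grid)
  # worked case on per-subject means (via %ID with values chosen so
  # normalized means equal the target values)
  a_vals <- c(1.1, 0.9, 1.0, 1.2); b_vals <- c(0.5, 0.6, 0.4, 0.5)
  sa <- lapply(seq_along(a_vals), function(i) mk(paste0("a", i), a_vals[i] * 1e4))
  sb <- lapply(seq_along(b_vals), function(i) mk(paste0("b", i), b_vals[i] * 1e4))
  out <- regional_fold_change(sa, sb, voi, normalization = "pid")
  expect_equal(out$fold, mean(a_vals) / mean(b_vals), tolerance = 1e-10)
  # independent oracle: stats::t.test pooled
  tt <- stats::t.test(a_vals, b_vals, var.equal = TRUE)
  expect_equal(out$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(abs(out$t), abs(unname(tt$statistic)), tolerance = 1e-10)
  # identical groups -> fold 1, p 1
  out1 <- regional_fold_change(sa, lapply(sa, function(s) {
    s$subject_id <- paste0(s$subject_id, "_b"); s }), voi, normalization = "pid")
  expect_equal(out1$fold, 1, tolerance = 1e-12)
  expect_equal(out1$p_value, 1, tolerance = 1e-12)
  # zero-variance degenerate case is flagged
  s2 <- lapply(1:3, function(i) mk(paste0("c", i), 2e4))
  s1 <- lapply(1:3, function(i) mk(paste0("d", i), 1e4))
  outz <- regional_fold_change(s2, s1, voi, normalization = "pid")
  expect_equal(outz$fold, 2, tolerance = 1e-10)
  expect_true(outz$flagged)
  expect_true(is.na(outz$p_value))
})
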