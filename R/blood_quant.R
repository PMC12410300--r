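# ------------------------------------------------------------------------
# Blood VOIs (geometric and data-driven), density-corrected image-derived
# blood levels, and the two normalization modes (blood ratio, %ID/g).
# ------------------------------------------------------------------------

#' Whole-blood density in g/mL used to convert Bq/mL to Bq/g
#' @export
BLOOD_DENSITY_G_PER_ML <- 1.057

new_voi <- function(kind, name, voxels, geometry = list()) {
  structure(list(kind = kind, name = name,
                 voxels = voxels, geometry = geometry),
            class = "voi")
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("<voi> '%s' (%s), %d voxels\n", x$name, x$kind, nrow(x$voxels)))
  invisible(x)
}

voi_linear_indices <- function(voi, dim3) {
  v <- voi$voxels
  if (any(v < 1L) || any(v[, 1] > dim3[1]) || any(v[, 2] > dim3[2]) ||
      any(v[, 3] > dim3[3]))
    stop("VOI voxels fall outside the volume grid")
  v[, 1] + (v[, 2] - 1L) * dim3[1] + (v[, 3] - 1L) * dim3[1] * dim3[2]
}

#' Spherical VOI in world coordinates
#'
#' A voxel is included iff its center lies within `radius_mm` of
#' `center_mm` (millimetres, NIfTI world convention: voxel `(i,j,k)` at
#' `((i-1)dx, (j-1)dy, (k-1)dz)`). The manual heart-sphere blood VOI and
#' the lung sphere (placed away from bone to avoid spill-over) both use
#' this primitive.
#'
#' @param center_mm world coordinate, length 3.
#' @param radius_mm sphere radius (> 0).
#' @param grid a [volume()] defining the target grid.
#' @param name VOI name.
#' @return A `voi`.
#' @export
sphere_voi <- function(center_mm, radius_mm, grid, name = "sphere") {
  stopifnot_volume(grid, what = "grid")
  if (!is.finite(radius_mm) || radius_mm <= 0) stop("'radius_mm' must be > 0")
  d <- dim(grid$values)
  co <- axis_coords_mm(d, grid$voxel_size_mm)
  d2 <- outer(outer((co[[1]] - center_mm[1])^2,
                    (co[[2]] - center_mm[2])^2, "+"),
              (co[[3]] - center_mm[3])^2, "+")
  inside <- which(d2 <= radius_mm^2, arr.ind = TRUE)
  if (!nrow(inside))
    stop("sphere VOI rasterizes to zero voxels; enlarge the radius or move the center")
  new_voi("sphere", name, inside,
          geometry = list(center_mm = center_mm, radius_mm = radius_mm))
}

#' Cylindrical (z-axis) VOI in world coordinates
#'
#' Axis-aligned cylinder along the third (body) axis; the primitive for a
#' carotid-artery blood VOI when heart spill-in must be avoided (e.g. in
#' infarct imaging).
#'
#' @param center_xy_mm world x/y of the cylinder axis (length 2).
#' @param radius_mm cylinder radius (> 0).
#' @param z_range_mm world z interval, length 2.
#' @param grid a [volume()] defining the target grid.
#' @param name VOI name.
#' @return A `voi`.
#' @export
cylinder_voi <- function(center_xy_mm, radius_mm, z_range_mm, grid,
                         name = "cylinder") {
  stopifnot_volume(grid, what = "grid")
  if (!is.finite(radius_mm) || radius_mm <= 0) stop("'radius_mm' must be > 0")
  d <- dim(grid$values)
  co <- axis_coords_mm(d, grid$voxel_size_mm)
  r2 <- outer((co[[1]] - center_xy_mm[1])^2, (co[[2]] - center_xy_mm[2])^2, "+")
  inz <- co[[3]] >= min(z_range_mm) & co[[3]] <= max(z_range_mm)
  inside <- which(outer(r2 <= radius_mm^2, inz, "&"), arr.ind = TRUE)
  if (!nrow(inside)) stop("cylinder VOI rasterizes to zero voxels")
  new_voi("cylinder", name, inside,
          geometry = list(center_xy_mm = center_xy_mm, radius_mm = radius_mm,
                          z_range_mm = z_range_mm))
}

#' VOI from a binary mask volume
#'
#' @param mask binary `"label"` [volume()].
#' @param name VOI name.
#' @return A `voi`.
#' @export
mask_voi <- function(mask, name = "mask") {
  stopifnot_volume(mask, units = "label", what = "mask")
  inside <- which(mask$values == 1L, arr.ind = TRUE)
  if (!nrow(inside)) stop("mask VOI is empty")
  new_voi("mask_label", name, inside)
}

cluster_union_voi <- function(clusters, name) {
  vox <- unique(do.call(rbind, lapply(clusters, `[[`, "voxels")))
  new_voi("cluster", name, vox[lex_order(vox), , drop = FALSE])
}

#' Derive the data-driven blood VOI
#'
#' Runs a voxelwise regression of the PET images on per-subject ex vivo
#' blood radioactivity, thresholds the positive-slope t-map at an
#' uncorrected one-sided p, and extracts connected clusters larger than
#' `min_size` voxels (defaults p = 0.005, more than 50 voxels). The
#' surviving voxels trace the blood pool/vascular tree. By default the VOI
#' is the union of all surviving clusters; with `seed_point_mm` it is
#' restricted to the single cluster containing that world point (e.g. the
#' heart blood pool centroid, mirroring an SPM-derived heart VOI, or the
#' carotid when heart spill-in must be avoided).
#'
#' @param scans list of [subject_scan()]; every scan must carry an ex vivo
#'   blood value unless `exvivo_blood` is given.
#' @param mask analysis mask (`"label"` [volume()]), e.g. from
#'   [build_analysis_mask()].
#' @param exvivo_blood optional per-subject covariate in Bq/g overriding
#'   the scans' `exvivo_blood_Bq_per_g`.
#' @param p uncorrected one-sided cluster-forming p (default 0.005).
#' @param min_size extent threshold, strict (default 50).
#' @param connectivity 6, 18 or 26.
#' @param seed_point_mm optional world point selecting a single cluster.
#' @return An object of class `blood_voi`: `voi`, `tmap`, `clusters`, and
#'   `params` recording p, min_size, connectivity, selection mode.
#' @export
derive_blood_voi <- function(scans, mask, exvivo_blood = NULL, p = 0.005,
                             min_size = 50L, connectivity = 18L,
                             seed_point_mm = NULL) {
  if (is.null(exvivo_blood))
    exvivo_blood <- vapply(scans, `[[`, 0, "exvivo_blood_Bq_per_g")
  if (any(is.na(exvivo_blood)))
    stop("every scan needs an ex vivo blood value to derive the blood VOI")
  tmap <- regression_tmap(scans, exvivo_blood, mask)
  t_crit <- t_threshold(p, tmap$dof, sided = "one")
  clusters <- extract_clusters(tmap, t_crit, min_size = min_size,
                               connectivity = connectivity)
  if (!length(clusters))
    stop("no cluster survived the blood-VOI thresholds; consider relaxing 'p' or 'min_size'")
  select <- "union"
  if (!is.null(seed_point_mm)) {
    select <- "seed"
    spacing <- tmap$t$voxel_size_mm
    seed_vox <- pmin(pmax(round(seed_point_mm / spacing) + 1L, 1L),
                     dim(tmap$t$values))
    hit <- vapply(clusters, function(cl)
      any(cl$voxels[, 1] == seed_vox[1] & cl$voxels[, 2] == seed_vox[2] &
            cl$voxels[, 3] == seed_vox[3]), logical(1))
    if (!any(hit))
      stop("no surviving cluster contains the seed point; check the seed or relax thresholds")
    clusters_sel <- clusters[which(hit)[1L]]
  } else {
    clusters_sel <- clusters
  }
  voi <- cluster_union_voi(clusters_sel, "data_driven_blood")
  structure(
    list(voi = voi, tmap = tmap, clusters = clusters,
         params = list(p = p, min_size = as.integer(min_size),
                       connectivity = as.integer(connectivity),
                       select = select)),
    class = "blood_voi")
}

#' @export
print.blood_voi <- function(x, ...) {
  cat(sprintf(
    "<blood_voi> %d voxels (%s of %d cluster(s); p = %g, min_size > %d, conn %d)\n",
    nrow(x$voi$voxels), x$params$select, length(x$clusters), x$params$p,
    x$params$min_size, x$params$connectivity))
  invisible(x)
}

#' Extract the density-corrected image-derived blood level
#'
#' Mean activity concentration over the VOI (Bq/mL) divided by the blood
#' density factor (default 1.057 g/mL), yielding Bq/g commensurate with
#' gamma-counter measurements of weighed blood samples.
#'
#' @param scan a [subject_scan()] (volume in Bq/mL).
#' @param voi a `voi` on the scan's grid.
#' @param density_g_per_mL blood density (default
#'   [BLOOD_DENSITY_G_PER_ML]).
#' @return An object of class `blood_estimate` with `subject_id`,
#'   `image_blood_Bq_per_g`, `exvivo_blood_Bq_per_g`, `voi_name`,
#'   `density_g_per_mL`.
#' @export
extract_blood_level <- function(scan, voi,
                                density_g_per_mL = BLOOD_DENSITY_G_PER_ML) {
  if (!inherits(scan, "subject_scan")) stop("'scan' must be a subject_scan")
  if (scan$vol$units != "Bq/mL")
    stop(sprintf("blood extraction requires Bq/mL input; got '%s'", scan$vol$units))
  if (!is.finite(density_g_per_mL) || density_g_per_mL <= 0)
    stop("'density_g_per_mL' must be > 0")
  idx <- voi_linear_indices(voi, dim(scan$vol$values))
  structure(
    list(subject_id = scan$subject_id,
         image_blood_Bq_per_g = mean(scan$vol$values[idx]) / density_g_per_mL,
         exvivo_blood_Bq_per_g = scan$exvivo_blood_Bq_per_g,
         voi_name = voi$name, density_g_per_mL = density_g_per_mL),
    class = "blood_estimate")
}

#' Image-derived blood levels for a whole cohort
#'
#' @param scans list of [subject_scan()].
#' @inheritParams extract_blood_level
#' @return Data frame with one row per subject: `subject_id`,
#'   `image_blood_Bq_per_g`, `exvivo_blood_Bq_per_g`, `voi_name`.
#' @export
extract_blood_levels <- function(scans, voi,
                                 density_g_per_mL = BLOOD_DENSITY_G_PER_ML) {
  est <- lapply(scans, extract_blood_level, voi = voi,
                density_g_per_mL = density_g_per_mL)
  data.frame(
    subject_id = vapply(est, `[[`, "", "subject_id"),
    image_blood_Bq_per_g = vapply(est, `[[`, 0, "image_blood_Bq_per_g"),
    exvivo_blood_Bq_per_g = vapply(est, `[[`, 0, "exvivo_blood_Bq_per_g"),
    voi_name = vapply(est, `[[`, "", "voi_name"),
    stringsAsFactors = FALSE)
}

#' Normalize a scan to its image-derived blood level
#'
#' Voxelwise `(Bq/mL / density) / image_blood_Bq_per_g`, giving a unitless
#' tissue-to-blood ratio. By construction the mean of the normalized image
#' over the defining blood VOI is exactly 1 (when the same density factor
#' is used, which the `blood_estimate` guarantees).
#'
#' @param scan a [subject_scan()].
#' @param blood a `blood_estimate` from [extract_blood_level()], or a
#'   positive blood level in Bq/g.
#' @return A [volume()] with units `"ratio"`.
#' @export
normalize_to_blood <- function(scan, blood) {
  if (inherits(blood, "blood_estimate")) {
    level <- blood$image_blood_Bq_per_g
    density <- blood$density_g_per_mL
  } else {
    level <- blood
    density <- BLOOD_DENSITY_G_PER_ML
  }
  if (!is.finite(level) || level <= 0)
    stop("blood level must be > 0 for blood normalization")
  if (scan$vol$units != "Bq/mL")
    stop(sprintf("blood normalization requires Bq/mL input; got '%s'", scan$vol$units))
  volume(scan$vol$values / density / level, scan$vol$voxel_size_mm, "ratio")
}

#' Normalize a scan to percent injected dose per gram
#'
#' Voxelwise `(Bq/mL / density) / injected_dose_Bq * 100`. No decay
#' correction is applied anywhere in the package; inputs are assumed
#' decay-corrected to a common reference by the scanner.
#'
#' @param scan a [subject_scan()] with a positive injected dose.
#' @param density_g_per_mL tissue density for the Bq/mL to Bq/g conversion
#'   (default [BLOOD_DENSITY_G_PER_ML], keeping %ID/g commensurate with
#'   the blood workflow).
#' @return A [volume()] with units `"%ID/g"`.
#' @export
normalize_to_pid <- function(scan, density_g_per_mL = BLOOD_DENSITY_G_PER_ML) {
  if (!inherits(scan, "subject_scan")) stop("'scan' must be a subject_scan")
  if (!is.finite(scan$injected_dose_Bq) || scan$injected_dose_Bq <= 0)
    stop("injected dose is missing or non-positive")
  if (scan$vol$units != "Bq/mL")
    stop(sprintf("%%ID/g normalization requires Bq/mL input; got '%s'", scan$vol$units))
  volume(scan$vol$values / density_g_per_mL / scan$injected_dose_Bq * 100,
         scan$vol$voxel_size_mm, "%ID/g")
}
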