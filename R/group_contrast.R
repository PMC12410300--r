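# ------------------------------------------------------------------------
# Voxelwise group comparison of normalized volumes, per-organ T summaries,
# and regional fold-change statistics.
# ------------------------------------------------------------------------

normalize_scans <- function(scans, normalization, blood = NULL,
                            density_g_per_mL = BLOOD_DENSITY_G_PER_ML) {
  if (normalization == "blood") {
    if (is.null(blood))
      stop("blood normalization requested but no blood estimates or VOI supplied")
    if (inherits(blood, "voi") || inherits(blood, "blood_voi")) {
      voi <- if (inherits(blood, "blood_voi")) blood$voi else blood
      lapply(scans, function(s)
        normalize_to_blood(s, extract_blood_level(s, voi, density_g_per_mL)))
    } else if (is.data.frame(blood)) {
      lapply(scans, function(s) {
        row <- match(s$subject_id, blood$subject_id)
        if (is.na(row))
          stop(sprintf("no blood estimate for subject '%s'", s$subject_id))
        normalize_to_blood(s, blood$image_blood_Bq_per_g[row])
      })
    } else stop("'blood' must be a VOI, blood_voi, or blood-estimate data frame")
  } else {
    lapply(scans, normalize_to_pid, density_g_per_mL = density_g_per_mL)
  }
}

#' Voxelwise group contrast of normalized PET volumes
#'
#' Normalizes every subject (image-derived blood ratio or %ID/g), computes
#' the pooled-variance two-sample t-map (positive where group A > group B),
#' thresholds one-sided at the uncorrected `p` (default 0.05 for contrast
#' maps) and keeps connected clusters larger than `min_size` voxels
#' (default more than 50).
#'
#' @param scansA,scansB disjoint lists of [subject_scan()].
#' @param normalization `"blood"` or `"pid"`.
#' @param mask analysis mask (`"label"` [volume()]).
#' @param blood for `"blood"`: a `voi`/`blood_voi` (levels are extracted
#'   per subject) or a data frame from [extract_blood_levels()].
#' @param p uncorrected one-sided p for the cluster-forming threshold.
#' @param min_size extent threshold, strict.
#' @param connectivity 6, 18 or 26.
#' @param density_g_per_mL density factor for the unit conversions.
#' @param contrast descriptor string.
#' @return An object of class `contrast_result`: `tmap`, `clusters`,
#'   `normalization`, `params`.
#' @export
run_contrast <- function(scansA, scansB, normalization = c("blood", "pid"),
                         mask, blood = NULL, p = 0.05, min_size = 50L,
                         connectivity = 18L,
                         density_g_per_mL = BLOOD_DENSITY_G_PER_ML,
                         contrast = "groupA > groupB") {
  normalization <- match.arg(normalization)
  idsA <- vapply(scansA, `[[`, "", "subject_id")
  idsB <- vapply(scansB, `[[`, "", "subject_id")
  if (length(intersect(idsA, idsB)))
    stop(sprintf("groups are not disjoint: %s",
                 paste(intersect(idsA, idsB), collapse = ", ")))
  volsA <- normalize_scans(scansA, normalization, blood, density_g_per_mL)
  volsB <- normalize_scans(scansB, normalization, blood, density_g_per_mL)
  tmap <- two_sample_tmap(volsA, volsB, mask, contrast = contrast)
  t_crit <- t_threshold(p, tmap$dof, sided = "one")
  clusters <- extract_clusters(tmap, t_crit, min_size = min_size,
                               connectivity = connectivity)
  structure(
    list(tmap = tmap, clusters = clusters, normalization = normalization,
         params = list(p = p, min_size = as.integer(min_size),
                       connectivity = as.integer(connectivity),
                       t_crit = t_crit)),
    class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> '%s', %s-normalized, %d cluster(s) at p = %g, size > %d\n",
              x$tmap$contrast, x$normalization, length(x$clusters),
              x$params$p, x$params$min_size))
  invisible(x)
}

#' Per-organ T-value summary of a t-map
#'
#' For each organ mask: mean t, peak t and voxel count over the
#' intersection of the organ with the t-map's analysis mask. Organs whose
#' intersection is empty are reported with `n_voxels = 0` and `NA`
#' statistics (flagged).
#'
#' @param tmap a `t_map`.
#' @param organ_masks named list of binary `"label"` [volume()]s on the
#'   t-map grid, or a `phantom_atlas` together with `organs`.
#' @param organs region names when `organ_masks` is an atlas (defaults to
#'   the four peripheral reporting organs: lung, liver, spleen,
#'   bone marrow).
#' @return Data frame: `organ`, `n_voxels`, `mean_t`, `peak_t`, `flagged`.
#' @export
organ_t_summary <- function(tmap, organ_masks,
                            organs = c("lung", "liver", "spleen", "bone_marrow")) {
  if (!inherits(tmap, "t_map")) stop("'tmap' must be a t_map")
  if (inherits(organ_masks, "phantom_atlas"))
    organ_masks <- stats::setNames(
      lapply(organs, atlas_region_mask, atlas = organ_masks), organs)
  if (is.null(names(organ_masks)) || any(!nzchar(names(organ_masks))))
    stop("'organ_masks' must be a named list")
  rows <- lapply(names(organ_masks), function(org) {
    m <- organ_masks[[org]]
    stopifnot_volume(m, units = "label", what = org)
    if (!identical(dim(m$values), dim(tmap$t$values)))
      stop(sprintf("organ mask '%s' is not on the t-map grid", org))
    idx <- which(m$values == 1L & tmap$mask$values == 1L)
    if (!length(idx))
      data.frame(organ = org, n_voxels = 0L, mean_t = NA_real_,
                 peak_t = NA_real_, flagged = TRUE, stringsAsFactors = FALSE)
    else {
      tv <- tmap$t$values[idx]
      data.frame(organ = org, n_voxels = length(idx), mean_t = mean(tv),
                 peak_t = max(tv), flagged = FALSE, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Regional fold change and group test in a VOI
#'
#' Computes each subject's mean normalized uptake inside the VOI, then
#' `fold = mean(A) / mean(B)` and a two-tailed unpaired pooled-variance
#' t-test on the per-subject means. With zero pooled variance the p-value
#' is undefined and flagged.
#'
#' @inheritParams run_contrast
#' @param voi a `voi` on the common grid.
#' @return List: `fold`, `p_value`, `t`, `dof`, `mean_A`, `mean_B`,
#'   `values_A`, `values_B`, `flagged`.
#' @export
regional_fold_change <- function(scansA, scansB, voi,
                                 normalization = c("blood", "pid"),
                                 blood = NULL,
                                 density_g_per_mL = BLOOD_DENSITY_G_PER_ML) {
  normalization <- match.arg(normalization)
  if (length(scansA) < 2L || length(scansB) < 2L)
    stop("each group needs at least 2 subjects")
  volsA <- normalize_scans(scansA, normalization, blood, density_g_per_mL)
  volsB <- normalize_scans(scansB, normalization, blood, density_g_per_mL)
  idx <- voi_linear_indices(voi, dim(volsA[[1]]$values))
  a <- vapply(volsA, function(v) mean(v$values[idx]), numeric(1))
  b <- vapply(volsB, function(v) mean(v$values[idx]), numeric(1))
  if (mean(b) == 0) stop("group B mean uptake in the VOI is zero; fold change undefined")
  nA <- length(a); nB <- length(b)
  dof <- nA + nB - 2L
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / dof
  flagged <- sp2 <= 0
  tval <- if (flagged) NA_real_ else
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / nA + 1 / nB))
  pval <- if (flagged) NA_real_ else 2 * stats::pt(-abs(tval), df = dof)
  list(fold = mean(a) / mean(b), p_value = pval, t = tval, dof = dof,
       mean_A = mean(a), mean_B = mean(b), values_A = a, values_B = b,
       flagged = flagged)
}
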