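# ------------------------------------------------------------------------
# End-to-end workflow: blood-VOI derivation -> image-derived blood levels
# -> blood and %ID normalization -> voxelwise contrasts -> per-organ T
# summaries -> agreement statistics -> JSON report + NIfTI artifacts.
# ------------------------------------------------------------------------

REPORT_SCHEMA_VERSION <- "1.0"

#' Pipeline configuration
#'
#' Validated bundle of the analysis parameters: cluster-forming thresholds
#' (p = 0.005 for the data-driven blood VOI, p = 0.05 for contrast maps),
#' the strict more-than-`min_cluster`-voxels extent threshold (default 50),
#' the blood density factor (1.057 g/mL), and the cluster connectivity
#' (default 18, the SPM convention).
#'
#' @param p_blood_voi uncorrected p for blood-VOI derivation.
#' @param p_contrast uncorrected p for group-contrast maps.
#' @param min_cluster extent threshold (clusters must exceed it).
#' @param density blood density in g/mL.
#' @param connectivity 6, 18 or 26.
#' @param normalization `"both"`, `"blood"` or `"pid"`.
#' @param mask_min_value analysis-mask threshold in Bq/mL.
#' @param blood_seed_region optional atlas region whose centroid seeds the
#'   blood-VOI cluster selection (e.g. `"heart_blood_pool"`); `NULL` takes
#'   the union of surviving clusters.
#' @param organs organ names summarized from the contrast t-maps.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(p_blood_voi = 0.005, p_contrast = 0.05,
                            min_cluster = 50L, density = BLOOD_DENSITY_G_PER_ML,
                            connectivity = 18L, normalization = "both",
                            mask_min_value = 0,
                            blood_seed_region = "heart_blood_pool",
                            organs = c("lung", "liver", "spleen", "bone_marrow")) {
  for (p in c(p_blood_voi, p_contrast))
    if (!is.finite(p) || p <= 0 || p >= 1) stop("p thresholds must be in (0, 1)")
  if (!is.finite(min_cluster) || min_cluster < 0) stop("'min_cluster' must be >= 0")
  if (!is.finite(density) || density <= 0) stop("'density' must be > 0")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("'connectivity' must be 6, 18 or 26")
  normalization <- match.arg(normalization, c("both", "blood", "pid"))
  structure(
    list(p_blood_voi = p_blood_voi, p_contrast = p_contrast,
         min_cluster = as.integer(min_cluster), density = density,
         connectivity = as.integer(connectivity), normalization = normalization,
         mask_min_value = mask_min_value, blood_seed_region = blood_seed_region,
         organs = organs),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  do.call(pipeline_config, cfg)
}

voi_to_mask <- function(voi, grid) {
  m <- array(0L, dim(grid$values))
  m[voi_linear_indices(voi, dim(grid$values))] <- 1L
  volume(m, grid$voxel_size_mm, "label")
}

#' Run the full blood-normalization analysis pipeline
#'
#' Executes the two-workflow analysis on a cohort with two groups:
#' derives the data-driven blood VOI from ex vivo blood values, extracts
#' per-subject image-derived blood levels, normalizes all volumes to blood
#' level and/or %ID/g, runs the voxelwise group contrast under each
#' normalization, summarizes per-organ T values, and computes agreement
#' statistics (linear fit and Bland-Altman, ex vivo vs image-derived
#' blood). Writes a versioned JSON report plus NIfTI t-maps and VOI masks
#' to `out_dir` when given.
#'
#' @param scans list of [subject_scan()] covering exactly two groups, or a
#'   manifest CSV path (see [load_cohort()]); all subjects need ex vivo
#'   blood values.
#' @param group_a name of the positive-contrast group (default: first
#'   group encountered).
#' @param atlas optional `phantom_atlas` (or named list of organ masks)
#'   enabling per-organ T summaries and centroid-seeded VOI selection.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for report.json and NIfTI
#'   artifacts.
#' @return The report, an R list mirroring the JSON schema, invisibly
#'   when `out_dir` is given.
#' @export
run_pipeline <- function(scans, group_a = NULL, atlas = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  if (is.character(scans)) scans <- load_cohort(scans)$scans
  check_cohort_grids(scans)
  if (any(is.na(vapply(scans, `[[`, 0, "exvivo_blood_Bq_per_g"))))
    stop(paste("pipeline stage blood_voi: missing ex vivo blood values;",
               "use the normalization-only operations (normalize_to_pid,",
               "normalize_to_blood with a geometric VOI) for such cohorts"))
  groups <- vapply(scans, `[[`, "", "group")
  glev <- unique(groups)
  if (length(glev) != 2L)
    stop(sprintf("pipeline expects exactly 2 groups; found: %s",
                 paste(glev, collapse = ", ")))
  if (is.null(group_a)) group_a <- glev[1L]
  if (!group_a %in% glev) stop(sprintf("unknown group_a '%s'", group_a))
  group_b <- setdiff(glev, group_a)
  scansA <- scans[groups == group_a]
  scansB <- scans[groups == group_b]

  mask <- build_analysis_mask(scans, min_value = config$mask_min_value)
  seed_mm <- if (!is.null(atlas) && inherits(atlas, "phantom_atlas") &&
                 !is.null(config$blood_seed_region))
    region_centroid_mm(atlas, config$blood_seed_region) else NULL
  bv <- derive_blood_voi(scans, mask, p = config$p_blood_voi,
                         min_size = config$min_cluster,
                         connectivity = config$connectivity,
                         seed_point_mm = seed_mm)
  levels <- extract_blood_levels(scans, bv$voi,
                                 density_g_per_mL = config$density)
  fit <- linear_fit(levels$exvivo_blood_Bq_per_g, levels$image_blood_Bq_per_g)
  ba <- bland_altman(levels$exvivo_blood_Bq_per_g, levels$image_blood_Bq_per_g)

  modes <- if (config$normalization == "both") c("blood", "pid")
           else config$normalization
  contrasts <- list()
  for (mode in modes) {
    cr <- run_contrast(scansA, scansB, normalization = mode, mask = mask,
                       blood = if (mode == "blood") levels else NULL,
                       p = config$p_contrast, min_size = config$min_cluster,
                       connectivity = config$connectivity,
                       density_g_per_mL = config$density,
                       contrast = sprintf("%s > %s", group_a, group_b))
    organ <- if (!is.null(atlas))
      organ_t_summary(cr$tmap, atlas, organs = config$organs) else NULL
    contrasts[[mode]] <- list(result = cr, organ_summary = organ)
  }

  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    parameters = list(
      p_blood_voi = config$p_blood_voi, p_contrast = config$p_contrast,
      min_cluster = config$min_cluster, density_g_per_mL = config$density,
      connectivity = config$connectivity,
      blood_voi_selection = bv$params$select,
      groups = list(A = group_a, B = group_b),
      n_subjects = list(A = length(scansA), B = length(scansB))),
    blood_voi = list(n_voxels = nrow(bv$voi$voxels),
                     n_clusters = length(bv$clusters),
                     peak_t = bv$clusters[[1L]]$peak_t),
    blood_levels = levels,
    agreement = list(
      slope = fit$slope, intercept = fit$intercept,
      r_squared = fit$r_squared, p_value = fit$p_value,
      ci95_slope = fit$ci95_slope,
      bland_altman = list(bias_Bq_per_g = ba$bias, sd_Bq_per_g = ba$sd_diff,
                          loa_low = ba$loa_low, loa_high = ba$loa_high)),
    contrasts = lapply(contrasts, function(cc) list(
      n_clusters = length(cc$result$clusters),
      cluster_sizes = vapply(cc$result$clusters, `[[`, 0L, "size_voxels"),
      cluster_peak_t = vapply(cc$result$clusters, `[[`, 0, "peak_t"),
      organ_summary = cc$organ_summary)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    grid <- scans[[1L]]$vol
    write_volume(voi_to_mask(bv$voi, grid),
                 file.path(out_dir, "blood_voi.nii.gz"))
    write_volume(bv$tmap$t, file.path(out_dir, "blood_regression_tmap.nii.gz"))
    write_volume(mask, file.path(out_dir, "analysis_mask.nii.gz"))
    for (mode in names(contrasts))
      write_volume(contrasts[[mode]]$result$tmap$t,
                   file.path(out_dir, sprintf("contrast_tmap_%s.nii.gz", mode)))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}
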