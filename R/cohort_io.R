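#' One subject's co-registered PET scan
#'
#' Bundles a subject's activity volume (Bq/mL) with its identifying
#' metadata: group/genotype label, injected dose, and (optionally) the
#' gamma-counter ex vivo blood radioactivity used as regression covariate
#' when deriving the data-driven blood VOI.
#'
#' @param subject_id unique string.
#' @param group group/genotype label.
#' @param injected_dose_Bq injected activity in Bq (> 0).
#' @param vol a [volume()] in Bq/mL.
#' @param exvivo_blood_Bq_per_g ex vivo blood radioactivity in Bq/g, or `NA`
#'   when no blood sample was drawn.
#' @return An object of class `subject_scan`.
#' @export
subject_scan <- function(subject_id, group, injected_dose_Bq, vol,
                         exvivo_blood_Bq_per_g = NA_real_) {
  stopifnot_volume(vol, units = "Bq/mL", what = "vol")
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id))
    stop("'subject_id' must be a non-empty string")
  if (!is.finite(injected_dose_Bq) || injected_dose_Bq <= 0)
    stop("'injected_dose_Bq' must be positive")
  if (!is.na(exvivo_blood_Bq_per_g) &&
      (!is.finite(exvivo_blood_Bq_per_g) || exvivo_blood_Bq_per_g < 0))
    stop("'exvivo_blood_Bq_per_g' must be >= 0 or NA")
  structure(
    list(subject_id = subject_id, group = as.character(group),
         injected_dose_Bq = as.numeric(injected_dose_Bq),
         exvivo_blood_Bq_per_g = as.numeric(exvivo_blood_Bq_per_g),
         vol = vol),
    class = "subject_scan")
}

#' @export
print.subject_scan <- function(x, ...) {
  cat(sprintf("<subject_scan> %s (group %s), dose %.3g Bq, ex vivo blood %s\n",
              x$subject_id, x$group, x$injected_dose_Bq,
              if (is.na(x$exvivo_blood_Bq_per_g)) "missing"
              else sprintf("%.3g Bq/g", x$exvivo_blood_Bq_per_g)))
  print(x$vol)
  invisible(x)
}

manifest_columns <- c("subject_id", "group", "injected_dose_Bq",
                      "exvivo_blood_Bq_per_g", "volume_path")

check_cohort_grids <- function(scans) {
  if (length(scans) < 1L) stop("cohort is empty")
  ref <- scans[[1L]]$vol
  for (s in scans[-1L]) {
    if (!same_grid(ref, s$vol))
      stop(sprintf(
        "grid mismatch: subject '%s' (%s @ %s mm) vs subject '%s' (%s @ %s mm)",
        scans[[1L]]$subject_id, paste(dim(ref$values), collapse = "x"),
        paste(format(ref$voxel_size_mm), collapse = "x"),
        s$subject_id, paste(dim(s$vol$values), collapse = "x"),
        paste(format(s$vol$voxel_size_mm), collapse = "x")))
  }
  invisible(scans)
}

#' Load a cohort from a CSV manifest
#'
#' The manifest is a UTF-8 CSV with header
#' `subject_id,group,injected_dose_Bq,exvivo_blood_Bq_per_g,volume_path`.
#' Relative `volume_path` entries are resolved against the manifest's
#' directory. All volumes must share grid shape and voxel spacing (the
#' package assumes images are already co-registered to a common grid);
#' a mismatch is an error naming both subjects. A blank/NA ex vivo blood
#' field is allowed — such subjects can be normalized but cannot
#' contribute to blood-VOI derivation.
#'
#' @param manifest_path path to the CSV manifest.
#' @return A list with `scans` (list of [subject_scan()], manifest order)
#'   and `manifest` (the parsed data frame).
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop(sprintf("manifest not found: %s", manifest_path))
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(manifest_columns, names(man))
  if (length(missing_cols))
    stop(sprintf("manifest is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(man$subject_id))
    stop(sprintf("duplicate subject_id in manifest: %s",
                 paste(unique(man$subject_id[duplicated(man$subject_id)]),
                       collapse = ", ")))
  base_dir <- dirname(normalizePath(manifest_path))
  scans <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$volume_path[i]
    if (!file.exists(p)) p <- file.path(base_dir, man$volume_path[i])
    subject_scan(man$subject_id[i], man$group[i], man$injected_dose_Bq[i],
                 read_volume(p, units = "Bq/mL"),
                 exvivo_blood_Bq_per_g =
                   suppressWarnings(as.numeric(man$exvivo_blood_Bq_per_g[i])))
  })
  check_cohort_grids(scans)
  list(scans = scans, manifest = man)
}

#' Build the cohort analysis mask
#'
#' A voxel enters the mask iff its value is finite and strictly greater
#' than `min_value` in every subject — the voxelwise logical AND used as
#' implicit mask for all cross-subject statistics, excluding air and
#' out-of-body voxels.
#'
#' @param scans list of [subject_scan()] on a common grid.
#' @param min_value threshold in Bq/mL (default 0).
#' @return Binary [volume()] with units `"label"`.
#' @export
build_analysis_mask <- function(scans, min_value = 0) {
  check_cohort_grids(scans)
  acc <- array(TRUE, dim(scans[[1L]]$vol$values))
  for (s in scans) {
    v <- s$vol$values
    acc <- acc & is.finite(v) & (v > min_value)
  }
  if (!any(acc)) stop("analysis mask is empty: no voxel exceeds 'min_value' in all subjects")
  volume(array(as.integer(acc), dim(acc)), scans[[1L]]$vol$voxel_size_mm, "label")
}

# value matrix (n_subjects x n_masked_voxels) for vectorized voxel stats
scan_matrix <- function(vols, mask_idx) {
  t(vapply(vols, function(v) v$values[mask_idx], numeric(length(mask_idx))))
}
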