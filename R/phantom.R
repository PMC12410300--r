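# ------------------------------------------------------------------------
# Digital-mouse phantom: label atlas + cohort simulator.
#
# The generative model is linear two-component at a single late time point:
# tissue activity (Bq/g) = blood_volume_fraction * B_i            (blood-borne)
#                        + binding_scale * expression * dose * u  (specific)
# followed by Gaussian PSF blur and signal-proportional noise. Knockout
# groups have binding_scale = 0, so their images are a deterministic
# function of the subject's blood level alone.
# ------------------------------------------------------------------------

PHANTOM_REGIONS <- c("background", "heart_blood_pool", "infarct", "myocardium",
                     "carotid", "brain_hippocampus", "brain_white_matter",
                     "brain_cortex", "lung", "spleen", "liver",
                     "bone_marrow", "bone")

# geometry in fractional coordinates of each axis (z = body axis, brain at
# high z). Shapes: ellipsoid (center + semi-axes) or z-cylinder (center_xy,
# radius_frac, z range). `min_vox` inflates tiny structures to at least the
# voxel(s) at their center so every region exists on coarse grids.
phantom_geometry <- function() {
  list(
    heart_blood_pool = list(shape = "ellipsoid", center = c(0.50, 0.45, 0.54),
                            semi = c(0.070, 0.070, 0.060), min_vox = 1.05),
    infarct = list(shape = "ellipsoid", center = c(0.50, 0.355, 0.54),
                   semi = c(0.050, 0.024, 0.050), min_vox = 0.71),
    myocardium = list(shape = "ellipsoid", center = c(0.50, 0.45, 0.54),
                      semi = c(0.115, 0.115, 0.100), min_vox = 1.8),
    carotid = list(shape = "cylinder", center_xy = c(0.44, 0.50),
                   radius = 0.035, zlim = c(0.67, 0.76), min_vox = 0.71),
    brain_hippocampus = list(shape = "ellipsoid", center = c(0.42, 0.50, 0.885),
                             semi = c(0.035, 0.035, 0.030), min_vox = 0.71),
    brain_white_matter = list(shape = "ellipsoid", center = c(0.50, 0.50, 0.885),
                              semi = c(0.090, 0.080, 0.050), min_vox = 1.05),
    brain_cortex = list(shape = "ellipsoid", center = c(0.50, 0.50, 0.890),
                        semi = c(0.160, 0.150, 0.085), min_vox = 2.0),
    lung = list(shape = "ellipsoid2", center = c(0.28, 0.50, 0.56),
                center2 = c(0.72, 0.50, 0.56),
                semi = c(0.090, 0.100, 0.090), min_vox = 1.05),
    spleen = list(shape = "ellipsoid", center = c(0.72, 0.42, 0.33),
                  semi = c(0.050, 0.040, 0.060), min_vox = 0.71),
    liver = list(shape = "ellipsoid", center = c(0.42, 0.48, 0.30),
                 semi = c(0.150, 0.130, 0.090), min_vox = 1.05),
    bone_marrow = list(shape = "cylinder", center_xy = c(0.50, 0.68),
                       radius = 0.022, zlim = c(0.18, 0.70), min_vox = 0.71),
    bone = list(shape = "cylinder", center_xy = c(0.50, 0.68),
                radius = 0.048, zlim = c(0.14, 0.74), min_vox = 1.8)
  )
}

# defaults chosen so whole-blood regions are pure blood, and specific WT
# uptake is the same order as the organ's blood-borne signal (the
# antibody-tracer regime in which blood normalization pays off).
# trem2_expression is in units of fractional injected dose per gram.
phantom_tissue_defaults <- function() {
  data.frame(
    region = PHANTOM_REGIONS,
    label = seq_along(PHANTOM_REGIONS) - 1L,
    blood_volume_fraction = c(0, 1, 0.08, 0.10, 1, 0.04, 0.03, 0.04,
                              0.15, 0.30, 0.30, 0.10, 0.04),
    trem2_expression = c(0, 0, 0.0050, 0.0004, 0, 0.0007, 0.0001, 0.0005,
                         0.0004, 0.0006, 0.0025, 0.0020, 0.0003),
    stringsAsFactors = FALSE)
}

#' Build the default digital-mouse atlas
#'
#' Places 13 anatomical regions (background, heart blood pool, infarct,
#' myocardium, carotid, hippocampus, white matter, cortex, lung, spleen,
#' liver, bone marrow, bone) as ellipsoids, shells and cylinders at
#' anatomically plausible relative positions on the requested grid: heart
#' blood pool at thorax center, carotid cylinder in the neck, brain at the
#' high-z end, liver/spleen in the abdomen, spine (bone around bone marrow)
#' dorsally. Regions are rasterized center-of-voxel-inside in precedence
#' order, so labels are disjoint by construction. Small structures are
#' guaranteed at least the voxel containing their center; if even that is
#' impossible the grid is too small and an error is raised.
#'
#' Each region carries a blood volume fraction (1 for whole-blood regions:
#' heart blood pool and carotid) and a TREM2 expression score (0 for
#' background and blood) controlling specific tracer binding in
#' [simulate_cohort()].
#'
#' @param grid_shape integer length-3 voxel counts, each >= 16.
#' @param voxel_size_mm isotropic voxel spacing in millimetres.
#' @return An object of class `phantom_atlas`: `labels` (a `"label"`
#'   [volume()]), `regions` (data frame with region, label,
#'   blood_volume_fraction, trem2_expression).
#' @export
build_default_atlas <- function(grid_shape = c(64, 64, 128), voxel_size_mm = 0.5) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("'grid_shape' must be three integers, each >= 16")
  if (!is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("'voxel_size_mm' must be positive")
  d <- grid_shape
  # fractional voxel-center coordinates per axis
  fr <- lapply(1:3, function(k) (seq_len(d[k]) - 0.5) / d[k])
  lab <- array(0L, d)
  geom <- phantom_geometry()
  tissue <- phantom_tissue_defaults()
  for (region in names(geom)) {
    g <- geom[[region]]
    code <- tissue$label[tissue$region == region]
    m <- rasterize_region(g, fr, d)
    m <- m & (lab == 0L)
    if (!any(m)) {
      # guarantee the voxel containing the region center
      ctr <- if (g$shape == "cylinder")
        c(g$center_xy, mean(g$zlim)) else g$center
      iv <- pmin(pmax(round(ctr * d + 0.5), 1L), d)
      if (lab[iv[1], iv[2], iv[3]] != 0L)
        stop(sprintf("grid too small to place region '%s'", region))
      m[iv[1], iv[2], iv[3]] <- TRUE
    }
    lab[m] <- code
  }
  structure(
    list(labels = volume(lab, voxel_size_mm, "label"), regions = tissue),
    class = "phantom_atlas")
}

rasterize_region <- function(g, fr, d) {
  semi_vox <- function(semi) pmax(semi * d, g$min_vox) / d
  ell <- function(center, semi) {
    s <- semi_vox(semi)
    dx2 <- ((fr[[1]] - center[1]) / s[1])^2
    dy2 <- ((fr[[2]] - center[2]) / s[2])^2
    dz2 <- ((fr[[3]] - center[3]) / s[3])^2
    outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
  }
  if (g$shape == "ellipsoid") {
    ell(g$center, g$semi)
  } else if (g$shape == "ellipsoid2") {
    ell(g$center, g$semi) | ell(g$center2, g$semi)
  } else { # z-cylinder
    r <- pmax(g$radius * d[1:2], g$min_vox) / d[1:2]
    dx2 <- ((fr[[1]] - g$center_xy[1]) / r[1])^2
    dy2 <- ((fr[[2]] - g$center_xy[2]) / r[2])^2
    inz <- fr[[3]] >= g$zlim[1] & fr[[3]] <= g$zlim[2]
    if (!any(inz)) inz[which.min(abs(fr[[3]] - mean(g$zlim)))] <- TRUE
    disc <- outer(dx2, dy2, "+") <= 1
    outer(disc, inz, "&")
  }
}

#' @export
print.phantom_atlas <- function(x, ...) {
  counts <- tabulate(x$labels$values + 1L, nbins = nrow(x$regions))
  cat(sprintf("<phantom_atlas> %s grid @ %g mm\n",
              paste(dim(x$labels$values), collapse = "x"),
              x$labels$voxel_size_mm[1]))
  print(cbind(x$regions, n_voxels = counts), row.names = FALSE)
  invisible(x)
}

#' Binary mask for one atlas region
#'
#' @param atlas a [build_default_atlas()] object.
#' @param region region name (see `atlas$regions$region`).
#' @return Binary `"label"` [volume()].
#' @export
atlas_region_mask <- function(atlas, region) {
  code <- atlas$regions$label[match(region, atlas$regions$region)]
  if (is.na(code)) stop(sprintf("unknown region '%s'", region))
  m <- atlas$labels$values == code
  volume(array(as.integer(m), dim(m)), atlas$labels$voxel_size_mm, "label")
}

#' World-coordinate centroid of an atlas region (mm)
#'
#' Convenient source of seed points, e.g. the heart blood pool or carotid
#' centroid for seed-restricted blood-VOI derivation.
#'
#' @inheritParams atlas_region_mask
#' @return Numeric length-3 world coordinate in millimetres.
#' @export
region_centroid_mm <- function(atlas, region) {
  m <- atlas_region_mask(atlas, region)
  idx <- which(m$values == 1L, arr.ind = TRUE)
  (colMeans(idx) - 1) * atlas$labels$voxel_size_mm
}

#' Specify a simulated cohort
#'
#' Encodes the study design of a late-time-point antibody-PET experiment:
#' group descriptors (specific-binding scale, with 0 encoding knockout, and
#' a group blood-level multiplier), injected-dose distribution,
#' inter-subject lognormal blood-clearance variability, scanner
#' point-spread blur, signal-proportional noise, and the relative error of
#' the simulated ex vivo gamma-counter measurement. The seed fully
#' determines the simulated cohort.
#'
#' Defaults emulate an 11-vs-11 wild-type vs TREM2-knockout whole-body
#' design at 20 h post injection: 34 +/- 6 MBq injected, 25% clearance CV
#' (so that percent-injected-dose normalization is visibly confounded by
#' blood-level variability), 0.8 mm PSF (typical small-animal PET
#' resolution), and a 15% higher knockout blood level (no target sink).
#'
#' @param n_per_group subjects per group (>= 2).
#' @param groups list of group descriptors, each a list with `name`,
#'   `specific_binding_scale` (>= 0; 0 = knockout) and
#'   `blood_level_multiplier` (> 0).
#' @param dose_mean_Bq,dose_cv lognormal injected-dose mean (Bq) and CV.
#' @param clearance_cv lognormal CV of inter-subject blood concentration.
#' @param psf_sigma_mm Gaussian PSF standard deviation in mm.
#' @param noise_scale multiplier on the signal-proportional noise SD
#'   (noise SD = `noise_scale * sqrt(max(signal, 1))` Bq/mL).
#' @param blood_assay_cv relative error of the ex vivo blood measurement.
#' @param base_blood_frac_per_g baseline blood concentration per unit
#'   injected dose (g^-1); 0.03 puts blood near 3 percent ID/g, typical for
#'   a slowly clearing antibody at 20 h.
#' @param uptake_coupling expression-to-uptake coupling constant `u`
#'   (fixed at 1; expression scores already carry the scale).
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 11L,
                        groups = list(
                          list(name = "wt", specific_binding_scale = 1,
                               blood_level_multiplier = 1),
                          list(name = "trem2_ko", specific_binding_scale = 0,
                               blood_level_multiplier = 1.15)),
                        dose_mean_Bq = 3.4e7, dose_cv = 0.18,
                        clearance_cv = 0.25, psf_sigma_mm = 0.8,
                        noise_scale = 30, blood_assay_cv = 0.05,
                        base_blood_frac_per_g = 0.03,
                        uptake_coupling = 1, seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 2L) stop("'n_per_group' must be >= 2")
  for (g in groups) {
    if (is.null(g$name) || is.null(g$specific_binding_scale) ||
        is.null(g$blood_level_multiplier))
      stop("each group needs 'name', 'specific_binding_scale', 'blood_level_multiplier'")
    if (!is.finite(g$specific_binding_scale) || g$specific_binding_scale < 0)
      stop("'specific_binding_scale' must be >= 0")
    if (!is.finite(g$blood_level_multiplier) || g$blood_level_multiplier <= 0)
      stop("'blood_level_multiplier' must be > 0")
  }
  if (anyDuplicated(vapply(groups, `[[`, "", "name")))
    stop("group names must be unique")
  num <- c(dose_mean_Bq = dose_mean_Bq, dose_cv = dose_cv,
           clearance_cv = clearance_cv, psf_sigma_mm = psf_sigma_mm,
           noise_scale = noise_scale, blood_assay_cv = blood_assay_cv,
           base_blood_frac_per_g = base_blood_frac_per_g,
           uptake_coupling = uptake_coupling)
  if (any(!is.finite(num)) || any(num < 0))
    stop("all numeric cohort parameters must be finite and >= 0")
  if (dose_mean_Bq <= 0 || base_blood_frac_per_g <= 0)
    stop("'dose_mean_Bq' and 'base_blood_frac_per_g' must be > 0")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer")
  structure(
    list(n_per_group = n_per_group, groups = groups,
         dose_mean_Bq = dose_mean_Bq, dose_cv = dose_cv,
         clearance_cv = clearance_cv, psf_sigma_mm = psf_sigma_mm,
         noise_scale = noise_scale, blood_assay_cv = blood_assay_cv,
         base_blood_frac_per_g = base_blood_frac_per_g,
         uptake_coupling = uptake_coupling, seed = seed),
    class = "cohort_spec")
}

# run code under a given seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a digital-mouse PET cohort
#'
#' For each subject: draws an injected dose `ID_i` (lognormal with the
#' specified mean/CV) and a true blood concentration
#' `B_i = base * ID_i * lognormal(clearance_cv) * blood_level_multiplier`
#' (Bq/g); builds the noiseless tissue map
#' `blood_volume_fraction * B_i + binding_scale * expression * ID_i * u`
#' per region (Bq/g), converts to Bq/mL with the blood-density factor
#' 1.057 g/mL, applies the Gaussian PSF, and adds zero-mean Gaussian noise
#' with SD `noise_scale * sqrt(max(signal, 1))`. The simulated ex vivo
#' measurement is `B_i * (1 + Normal(0, blood_assay_cv))`, clipped at zero
#' with a warning if negative. The same spec (including seed) always yields
#' bit-identical output.
#'
#' @param atlas a [build_default_atlas()] object.
#' @param spec a [cohort_spec()].
#' @return List with `scans` (list of [subject_scan()]) and `truth`:
#'   a data frame of per-subject latent quantities (`true_blood_Bq_per_g`,
#'   dose, group) plus `region_uptake`, the subjects x regions matrix of
#'   true specific uptake in Bq/g (all-zero rows for knockouts).
#' @export
simulate_cohort <- function(atlas, spec) {
  if (!inherits(atlas, "phantom_atlas")) stop("'atlas' must be a phantom_atlas")
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec")
  lab <- atlas$labels$values
  d <- dim(lab)
  spacing <- atlas$labels$voxel_size_mm
  tissue <- atlas$regions
  lab1 <- lab + 1L  # lookup index into tissue rows (label codes are 0-based)
  with_local_seed(spec$seed, {
    scans <- list()
    rows <- list()
    uptake <- list()
    for (g in spec$groups) {
      for (i in seq_len(spec$n_per_group)) {
        sid <- sprintf("%s_%02d", g$name, i)
        dose <- spec$dose_mean_Bq * rlnorm_cv(1L, spec$dose_cv)
        B <- spec$base_blood_frac_per_g * dose *
          rlnorm_cv(1L, spec$clearance_cv) * g$blood_level_multiplier
        exvivo <- B * (1 + stats::rnorm(1L, 0, spec$blood_assay_cv))
        if (exvivo < 0) {
          warning(sprintf("subject %s: negative simulated blood measurement clipped to 0", sid))
          exvivo <- 0
        }
        specific <- g$specific_binding_scale * tissue$trem2_expression *
          dose * spec$uptake_coupling            # Bq/g per region
        per_region <- tissue$blood_volume_fraction * B + specific
        vals <- array(per_region[lab1] * BLOOD_DENSITY_G_PER_ML, d)  # Bq/mL
        vol <- volume(vals, spacing, "Bq/mL")
        if (spec$psf_sigma_mm > 0) vol <- gaussian_smooth(vol, spec$psf_sigma_mm)
        if (spec$noise_scale > 0) {
          sd_map <- spec$noise_scale * sqrt(pmax(vol$values, 1))
          vol$values <- vol$values +
            array(stats::rnorm(length(sd_map)), d) * sd_map
        }
        scans[[sid]] <- subject_scan(sid, g$name, dose, vol,
                                     exvivo_blood_Bq_per_g = exvivo)
        rows[[sid]] <- data.frame(
          subject_id = sid, group = g$name, injected_dose_Bq = dose,
          true_blood_Bq_per_g = B, exvivo_blood_Bq_per_g = exvivo,
          stringsAsFactors = FALSE)
        uptake[[sid]] <- specific
      }
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    region_uptake <- do.call(rbind, uptake)
    colnames(region_uptake) <- tissue$region
    list(scans = unname(scans),
         truth = list(subjects = truth, region_uptake = region_uptake))
  })
}

#' Write a simulated cohort to disk
#'
#' Writes one NIfTI-1 volume per subject (`<subject_id>.nii.gz`, Bq/mL,
#' 32-bit float), the cohort manifest CSV, the atlas label map as integer
#' NIfTI, the region dictionary as JSON, and the latent ground truth as
#' JSON.
#'
#' @inheritParams simulate_cohort
#' @param dir output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
simulate_cohort_to_dir <- function(atlas, spec, dir) {
  sim <- simulate_cohort(atlas, spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(sim$scans, function(s) {
    p <- file.path(dir, paste0(s$subject_id, ".nii.gz"))
    write_volume(s$vol, p)
    p
  }, character(1))
  man <- data.frame(
    subject_id = vapply(sim$scans, `[[`, "", "subject_id"),
    group = vapply(sim$scans, `[[`, "", "group"),
    injected_dose_Bq = vapply(sim$scans, `[[`, 0, "injected_dose_Bq"),
    exvivo_blood_Bq_per_g = vapply(sim$scans, `[[`, 0, "exvivo_blood_Bq_per_g"),
    volume_path = basename(paths), stringsAsFactors = FALSE)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  write_volume(atlas$labels, file.path(dir, "atlas_labels.nii.gz"))
  jsonlite::write_json(atlas$regions, file.path(dir, "atlas_regions.json"),
                       dataframe = "rows", digits = NA)
  jsonlite::write_json(
    list(subjects = sim$truth$subjects,
         region_uptake = as.data.frame(sim$truth$region_uptake)),
    file.path(dir, "ground_truth.json"), dataframe = "rows", digits = NA)
  invisible(man_path)
}
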