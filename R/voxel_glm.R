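# ------------------------------------------------------------------------
# Per-voxel statistics across subjects (SPM-style mass-univariate GLM) and
# cluster-extent thresholding. Everything is computed vectorized across the
# masked voxels via closed-form OLS / pooled-t sums.
# ------------------------------------------------------------------------

# t assigned to voxels whose model fit is exact (zero residual, nonzero
# slope); keeps t-maps finite in noiseless ideal-limit data.
T_PERFECT_FIT <- 1e10

new_tmap <- function(t_array, spacing, dof, contrast, mask,
                     zero_variance = integer(), perfect_fit = integer()) {
  structure(
    list(t = volume(t_array, spacing, "t_value"), dof = as.integer(dof),
         contrast = contrast, mask = mask,
         zero_variance = as.integer(zero_variance),
         perfect_fit = as.integer(perfect_fit)),
    class = "t_map")
}

#' @export
print.t_map <- function(x, ...) {
  inm <- which(x$mask$values == 1L)
  tv <- x$t$values[inm]
  cat(sprintf("<t_map> '%s', dof = %d, %d masked voxels, t range [%.3g, %.3g]\n",
              x$contrast, x$dof, length(inm), min(tv), max(tv)))
  if (length(x$zero_variance))
    cat(sprintf("  %d zero-variance voxel(s) flagged (t = 0)\n", length(x$zero_variance)))
  if (length(x$perfect_fit))
    cat(sprintf("  %d perfect-fit voxel(s) clamped to +/-%g\n",
                length(x$perfect_fit), T_PERFECT_FIT))
  invisible(x)
}

as_vol_list <- function(scans) {
  lapply(scans, function(s) if (is_volume(s)) s else s$vol)
}

#' Voxelwise simple-regression t-map against a covariate
#'
#' At every voxel inside the mask, fits ordinary least squares of the voxel
#' value on the per-subject covariate (with intercept) and returns
#' `t = slope / SE(slope)` with `n - 2` degrees of freedom. Positive t
#' means uptake increases with the covariate. This is the map used to find
#' voxels that track ex vivo blood radioactivity. Voxels with zero variance
#' across subjects are flagged and set to t = 0; voxels with an exact fit
#' (zero residual, nonzero slope — possible in noiseless simulations) are
#' clamped to a large finite value and flagged.
#'
#' @param scans list of [subject_scan()] (or [volume()]s) on a common grid.
#' @param covariate numeric, one value per scan, nonzero variance.
#' @param mask `"label"` [volume()] analysis mask.
#' @param presmooth_sigma_mm optional Gaussian pre-smoothing in mm
#'   (default 0 = none).
#' @return A `t_map` object.
#' @export
regression_tmap <- function(scans, covariate, mask, presmooth_sigma_mm = 0) {
  vols <- as_vol_list(scans)
  n <- length(vols)
  if (n < 3L) stop("regression requires at least 3 subjects")
  if (length(covariate) != n) stop("one covariate value per scan required")
  if (any(!is.finite(covariate))) stop("covariate must be finite")
  if (stats::var(covariate) <= 0) stop("covariate has zero variance")
  stopifnot_volume(mask, units = "label", what = "mask")
  if (presmooth_sigma_mm > 0)
    vols <- lapply(vols, gaussian_smooth, sigma_mm = presmooth_sigma_mm)
  mask_idx <- which(mask$values == 1L)
  Y <- scan_matrix(vols, mask_idx)
  xc <- covariate - mean(covariate)
  sxx <- sum(xc^2)
  ybar <- colMeans(Y)
  slope <- colSums(xc * Y) / sxx
  ss_tot <- colSums(Y^2) - n * ybar^2
  ss_res <- pmax(ss_tot - slope^2 * sxx, 0)
  dof <- n - 2L
  sigma2 <- ss_res / dof
  se <- sqrt(sigma2 / sxx)
  tval <- ifelse(se > 0, slope / se, 0)
  zero_var <- mask_idx[ss_tot <= 0]
  perfect <- (ss_tot > 0) & (ss_res <= 1e-12 * ss_tot) & (slope != 0)
  tval[perfect] <- sign(slope[perfect]) * T_PERFECT_FIT
  big <- abs(tval) > T_PERFECT_FIT
  tval[big] <- sign(tval[big]) * T_PERFECT_FIT
  t_arr <- array(0, dim(mask$values))
  t_arr[mask_idx] <- tval
  new_tmap(t_arr, mask$voxel_size_mm, dof, "positive slope vs covariate",
           mask, zero_variance = zero_var, perfect_fit = mask_idx[perfect])
}

#' Voxelwise two-sample (pooled-variance) t-map
#'
#' Unpaired pooled-variance t at every masked voxel, positive where
#' `mean(A) > mean(B)`, with `nA + nB - 2` degrees of freedom. Voxels with
#' zero pooled variance are flagged and set to t = 0 so the map geometry
#' stays stable.
#'
#' @param scansA,scansB lists of [subject_scan()] (or [volume()]s), at
#'   least 2 subjects each, common grid.
#' @param mask `"label"` [volume()] analysis mask.
#' @param contrast descriptor string stored in the result.
#' @return A `t_map` object.
#' @export
two_sample_tmap <- function(scansA, scansB, mask, contrast = "groupA > groupB") {
  volsA <- as_vol_list(scansA)
  volsB <- as_vol_list(scansB)
  nA <- length(volsA); nB <- length(volsB)
  if (nA < 2L || nB < 2L) stop("each group needs at least 2 subjects")
  stopifnot_volume(mask, units = "label", what = "mask")
  mask_idx <- which(mask$values == 1L)
  A <- scan_matrix(volsA, mask_idx)
  B <- scan_matrix(volsB, mask_idx)
  mA <- colMeans(A); mB <- colMeans(B)
  ssA <- colSums(A^2) - nA * mA^2
  ssB <- colSums(B^2) - nB * mB^2
  dof <- nA + nB - 2L
  sp2 <- pmax(ssA + ssB, 0) / dof
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tval <- ifelse(se > 0, (mA - mB) / se, 0)
  tval <- pmin(pmax(tval, -T_PERFECT_FIT), T_PERFECT_FIT)
  zero_var <- mask_idx[se <= 0]
  t_arr <- array(0, dim(mask$values))
  t_arr[mask_idx] <- tval
  new_tmap(t_arr, mask$voxel_size_mm, dof, contrast, mask,
           zero_variance = zero_var)
}

#' Critical t for an uncorrected voxelwise p threshold
#'
#' @param p_uncorrected tail probability in (0, 1).
#' @param dof degrees of freedom (>= 1).
#' @param sided `"one"` (upper-tail) or `"two"`.
#' @return The critical t value.
#' @export
t_threshold <- function(p_uncorrected, dof, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (!is.finite(p_uncorrected) || p_uncorrected <= 0 || p_uncorrected >= 1)
    stop("'p_uncorrected' must be in (0, 1)")
  if (!is.finite(dof) || dof < 1) stop("'dof' must be >= 1")
  p <- if (sided == "one") p_uncorrected else p_uncorrected / 2
  stats::qt(1 - p, df = dof)
}

# neighbor offsets (full set) for a given connectivity
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("'connectivity' must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1)
  off[keep, , drop = FALSE]
}

# lexicographically positive half of the offsets (each undirected neighbor
# pair visited once)
half_offsets <- function(connectivity) {
  off <- connectivity_offsets(connectivity)
  pos <- off[, 3] > 0 |
    (off[, 3] == 0 & (off[, 2] > 0 | (off[, 2] == 0 & off[, 1] > 0)))
  off[pos, , drop = FALSE]
}

# order of rows of an Nx3 index matrix: lexicographic by (i, j, k)
lex_order <- function(ind) order(ind[, 1], ind[, 2], ind[, 3])

#' Extract suprathreshold clusters from a t-map
#'
#' Connected components of the suprathreshold set `{t > t_crit}` (inside
#' the analysis mask) under 6-, 18- or 26-neighborhood connectivity.
#' Components are retained when strictly larger than `min_size` voxels
#' (the "more than k voxels" extent-threshold convention) and returned
#' sorted by peak t (descending), ties broken by size then by
#' lexicographic peak index.
#'
#' @param tmap a `t_map`.
#' @param t_crit cluster-forming threshold (see [t_threshold()]).
#' @param min_size extent threshold; clusters must have `size > min_size`.
#' @param connectivity 6, 18 or 26 (default 18, the SPM convention).
#' @return List of `cluster_voi` objects, each with `voxels` (Nx3 1-based
#'   index matrix), `size_voxels`, `peak_t`, `peak_index`.
#' @export
extract_clusters <- function(tmap, t_crit, min_size = 50L, connectivity = 18L) {
  if (!inherits(tmap, "t_map")) stop("'tmap' must be a t_map")
  if (!is.finite(t_crit)) stop("'t_crit' must be finite")
  if (min_size < 0) stop("'min_size' must be >= 0")
  d <- dim(tmap$t$values)
  supra <- which(tmap$t$values > t_crit & tmap$mask$values == 1L)
  if (!length(supra)) return(list())
  ind <- arrayInd(supra, d)
  m <- length(supra)
  pos <- array(0L, d)
  pos[supra] <- seq_len(m)
  offs <- half_offsets(as.integer(connectivity))
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    ok <- ind[, 1] + o[1] >= 1L & ind[, 1] + o[1] <= d[1] &
          ind[, 2] + o[2] >= 1L & ind[, 2] + o[2] <= d[2] &
          ind[, 3] + o[3] >= 1L & ind[, 3] + o[3] <= d[3]
    if (!any(ok)) next
    nb_lin <- supra[ok] + o[1] + o[2] * d[1] + o[3] * d[1] * d[2]
    nb_rank <- pos[nb_lin]
    hit <- nb_rank > 0L
    if (any(hit))
      edges[[r]] <- cbind(which(ok)[hit], nb_rank[hit])
  }
  edges <- do.call(rbind, edges)
  membership <- if (is.null(edges)) {
    seq_len(m)
  } else {
    g <- igraph::make_graph(t(edges), n = m, directed = FALSE)
    as.integer(igraph::components(g)$membership)
  }
  sizes <- tabulate(membership)
  keep <- which(sizes > min_size)
  if (!length(keep)) return(list())
  tvals <- tmap$t$values[supra]
  clusters <- lapply(keep, function(comp) {
    sel <- membership == comp
    vox <- ind[sel, , drop = FALSE]
    tv <- tvals[sel]
    peak <- max(tv)
    cand <- vox[tv == peak, , drop = FALSE]
    peak_idx <- cand[lex_order(cand)[1L], ]
    structure(
      list(voxels = vox, size_voxels = nrow(vox), peak_t = peak,
           peak_index = as.integer(peak_idx)),
      class = "cluster_voi")
  })
  ord <- order(
    -vapply(clusters, `[[`, 0, "peak_t"),
    -vapply(clusters, `[[`, 0L, "size_voxels"),
    vapply(clusters, function(cl) cl$peak_index[1], 0L),
    vapply(clusters, function(cl) cl$peak_index[2], 0L),
    vapply(clusters, function(cl) cl$peak_index[3], 0L))
  clusters[ord]
}

#' @export
print.cluster_voi <- function(x, ...) {
  cat(sprintf("<cluster_voi> %d voxels, peak t = %.3g at (%s)\n",
              x$size_voxels, x$peak_t, paste(x$peak_index, collapse = ", ")))
  invisible(x)
}
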