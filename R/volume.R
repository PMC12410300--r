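#' @keywords internal
"_PACKAGE"

# Recognised physical unit tags. Every operation propagates (and checks) the
# tag; implicit unit coercion is an error by design.
VOLUME_UNITS <- c("Bq/mL", "Bq/g", "ratio", "%ID/g", "t_value", "label")

#' 3-D scalar volume with voxel spacing and physical units
#'
#' Minimal in-memory container for co-registered preclinical PET data: a
#' numeric 3-D array, isotropic or anisotropic voxel spacing in millimetres,
#' and an explicit unit tag. Activity images are stored as `"Bq/mL"`;
#' normalized images as `"ratio"` or `"%ID/g"`; statistic maps as
#' `"t_value"`; masks and atlases as `"label"`.
#'
#' Voxel indices throughout the package are 1-based (R convention). World
#' coordinates follow NIfTI: voxel `(i, j, k)` sits at
#' `((i-1)*dx, (j-1)*dy, (k-1)*dz)` millimetres.
#'
#' @param values numeric 3-D array.
#' @param voxel_size_mm positive spacing, length 1 (isotropic) or 3.
#' @param units one of `"Bq/mL"`, `"Bq/g"`, `"ratio"`, `"%ID/g"`,
#'   `"t_value"`, `"label"`.
#' @return An object of class `pet_volume`.
#' @export
volume <- function(values, voxel_size_mm, units) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be positive, length 1 or 3")
  units <- match.arg(units, VOLUME_UNITS)
  structure(
    list(values = values, voxel_size_mm = as.numeric(voxel_size_mm),
         units = units),
    class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume> %s grid, %s mm spacing, units '%s'\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x"), x$units))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  range [%g, %g], mean %g\n", min(v), max(v), mean(v)))
  invisible(x)
}

#' @export
dim.pet_volume <- function(x) dim(x$values)

is_volume <- function(x) inherits(x, "pet_volume")

stopifnot_volume <- function(x, units = NULL, what = "volume") {
  if (!is_volume(x)) stop(sprintf("'%s' must be a pet_volume", what))
  if (!is.null(units) && x$units != units)
    stop(sprintf("'%s' has units '%s'; expected '%s'", what, x$units, units))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm, tolerance = 1e-8))
}

#' Write a volume to NIfTI-1
#'
#' Activity/ratio/t volumes are written as 32-bit float, label volumes as
#' 32-bit integer. The affine is diagonal RAS+ built from the voxel spacing.
#'
#' @param vol a [volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot_volume(vol)
  dt <- if (vol$units == "label") "int32" else "float"
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' NIfTI carries no activity-unit metadata, so the caller supplies the unit
#' tag (default `"Bq/mL"`, the convention for reconstructed PET).
#'
#' @param path NIfTI file.
#' @param units unit tag to attach (see [volume()]).
#' @return A [volume()].
#' @export
read_volume <- function(path, units = "Bq/mL") {
  if (!file.exists(path)) stop(sprintf("volume file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3-D volume in %s", path))
  vals <- array(as.vector(img), d)  # plain array, NIfTI attributes dropped
  sp <- RNifti::pixdim(img)[seq_len(3L)]
  volume(vals, sp, units)
}

#' Separable 3-D Gaussian smoothing
#'
#' Applies a truncated (4 sigma) Gaussian kernel along each axis with
#' edge renormalization: near the boundary the kernel weights are rescaled
#' to sum to one, so flat fields are preserved and interior signal is
#' redistributed, not created or destroyed. Used as the point-spread-function
#' model of the phantom simulator and as optional pre-smoothing before the
#' voxelwise GLM.
#'
#' @param vol a [volume()].
#' @param sigma_mm Gaussian standard deviation in millimetres (0 = identity).
#' @return Smoothed [volume()], same units.
#' @export
gaussian_smooth <- function(vol, sigma_mm) {
  stopifnot_volume(vol)
  if (!is.finite(sigma_mm) || sigma_mm < 0) stop("'sigma_mm' must be >= 0")
  if (sigma_mm == 0) return(vol)
  v <- vol$values
  d <- dim(v)
  for (ax in 1:3) {
    sig <- sigma_mm / vol$voxel_size_mm[ax]
    if (sig < 1e-8) next
    K <- gauss_band_matrix(d[ax], sig)
    v <- apply_along_axis(v, ax, K)
  }
  volume(v, vol$voxel_size_mm, vol$units)
}

# n x n row-normalized truncated Gaussian convolution matrix (sigma in voxels)
gauss_band_matrix <- function(n, sigma) {
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) {
    d <- abs(i - j)
    ifelse(d <= ceiling(4 * sigma), exp(-d^2 / (2 * sigma^2)), 0)
  })
  K / rowSums(K)
}

# multiply K (n_ax x n_ax) along axis `ax` of 3-D array v
apply_along_axis <- function(v, ax, K) {
  d <- dim(v)
  if (ax == 1L) {
    out <- K %*% matrix(v, d[1], d[2] * d[3])
    array(out, d)
  } else if (ax == 2L) {
    vp <- aperm(v, c(2, 1, 3))
    out <- K %*% matrix(vp, d[2], d[1] * d[3])
    aperm(array(out, c(d[2], d[1], d[3])), c(2, 1, 3))
  } else {
    out <- matrix(v, d[1] * d[2], d[3]) %*% t(K)
    array(out, d)
  }
}

# world (mm) coordinates of voxel centers along each axis
axis_coords_mm <- function(dim3, spacing) {
  lapply(1:3, function(k) (seq_len(dim3[k]) - 1) * spacing[k])
}
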