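#' Volumetric image container
#'
#' A minimal 3D scalar image: an intensity array plus voxel spacing, a
#' free-text space label (e.g. `"MNI152"`) and a 4x4 affine mapping grid
#' indices (0-based, NIfTI storage order) to world coordinates.  All
#' maps produced downstream inherit the input volume's affine so that
#' overlays align.
#'
#' @param data 3D numeric array of finite intensities.
#' @param voxel_size_mm positive numeric triple.
#' @param space free-text space label.
#' @param affine 4x4 numeric matrix; defaults to a scaling by
#'   `voxel_size_mm`.
#' @return an object of class `volume3d`.
#' @export
new_volume <- function(data, voxel_size_mm = c(1, 1, 1), space = "unknown",
                       affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!all(is.finite(data))) stop("intensities must all be finite")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be three strictly positive values")
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be 4x4")
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 space = space, affine = affine),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat("<volume3d> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$voxel_size_mm, 4), collapse = "/"),
      " mm, space ", x$space, "\n", sep = "")
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

as_volume_array <- function(volume) {
  if (inherits(volume, "volume3d")) return(volume$data)
  if (is.array(volume) && length(dim(volume)) == 3L) return(volume)
  stop("expected a volume3d or a 3D array")
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a readable `.nii` or `.nii.gz` file containing a
#'   3D image; 4D time series are rejected.
#' @return a [new_volume()] with shape, voxel size and affine taken from
#'   the NIfTI header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D image, got %dD: %s", length(d), path))
  pix <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  new_volume(array(as.numeric(img), dim = d),
             voxel_size_mm = abs(pix[seq_len(3)]),
             space = "unknown",
             affine = unclass(RNifti::xform(img)))
}

#' Write a volume as NIfTI-1
#'
#' @param volume a `volume3d`.
#' @param path output path (`.nii` or `.nii.gz`); the parent directory
#'   must exist.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume3d"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(volume$data)
  # pixdim must agree with the affine scale for the xform to round-trip
  RNifti::pixdim(img) <- sqrt(colSums(volume$affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume by a scale factor
#'
#' Each output axis length is `round(input_length * factor)` (so a
#' 182 x 218 x 182 volume at factor 0.5 becomes 91 x 109 x 91) and the
#' voxel size is scaled by `1/factor`.  Intensities are interpolated
#' with a separable B-spline of the given order (0-5, default cubic)
#' under an endpoint-aligned coordinate mapping.
#'
#' @param volume a `volume3d`.
#' @param factor strictly positive scale factor.
#' @param spline_order integer in 0..5.
#' @return the resampled `volume3d`.
#' @export
resample_volume <- function(volume, factor, spline_order = 3L) {
  stopifnot(inherits(volume, "volume3d"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("`factor` must be a single positive number")
  if (!spline_order %in% 0:5) stop("`spline_order` must be in 0..5")
  din <- dim(volume$data)
  dout <- pmax(1L, as.integer(floor(din * factor + 0.5)))
  arr <- .resample3d(as.numeric(volume$data), as.integer(din),
                     as.integer(dout), as.integer(spline_order))
  # index scaling of the endpoint-aligned map, folded into the affine
  s <- ifelse(dout > 1L, (din - 1) / (dout - 1), 1)
  affine <- volume$affine %*% diag(c(s, 1))
  new_volume(array(arr, dim = dout),
             voxel_size_mm = volume$voxel_size_mm / factor,
             space = volume$space, affine = affine)
}

#' Body mass index from weight and height
#'
#' BMI = weight (kg) / height (m)^2.
#'
#' @param weight_kg,height_m strictly positive numerics (vectorized).
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0))
    stop("`weight_kg` must be strictly positive")
  if (any(!is.finite(height_m)) || any(height_m <= 0))
    stop("`height_m` must be strictly positive")
  weight_kg / height_m^2
}

#' Standardize volume intensities in place (optional preprocessing)
#'
#' Off by default throughout the package: intensities are used as
#' stored.  Provided for cohorts whose acquisition scales differ.
#'
#' @param volume a `volume3d`.
#' @return the volume with zero-mean, unit-variance intensities.
#' @export
standardize_volume <- function(volume) {
  stopifnot(inherits(volume, "volume3d"))
  x <- volume$data
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("constant volume cannot be standardized")
  volume$data <- (x - mean(x)) / s
  volume
}
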