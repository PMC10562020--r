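#' Construct a volume
#'
#' A volume is a 3-D intensity grid in canonical anatomical order together
#' with its voxel spacing in mm. The canonical axis order is
#' (cranio-caudal, anterior-posterior, left-right): index 1 increases towards
#' the head (S+), index 2 towards the front (A+), index 3 towards the
#' patient's right (R+). Sagittal slices are `data[, , k]`; axial slices are
#' `data[i, , ]`. Coordinates are 0-based and voxel-centred: voxel index `i`
#' (0-based) sits at `i * spacing` mm along its axis.
#'
#' @param data 3-D numeric array, finite values.
#' @param spacing_mm numeric length-3, strictly positive, mm per voxel along
#'   each canonical axis.
#' @param axes character length-3 axis direction labels; fixed to
#'   `c("S", "A", "R")` in canonical volumes.
#' @return An object of class `cc_volume`.
#' @export
volume <- function(data, spacing_mm, axes = c("S", "A", "R")) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array")
  if (!all(is.finite(data))) stop("`data` must be finite")
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be 3 strictly positive numbers")
  }
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 axes = axes),
            class = "cc_volume")
}

#' Construct a binary mask volume
#'
#' Same geometry contract as [volume()]; values must be 0/1.
#'
#' @inheritParams volume
#' @return An object of class `cc_mask` (also `cc_volume`).
#' @export
mask_volume <- function(data, spacing_mm, axes = c("S", "A", "R")) {
  if (!all(data %in% c(0, 1))) stop("mask values must be 0 or 1")
  v <- volume(data, spacing_mm, axes)
  class(v) <- c("cc_mask", class(v))
  v
}

#' @export
print.cc_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, axes %s\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = " x "),
              paste(x$axes, collapse = "")))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol)
}

#' Read a NIfTI volume in canonical orientation
#'
#' Reads a NIfTI-1 file (`.nii` / `.nii.gz`), reorients the voxel data to the
#' canonical (cranio-caudal, anterior-posterior, left-right) order using the
#' stored qform/sform (sform preferred when both are valid, as RNifti does),
#' and extracts the voxel spacing from the reoriented transform.
#'
#' @param path file path.
#' @param mask logical; read as a binary mask (values are binarized at 0.5).
#' @return A [volume()] (or [mask_volume()] when `mask = TRUE`).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("cannot read volume: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("ill-formed NIfTI file: ", path))
  xf <- RNifti::xform(img)
  if (!is.null(attr(xf, "code")) && attr(xf, "code") > 0) {
    RNifti::orientation(img) <- "RAS"
    xf <- RNifti::xform(img)
    sp_xyz <- sqrt(colSums(xf[1:3, 1:3]^2))
  } else {
    sp_xyz <- RNifti::pixdim(img)[1:3]
  }
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3-D volume: ", path)
  # RAS (x = R+, y = A+, z = S+) -> canonical (S+, A+, R+)
  dat <- aperm(arr, c(3, 2, 1))
  sp <- as.numeric(sp_xyz[c(3, 2, 1)])
  if (mask) mask_volume((dat > 0.5) * 1, sp) else volume(dat, sp)
}

#' Write a volume as NIfTI
#'
#' Writes the canonical array back in RAS+ axis order with a diagonal
#' spacing affine (both qform and sform set).
#'
#' @param v a [volume()] or [mask_volume()].
#' @param path output path (`.nii` or `.nii.gz`); parent must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "cc_volume"))
  if (!dir.exists(dirname(path))) stop("no such directory: ", dirname(path))
  arr <- aperm(v$data, c(3, 2, 1))   # back to (R, A, S) = x, y, z
  img <- RNifti::asNifti(arr)
  sp_xyz <- v$spacing_mm[c(3, 2, 1)]
  RNifti::pixdim(img) <- sp_xyz
  aff <- structure(diag(c(sp_xyz, 1)), code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample the axial plane to a target in-plane resolution
#'
#' The axial plane of a sagittal acquisition is spanned by the
#' anterior-posterior and left-right axes; axial slices are indexed along the
#' cranio-caudal axis, whose sampling is left untouched. The output grid size
#' along each resampled axis is `round(extent / target_mm)` with the first
#' voxel centre aligned to the input's first voxel centre. Intensities are
#' interpolated bilinearly; masks use nearest-neighbour and stay binary.
#'
#' @param v a [volume()] or [mask_volume()].
#' @param target_mm target axial in-plane spacing, mm (default 0.5).
#' @param interpolation `"linear"` or `"nearest"`; defaults to nearest for
#'   masks and linear otherwise.
#' @return A resampled volume of the same class.
#' @export
resample_axial <- function(v, target_mm = 0.5,
                           interpolation = if (inherits(v, "cc_mask"))
                             "nearest" else "linear") {
  stopifnot(inherits(v, "cc_volume"))
  if (!is.finite(target_mm) || target_mm <= 0) {
    stop("`target_mm` must be strictly positive")
  }
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  d <- dim(v$data)
  sp <- v$spacing_mm
  m2 <- max(1L, as.integer(round(d[2] * sp[2] / target_mm)))
  m3 <- max(1L, as.integer(round(d[3] * sp[3] / target_mm)))
  out <- array(0, c(d[1], m2, m3))
  nearest <- interpolation == "nearest"
  for (i in seq_len(d[1])) {
    out[i, , ] <- cc_resize(v$data[i, , , drop = TRUE], m2, m3,
                            target_mm / sp[2], target_mm / sp[3],
                            0, 0, nearest, TRUE)
  }
  sp_out <- c(sp[1], target_mm, target_mm)
  if (inherits(v, "cc_mask")) mask_volume((out > 0.5) * 1, sp_out)
  else volume(out, sp_out)
}
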