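# Axial cropping around the centerline with exact reinsertion bookkeeping,
# percentile intensity normalization, sagittal reconstruction of axial
# outputs, and assembly of the sagittal network's two-channel inputs.

#' Crop 64x64 axial patches around the centerline
#'
#' For every valid centerline slice, extracts a square patch of physical side
#' `crop_mm` (64x64 voxels at the working 0.5 mm resolution), centred so the
#' centerline voxel maps to patch index (32, 32) (0-based). Out-of-bounds
#' regions are zero-padded; a crop record per slice enables voxel-exact
#' reinsertion.
#'
#' @param v a resampled [volume()] or [mask_volume()] (equal axial in-plane
#'   spacings).
#' @param cl a [centerline()] for `v`.
#' @param crop_mm physical crop side, mm (default 32).
#' @return List of `axial_patch` objects (`image` 2-D grid, `record`); the
#'   records alone are available via `lapply(x, \(p) p$record)`.
#' @export
crop_axial <- function(v, cl, crop_mm = 32) {
  stopifnot(inherits(v, "cc_volume"), inherits(cl, "cc_centerline"))
  sp <- v$spacing_mm
  if (abs(sp[2] - sp[3]) > 1e-6) {
    stop("crop_axial expects equal axial in-plane spacings")
  }
  d <- dim(v$data)
  if (nrow(cl$centers_mm) != d[1]) {
    stop("centerline length does not match the number of axial slices")
  }
  if (!any(cl$valid)) stop("no valid centerline slice to crop around")
  n_px <- as.integer(round(crop_mm / sp[2]))
  half <- n_px %/% 2L
  out <- list()
  for (i in which(cl$valid)) {
    ctr <- as.integer(round(cl$centers_mm[i, ] / sp[2:3]))  # 0-based voxel
    origin <- ctr - half                                    # 0-based
    patch <- matrix(0, n_px, n_px)
    r0 <- max(origin[1], 0L); r1 <- min(origin[1] + n_px - 1L, d[2] - 1L)
    c0 <- max(origin[2], 0L); c1 <- min(origin[2] + n_px - 1L, d[3] - 1L)
    if (r0 <= r1 && c0 <= c1) {
      patch[(r0 - origin[1] + 1L):(r1 - origin[1] + 1L),
            (c0 - origin[2] + 1L):(c1 - origin[2] + 1L)] <-
        v$data[i, (r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L)]
    }
    rec <- list(slice_index = i - 1L,          # 0-based axial slice
                origin_voxel = origin,         # 0-based (row, col)
                extent_voxel = c(n_px, n_px),
                origin_mm = origin * sp[2:3])
    out[[length(out) + 1L]] <- structure(list(image = patch, record = rec),
                                         class = "axial_patch")
  }
  out
}

#' Percentile intensity normalization
#'
#' Clips a 2-D grid to its own 2nd/98th intensity percentiles
#' (linear-interpolation percentile definition) and maps that range affinely
#' onto `[0, 1]`. A constant grid maps to all zeros with a warning.
#'
#' @param g finite 2-D numeric grid.
#' @param pclip percentile pair, default `c(2, 98)`.
#' @return Grid of the same shape with values in `[0, 1]`.
#' @export
normalize_intensity <- function(g, pclip = c(2, 98)) {
  if (!all(is.finite(g))) stop("grid must be finite")
  q <- quantile(g, pclip / 100, names = FALSE, type = 7)
  if (q[2] - q[1] < .Machine$double.eps) {
    warning("constant grid: normalized to all zeros")
    return(array(0, dim(g)))
  }
  pmin(pmax((g - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Reinsert axial patches into scan space
#'
#' The exact inverse of [crop_axial()]: each 64x64 grid (a patch, an axial
#' network probability map, or a mask crop) is written back at its recorded
#' origin in the resampled scan grid; voxels outside every crop are zero.
#' The result is a full 3-D stack, from which sagittal slices are
#' `result$data[, , k]`.
#'
#' @param grids list of 2-D grids, one per record.
#' @param records list of crop records (from [crop_axial()]).
#' @param geom scan geometry: list with `dim` (3 integers) and `spacing_mm`.
#' @return A [volume()] in resampled scan space.
#' @export
reconstruct_sagittal <- function(grids, records, geom) {
  if (length(grids) != length(records)) {
    stop("patch/record count mismatch: ", length(grids), " vs ",
         length(records))
  }
  out <- array(0, geom$dim)
  d <- geom$dim
  for (t in seq_along(grids)) {
    rec <- records[[t]]
    g <- grids[[t]]
    if (!all(dim(g) == rec$extent_voxel)) stop("grid does not match record")
    i <- rec$slice_index + 1L
    og <- rec$origin_voxel
    r0 <- max(og[1], 0L); r1 <- min(og[1] + rec$extent_voxel[1] - 1L, d[2] - 1L)
    c0 <- max(og[2], 0L); c1 <- min(og[2] + rec$extent_voxel[2] - 1L, d[3] - 1L)
    if (r0 <= r1 && c0 <= c1) {
      out[i, (r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L)] <-
        g[(r0 - og[1] + 1L):(r1 - og[1] + 1L),
          (c0 - og[2] + 1L):(c1 - og[2] + 1L)]
    }
  }
  volume(out, geom$spacing_mm)
}

# Aspect-preserving square-canvas mapping. Content is scaled by a single
# factor, centred, zero-padded; the record allows an exact inverse mapping.
canvas_record <- function(h, w, size) {
  scale <- min(size / h, size / w)
  ch <- round(h * scale); cw <- round(w * scale)
  list(h = h, w = w, size = size, scale = scale,
       or = (size - ch) %/% 2, oc = (size - cw) %/% 2,
       ch = ch, cw = cw)
}

resize_to_canvas <- function(g, rec, nearest = FALSE) {
  # out(i,j) = g((i - or)/scale, (j - oc)/scale)
  cc_resize(g, rec$size, rec$size, 1 / rec$scale, 1 / rec$scale,
            -rec$or / rec$scale, -rec$oc / rec$scale, nearest)
}

resize_from_canvas <- function(g, rec, nearest = FALSE) {
  cc_resize(g, rec$h, rec$w, rec$scale, rec$scale,
            rec$or, rec$oc, nearest)
}

#' Build the sagittal network's two-channel inputs
#'
#' For every original sagittal slice: channel 1 is the slice's intensities
#' masked to the crop corridor (zero elsewhere), percentile-normalized;
#' channel 2 is the sagittally rearranged axial segmentation (continuous
#' values kept in `[0, 1]`, no percentile normalization). Both channels are
#' mapped onto a `size x size` canvas with one aspect-preserving scale and
#' recorded offsets so the sagittal output can be mapped back exactly onto
#' the scan grid. A config switch substitutes the raw (unmasked) slice for
#' channel 1.
#'
#' @param v_orig the original (un-resampled) [volume()].
#' @param axial_seg [volume()] from [reconstruct_sagittal()] (resampled
#'   space), continuous values in `[0, 1]`.
#' @param records crop records used to rebuild the corridor.
#' @param size canvas side in voxels (default 384).
#' @param corridor one of `"masked"` (default) or `"raw"`.
#' @return List of `sagittal_input` objects: `x` (array `size x size x 2`),
#'   `record` (canvas mapping + slice index), `slice_index` (0-based).
#' @export
build_sagittal_input <- function(v_orig, axial_seg, records, size = 384,
                                 corridor = c("masked", "raw")) {
  stopifnot(inherits(v_orig, "cc_volume"), inherits(axial_seg, "cc_volume"))
  corridor <- match.arg(corridor)
  d_o <- dim(v_orig$data); d_r <- dim(axial_seg$data)
  if (d_o[1] != d_r[1]) {
    stop("geometry mismatch: cranio-caudal extents differ")
  }
  sp_o <- v_orig$spacing_mm; sp_r <- axial_seg$spacing_mm
  corridor_vol <- reconstruct_sagittal(
    lapply(records, function(r) matrix(1, r$extent_voxel[1],
                                       r$extent_voxel[2])),
    records, list(dim = d_r, spacing_mm = sp_r))
  out <- list()
  for (k in seq_len(d_o[3])) {
    lr_mm <- (k - 1) * sp_o[3]
    kr <- min(max(as.integer(round(lr_mm / sp_r[3])) + 1L, 1L), d_r[3])
    # map resampled-AP columns onto the original slice grid (rows untouched)
    seg_sl <- cc_resize(axial_seg$data[, , kr, drop = TRUE], d_o[1], d_o[2],
                        1, sp_o[2] / sp_r[2], 0, 0, FALSE)
    cor_sl <- cc_resize(corridor_vol$data[, , kr, drop = TRUE], d_o[1],
                        d_o[2], 1, sp_o[2] / sp_r[2], 0, 0, TRUE)
    img_sl <- v_orig$data[, , k, drop = TRUE]
    ch1_src <- if (corridor == "masked") img_sl * cor_sl else img_sl
    rec <- canvas_record(d_o[1], d_o[2], size)
    ch1 <- suppressWarnings(normalize_intensity(resize_to_canvas(ch1_src,
                                                                 rec)))
    ch2 <- pmin(pmax(resize_to_canvas(seg_sl, rec), 0), 1)
    rec$slice_index <- k - 1L
    out[[k]] <- structure(
      list(x = array(c(ch1, ch2), c(size, size, 2L)), record = rec,
           slice_index = k - 1L),
      class = "sagittal_input")
  }
  out
}
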