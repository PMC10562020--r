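# Overlap and surface-distance metrics. Distances are computed in 3-D scan
# space in mm using the anisotropic voxel spacing; boundary voxels are
# positive voxels with at least one face-adjacent (6-connectivity)
# background neighbour, with the volume border counting as background.

check_geometry <- function(a, b) {
  stopifnot(inherits(a, "cc_mask"), inherits(b, "cc_mask"))
  if (!same_geometry(a, b)) stop("mask geometries differ")
}

#' Dice coefficient
#'
#' `2 |A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [mask_volume()]s with identical geometry.
#' @return Dice in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_geometry(a, b)
  sa <- sum(a$data); sb <- sum(b$data)
  if (sa + sb == 0) return(1.0)
  2 * sum(a$data * b$data) / (sa + sb)
}

#' True positive rate, both conventions
#'
#' The protocol's verbal definition — the proportion of voxels segmented by
#' the network that are also on the reference mask — is precision
#' (`|P n T| / |P|`); the conventional TPR (sensitivity) is
#' `|P n T| / |T|`. Both are returned; reports use `tpr_paper` by default.
#'
#' @param pred,truth [mask_volume()]s with identical geometry.
#' @return Named numeric: `tpr_paper`, `tpr_standard` (`NA` when the
#'   denominator is empty).
#' @export
tpr <- function(pred, truth) {
  check_geometry(pred, truth)
  inter <- sum(pred$data * truth$data)
  c(tpr_paper = if (sum(pred$data) > 0) inter / sum(pred$data) else NA_real_,
    tpr_standard = if (sum(truth$data) > 0) inter / sum(truth$data)
                   else NA_real_)
}

boundary_points_mm <- function(m) {
  b <- cc_boundary6(m$data)
  w <- which(b > 0, arr.ind = TRUE)
  if (nrow(w) == 0) return(matrix(numeric(0), 0, 3))
  sweep(w - 1, 2, m$spacing_mm, `*`)
}

#' Mean surface distance
#'
#' Symmetric average of nearest-neighbour Euclidean distances between the
#' two masks' boundary voxels (the mean of both directed means), in mm.
#'
#' @param a,b non-empty [mask_volume()]s with identical geometry.
#' @return Distance in mm (`NA` if either mask is empty).
#' @export
mean_surface_distance <- function(a, b) {
  check_geometry(a, b)
  pa <- boundary_points_mm(a); pb <- boundary_points_mm(b)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(NA_real_)
  (mean(cc_nn_directed(pa, pb)) + mean(cc_nn_directed(pb, pa))) / 2
}

#' Maximal (symmetric) Hausdorff distance
#'
#' The larger of the two directed maximum nearest-neighbour distances over
#' boundary voxels, in mm.
#'
#' @param a,b non-empty [mask_volume()]s with identical geometry.
#' @return Distance in mm (`NA` if either mask is empty).
#' @export
max_hausdorff <- function(a, b) {
  check_geometry(a, b)
  pa <- boundary_points_mm(a); pb <- boundary_points_mm(b)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(NA_real_)
  max(max(cc_nn_directed(pa, pb)), max(cc_nn_directed(pb, pa)))
}

#' Per-scan metrics table
#'
#' @param pred named list of predicted [mask_volume()]s.
#' @param truth named list of ground-truth [mask_volume()]s (same names).
#' @param method label recorded in the `method` column.
#' @return data.frame: `scan`, `method`, `dice`, `tpr_paper`,
#'   `tpr_standard`, `msd_mm`, `mhd_mm`.
#' @export
evaluate_masks <- function(pred, truth, method = "network") {
  stopifnot(length(pred) == length(truth))
  nms <- names(pred) %||% as.character(seq_along(pred))
  do.call(rbind, lapply(seq_along(pred), function(i) {
    tp <- tpr(pred[[i]], truth[[i]])
    data.frame(scan = nms[i], method = method,
               dice = dice(pred[[i]], truth[[i]]),
               tpr_paper = tp[["tpr_paper"]],
               tpr_standard = tp[["tpr_standard"]],
               msd_mm = mean_surface_distance(pred[[i]], truth[[i]]),
               mhd_mm = max_hausdorff(pred[[i]], truth[[i]]),
               stringsAsFactors = FALSE)
  }))
}
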