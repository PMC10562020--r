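# Paired elastic + rotation augmentation with scheduled renewal and dataset
# doubling. The elastic transform is a Gaussian-smoothed random displacement
# field rescaled so its peak displacement magnitude equals the coefficient
# (in voxels); identical geometry is applied to image and mask.

#' Augmentation policy
#'
#' Stage defaults follow the training protocol: axial slices draw an elastic
#' coefficient from (-10, 10) and a rotation from (-5, 5) degrees with
#' augmented copies renewed every epoch; sagittal slices draw from (-50, 50)
#' and (-15, 15) with renewal every 10 epochs. The displacement field's
#' smoothing scale defaults to 16 voxels for the axial stage (64 x 64
#' patches) and 96 for the sagittal stage (384 x 384 inputs): roughly twice
#' the largest in-range peak displacement, which keeps the warp
#' diffeomorphic (positive Jacobian, no tearing) over the whole coefficient
#' range. Both stages double the dataset: every epoch dataset is originals
#' plus one augmented copy of each.
#'
#' @param stage `"axial"` or `"sagittal"` (sets defaults), or override the
#'   individual fields.
#' @param elastic_range,rotation_range_deg symmetric ranges (lo, hi).
#' @param elastic_sigma Gaussian smoothing scale of the displacement field,
#'   voxels.
#' @param renewal_every_epochs regenerate augmented copies when
#'   `epoch %% renewal == 0` (and at the first build).
#' @param double_dataset keep originals alongside augmented copies.
#' @param rng_seed integer seed for augmentation randomness.
#' @return An object of class `augment_policy`.
#' @export
augment_policy <- function(stage = c("axial", "sagittal"),
                           elastic_range = NULL,
                           rotation_range_deg = NULL,
                           elastic_sigma = NULL,
                           renewal_every_epochs = NULL,
                           double_dataset = TRUE,
                           rng_seed = 1L) {
  stage <- match.arg(stage)
  def <- if (stage == "axial") {
    list(elastic_range = c(-10, 10), rotation_range_deg = c(-5, 5),
         elastic_sigma = 16, renewal_every_epochs = 1L)
  } else {
    list(elastic_range = c(-50, 50), rotation_range_deg = c(-15, 15),
         elastic_sigma = 96, renewal_every_epochs = 10L)
  }
  p <- list(
    stage = stage,
    elastic_range = if (is.null(elastic_range)) def$elastic_range
                    else elastic_range,
    rotation_range_deg = if (is.null(rotation_range_deg))
                           def$rotation_range_deg else rotation_range_deg,
    elastic_sigma = if (is.null(elastic_sigma)) def$elastic_sigma
                    else elastic_sigma,
    renewal_every_epochs = if (is.null(renewal_every_epochs))
                             def$renewal_every_epochs
                           else as.integer(renewal_every_epochs),
    double_dataset = isTRUE(double_dataset),
    rng_seed = as.integer(rng_seed)
  )
  if (abs(p$elastic_range[1] + p$elastic_range[2]) > 1e-9 ||
      abs(p$rotation_range_deg[1] + p$rotation_range_deg[2]) > 1e-9) {
    stop("augmentation ranges must be symmetric about 0")
  }
  if (p$renewal_every_epochs < 1L) stop("renewal interval must be >= 1")
  class(p) <- "augment_policy"
  p
}

#' Smoothed random displacement field
#'
#' Uniform random per-voxel displacements smoothed with a Gaussian of scale
#' `sigma` voxels and rescaled so the peak displacement magnitude equals
#' `|coefficient|` voxels (the field's sign follows the coefficient's).
#'
#' @param h,w field shape.
#' @param coefficient signed peak displacement, voxels.
#' @param sigma smoothing scale, voxels.
#' @param seed integer seed.
#' @return List with matrices `dr`, `dc` (row/column displacements).
#' @export
elastic_field <- function(h, w, coefficient, sigma = 16, seed = 1L) {
  with_local_seed(seed, {
    dr <- cc_gauss_blur(matrix(runif(h * w, -1, 1), h, w), sigma)
    dc <- cc_gauss_blur(matrix(runif(h * w, -1, 1), h, w), sigma)
    mag <- sqrt(dr^2 + dc^2)
    m <- max(mag)
    s <- if (m > 0) coefficient / m else 0
    list(dr = s * dr, dc = s * dc)
  })
}

#' Apply one elastic + rotation transform to an image/mask pair
#'
#' The identical geometric transform is applied to both grids: rotation by
#' `rot_deg` about the grid centre composed with the elastic displacement
#' field. The image is interpolated bilinearly, the mask nearest-neighbour
#' and re-binarized; out-of-range samples are zero-filled. Shape is
#' unchanged. `image` may be a 2-D grid or an `H x W x C` array (all
#' channels share the transform).
#'
#' @param image 2-D grid or 3-D array.
#' @param mask 2-D binary grid of the same spatial shape, or `NULL`.
#' @param elastic_c signed elastic coefficient (peak displacement, voxels).
#' @param rot_deg rotation, degrees.
#' @param seed integer seed for the displacement field.
#' @param sigma field smoothing scale, voxels.
#' @return List with `image` and `mask` (transformed).
#' @export
augment_pair <- function(image, mask = NULL, elastic_c = 0, rot_deg = 0,
                         seed = 1L, sigma = 16) {
  dims <- dim(image)
  h <- dims[1]; w <- dims[2]
  if (!is.null(mask) && !all(dim(mask)[1:2] == c(h, w))) {
    stop("image and mask shapes differ")
  }
  f <- elastic_field(h, w, elastic_c, sigma, seed)
  th <- rot_deg * pi / 180
  ctr_r <- (h - 1) / 2; ctr_c <- (w - 1) / 2
  rr <- matrix(seq_len(h) - 1, h, w) - ctr_r
  cc <- matrix(rep(seq_len(w) - 1, each = h), h, w) - ctr_c
  src_r <- ctr_r + cos(th) * rr - sin(th) * cc + f$dr
  src_c <- ctr_c + sin(th) * rr + cos(th) * cc + f$dc
  warp1 <- function(g, nearest) cc_warp(g, src_r, src_c, nearest)
  out_img <- if (length(dims) == 3L) {
    array(vapply(seq_len(dims[3]), function(c) warp1(image[, , c], FALSE),
                 matrix(0, h, w)), dims)
  } else {
    warp1(image, FALSE)
  }
  out_mask <- if (is.null(mask)) NULL else (warp1(mask, TRUE) > 0.5) * 1
  list(image = out_img, mask = out_mask)
}

#' Build the training dataset for one epoch
#'
#' Returns the originals plus one augmented copy of each (dataset doubled).
#' Augmented copies are regenerated with fresh random coefficients at the
#' first build and whenever `epoch %% renewal_every_epochs == 0`; otherwise
#' the previous epoch's augmented copies are reused. Validation data must
#' never pass through this function.
#'
#' @param originals list of items, each `list(x = grid or array, y = mask)`.
#' @param policy an [augment_policy()].
#' @param epoch 1-based epoch number.
#' @param previous the previous epoch's return value, or `NULL`.
#' @return List with `items` (length `2 * length(originals)` when doubling),
#'   `augmented`, and `epoch`.
#' @export
build_epoch_dataset <- function(originals, policy, epoch, previous = NULL) {
  stopifnot(inherits(policy, "augment_policy"), length(originals) > 0)
  if (!policy$double_dataset) {
    return(list(items = originals, augmented = list(), epoch = epoch))
  }
  renew <- is.null(previous) || epoch %% policy$renewal_every_epochs == 0L
  augmented <- if (!renew) {
    previous$augmented
  } else {
    base <- derive_seed(policy$rng_seed, epoch)
    lapply(seq_along(originals), function(t) {
      it <- originals[[t]]
      pars <- with_local_seed(derive_seed(base, t), {
        c(runif(1, policy$elastic_range[1], policy$elastic_range[2]),
          runif(1, policy$rotation_range_deg[1],
                policy$rotation_range_deg[2]))
      })
      a <- augment_pair(it$x, it$y, pars[1], pars[2],
                        seed = derive_seed(base, t + length(originals)),
                        sigma = policy$elastic_sigma)
      list(x = a$image, y = a$mask)
    })
  }
  list(items = c(originals, augmented), augmented = augmented, epoch = epoch)
}
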