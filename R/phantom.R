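# Synthetic sagittal T2-like spinal phantoms. A T2-weighted cord appears as a
# mid-intensity tube inside a bright CSF rim over darker tissue; traumatic
# lesions locally collapse the cord/CSF contrast. Geometry is anisotropic:
# fine in-plane sagittal sampling, thick left-right slices.

PHANTOM_RANGES <- list(
  sagittal_spacing_mm = c(0.488, 0.703),
  slice_thickness_mm = c(3.0, 4.0),
  slice_gap_mm = c(3.3, 5.0),
  cord_radius_mm = c(3.5, 5.0)
)

PHANTOM_INTENSITY <- list(background = 0.30, cord = 0.45, rim = 0.85,
                          rim_thickness_mm = 2.0)

#' Specify a synthetic spinal phantom
#'
#' Unsupplied acquisition parameters are sampled (deterministically from
#' `seed`) from the observed clinical ranges: sagittal in-plane resolution
#' U(0.488, 0.703) mm, slice thickness U(3.0, 4.0) mm, slice gap
#' U(3.3, 5.0) mm, cord radius U(3.5, 5.0) mm. Sagittal slice centres are
#' spaced `slice_thickness_mm + slice_gap_mm` apart. Explicitly supplied
#' values are accepted as-is (positivity checked), so degenerate or
#' fine-sampled geometries can be constructed for testing.
#'
#' @param seed integer; drives both parameter sampling and image noise.
#' @param n_sagittal_slices number of sagittal slices (default 13).
#' @param in_plane_shape integer pair, sagittal in-plane grid
#'   (cranio-caudal x anterior-posterior voxels), default `c(384, 320)`.
#' @param sagittal_spacing_mm,slice_thickness_mm,slice_gap_mm,cord_radius_mm
#'   acquisition/anatomy parameters in mm; `NULL` to sample.
#' @param curvature_amplitude_mm peak anterior-posterior deviation of the
#'   cord curve from a straight line, mm.
#' @param n_lesions number of traumatic lesions placed on the cord axis.
#' @param lesion_contrast_loss fraction in `[0, 1]` of cord/CSF contrast
#'   lost inside lesions (1 = boundary fully erased).
#' @param noise_sigma standard deviation of additive Gaussian noise on the
#'   `[0, 1]` intensity scale.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed,
                         n_sagittal_slices = 13L,
                         in_plane_shape = c(384L, 320L),
                         sagittal_spacing_mm = NULL,
                         slice_thickness_mm = NULL,
                         slice_gap_mm = NULL,
                         cord_radius_mm = NULL,
                         curvature_amplitude_mm = 10,
                         n_lesions = 1L,
                         lesion_contrast_loss = 0.7,
                         noise_sigma = 0.03) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  sampled <- with_local_seed(derive_seed(seed, 0L), {
    lapply(PHANTOM_RANGES, function(r) runif(1, r[1], r[2]))
  })
  take <- function(value, name) {
    if (is.null(value)) sampled[[name]]
    else {
      if (!is.finite(value) || value <= 0) stop(name, " must be positive")
      value
    }
  }
  spec <- list(
    seed = as.integer(seed),
    n_sagittal_slices = as.integer(n_sagittal_slices),
    in_plane_shape = as.integer(in_plane_shape),
    sagittal_spacing_mm = take(sagittal_spacing_mm, "sagittal_spacing_mm"),
    slice_thickness_mm = take(slice_thickness_mm, "slice_thickness_mm"),
    slice_gap_mm = take(slice_gap_mm, "slice_gap_mm"),
    cord_radius_mm = take(cord_radius_mm, "cord_radius_mm"),
    curvature_amplitude_mm = curvature_amplitude_mm,
    n_lesions = as.integer(n_lesions),
    lesion_contrast_loss = lesion_contrast_loss,
    noise_sigma = noise_sigma
  )
  if (spec$n_sagittal_slices < 1L || any(spec$in_plane_shape < 8L)) {
    stop("invalid phantom shape")
  }
  if (spec$curvature_amplitude_mm < 0 || spec$noise_sigma < 0 ||
      spec$n_lesions < 0L || spec$lesion_contrast_loss < 0 ||
      spec$lesion_contrast_loss > 1) {
    stop("invalid phantom configuration")
  }
  class(spec) <- "phantom_spec"
  spec
}

# Smooth random centre curve along the cranio-caudal axis: cubic spline
# through jittered control points, deviations rescaled so the cord keeps a
# safety margin from the volume borders (the crop corridor must stay
# interior).
phantom_curve <- function(n_cc, extent_mm, amplitude_mm, margin_target_mm,
                          n_ctrl = 6L) {
  centre <- extent_mm / 2
  margin <- min(margin_target_mm, 0.35 * extent_mm)
  ctrl_x <- seq(0, n_cc - 1, length.out = n_ctrl)
  ctrl_y <- runif(n_ctrl, -1, 1) * amplitude_mm
  dev <- spline(ctrl_x, ctrl_y, xout = seq_len(n_cc) - 1)$y
  max_allow <- max(extent_mm / 2 - margin, 0)
  m <- max(abs(dev))
  if (m > max_allow && m > 0) dev <- dev * (max_allow / m)
  centre + dev
}

#' Generate a synthetic phantom volume
#'
#' Renders a curved cord tube (mid intensity) wrapped in a bright CSF rim
#' over darker background tissue, with optional traumatic lesions where the
#' cord/rim intensities are pulled towards their common mean (contrast scaled
#' by `1 - lesion_contrast_loss`, so the cord brightens and the rim darkens
#' locally) and additive Gaussian noise. Ground truth is exact: the binary
#' cord mask, the lesion mask (lesioned cord voxels), and the generative
#' centerline sampled at every axial slice.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_volume`: list with elements `image`
#'   ([volume()]), `cord_mask`, `lesion_mask` ([mask_volume()]),
#'   `centerline` ([centerline()]), `spec`, and the generative geometry.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n1 <- spec$in_plane_shape[1]           # cranio-caudal
  n2 <- spec$in_plane_shape[2]           # anterior-posterior
  n3 <- spec$n_sagittal_slices           # left-right
  sp <- c(spec$sagittal_spacing_mm, spec$sagittal_spacing_mm,
          spec$slice_thickness_mm + spec$slice_gap_mm)
  ext <- dim_extent_mm(c(n1, n2, n3), sp)
  inten <- PHANTOM_INTENSITY
  r <- spec$cord_radius_mm
  rim_out <- r + inten$rim_thickness_mm

  with_local_seed(derive_seed(spec$seed, 1L), {
    curve_ap <- phantom_curve(n1, ext[2], spec$curvature_amplitude_mm, 20)
    curve_lr <- phantom_curve(n1, ext[3], 0.15 * spec$curvature_amplitude_mm,
                              20)
    ap_mm <- (seq_len(n2) - 1) * sp[2]
    lr_mm <- (seq_len(n3) - 1) * sp[3]
    img <- array(inten$background, c(n1, n2, n3))
    cord <- array(0, c(n1, n2, n3))
    for (i in seq_len(n1)) {
      d2 <- outer((ap_mm - curve_ap[i])^2, (lr_mm - curve_lr[i])^2, `+`)
      dist <- sqrt(d2)
      sl <- img[i, , ]
      sl[dist <= rim_out] <- inten$rim
      sl[dist <= r] <- inten$cord
      img[i, , ] <- sl
      cord[i, , ] <- (dist <= r) * 1
    }

    lesion <- array(0, c(n1, n2, n3))
    if (spec$n_lesions > 0L && spec$lesion_contrast_loss > 0) {
      mid <- (inten$cord + inten$rim) / 2
      half_delta <- (inten$rim - inten$cord) / 2
      keep <- 1 - spec$lesion_contrast_loss
      for (l in seq_len(spec$n_lesions)) {
        len <- runif(1, 10, 30)                        # lesion length, mm
        ctr <- runif(1, 0.2, 0.8) * (n1 - 1)           # centre slice index
        half_cc <- len / 2 / sp[1]
        rad <- rim_out + 0.5                           # radial half-axis, mm
        for (i in seq_len(n1)) {
          u <- (i - 1 - ctr) / half_cc
          if (abs(u) >= 1) next
          d2 <- outer((ap_mm - curve_ap[i])^2, (lr_mm - curve_lr[i])^2, `+`)
          dist <- sqrt(d2)
          inside <- dist <= rad * sqrt(1 - u^2)
          sl <- img[i, , ]
          in_cord <- inside & dist <= r
          in_rim <- inside & dist > r & dist <= rim_out
          sl[in_cord] <- mid - keep * half_delta
          sl[in_rim] <- mid + keep * half_delta
          img[i, , ] <- sl
          lesion[i, , ] <- lesion[i, , ] + in_cord
        }
      }
      lesion <- (lesion > 0) * 1
    }

    if (spec$noise_sigma > 0) {
      img <- img + array(rnorm(length(img), 0, spec$noise_sigma), dim(img))
    }

    cl <- centerline(cbind(curve_ap, curve_lr),
                     valid = vapply(seq_len(n1),
                                    function(i) any(cord[i, , ] > 0),
                                    logical(1)),
                     source = "oracle")
    structure(list(
      image = volume(img, sp),
      cord_mask = mask_volume(cord, sp),
      lesion_mask = mask_volume(lesion, sp),
      centerline = cl,
      spec = spec,
      curve_ap_mm = curve_ap,
      curve_lr_mm = curve_lr,
      intensities = inten
    ), class = "phantom_volume")
  })
}

dim_extent_mm <- function(d, spacing) d * spacing

#' Generate a cohort of phantom scans with patient grouping
#'
#' Produces `sum(scans_per_patient)` phantom scans; each scan carries its
#' patient id so splits can be patient-grouped. Scans of the same patient
#' share anatomy-like parameters only through chance; each scan has its own
#' deterministic child seed.
#'
#' @param n_patients number of patients (>= 1).
#' @param scans_per_patient integer vector of length `n_patients` (default
#'   one scan each).
#' @param seed integer master seed.
#' @param spec_args named list of arguments forwarded to [phantom_spec()]
#'   (e.g. smaller `in_plane_shape` for fast tests).
#' @param generate logical; when `FALSE` only the manifest entries are
#'   produced (no volumes), which is sufficient for fold planning.
#' @return A list of class `phantom_cohort`: elements are lists with
#'   `patient_id`, `scan_id`, and (when `generate`) `phantom`.
#' @export
generate_cohort <- function(n_patients, scans_per_patient = NULL, seed = 1L,
                            spec_args = list(), generate = TRUE) {
  if (n_patients < 1L) stop("`n_patients` must be >= 1")
  if (is.null(scans_per_patient)) scans_per_patient <- rep(1L, n_patients)
  if (length(scans_per_patient) != n_patients ||
      any(scans_per_patient < 1L)) {
    stop("`scans_per_patient` must give >= 1 scan for each patient")
  }
  entries <- list()
  idx <- 0L
  for (p in seq_len(n_patients)) {
    for (s in seq_len(scans_per_patient[p])) {
      idx <- idx + 1L
      entry <- list(patient_id = sprintf("P%04d", p),
                    scan_id = sprintf("P%04d_S%d", p, s))
      if (generate) {
        args <- c(list(seed = derive_seed(seed, idx)), spec_args)
        entry$phantom <- generate_phantom(do.call(phantom_spec, args))
      }
      entries[[idx]] <- entry
    }
  }
  structure(entries, class = "phantom_cohort")
}

#' Manifest of a phantom cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @return data.frame with columns `scan_id`, `patient_id` (plus `scan_path`,
#'   `mask_path` when present).
#' @export
cohort_manifest <- function(cohort) {
  df <- data.frame(
    scan_id = vapply(cohort, `[[`, "", "scan_id"),
    patient_id = vapply(cohort, `[[`, "", "patient_id"),
    stringsAsFactors = FALSE
  )
  if (!is.null(cohort[[1]]$scan_path)) {
    df$scan_path <- vapply(cohort, `[[`, "", "scan_path")
    df$mask_path <- vapply(cohort, `[[`, "", "mask_path")
  }
  df
}

#' Write a phantom cohort to disk
#'
#' Writes each scan and its cord mask as `.nii.gz` plus a `manifest.csv`
#' (`patient_id`, `scan_id`, `scan_path`, `mask_path`).
#'
#' @param cohort a generated [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort)) {
    e <- cohort[[i]]
    if (is.null(e$phantom)) stop("cohort was generated with generate = FALSE")
    sp <- file.path(dir, paste0(e$scan_id, ".nii.gz"))
    mp <- file.path(dir, paste0(e$scan_id, "_mask.nii.gz"))
    write_volume(e$phantom$image, sp)
    write_volume(e$phantom$cord_mask, mp)
    cohort[[i]]$scan_path <- sp
    cohort[[i]]$mask_path <- mp
  }
  mf <- cohort_manifest(cohort)
  write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(mf)
}
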