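test_that("phantom generation is deterministic and geometrically sound", {
  p1 <- small_phantom(1L)
  p2 <- small_phantom(1L)
  expect_identical(p1$image$data, p2$image$data)
  expect_identical(p1$cord_mask$data, p2$cord_mask$data)

  expect_equal(dice(p1$cord_mask, p1$cord_mask), 1.0)

  # cord is one 26-connected component spanning the cranio-caudal extent
  expect_identical(n_components_26(p1$cord_mask$data), 1L)
  occupied <- apply(p1$cord_mask$data, 1, sum) > 0
  expect_gte(mean(occupied), 0.8)

  # lesioned voxels lie on the cord
  expect_true(all(p1$lesion_mask$data <= p1$cord_mask$data))

  # generative centerline lies inside the mask on every non-empty slice
  sp <- p1$image$spacing_mm
  for (i in which(p1$centerline$valid)) {
    ctr <- as.integer(round(p1$centerline$centers_mm[i, ] / sp[2:3])) + 1L
    expect_equal(p1$cord_mask$data[i, ctr[1], ctr[2]], 1)
  }
})

test_that("noiseless cord field thresholds back to the exact mask", {
  p <- small_phantom(3L, n_lesions = 0L, noise_sigma = 0)
  cord_val <- p$intensities$cord
  recovered <- (abs(p$image$data - cord_val) < 1e-12) * 1
  expect_identical(recovered, p$cord_mask$data)
})

test_that("full contrast loss erases the cord/rim boundary inside lesions", {
  p <- small_phantom(2L, lesion_contrast_loss = 1.0, noise_sigma = 0,
                     in_plane_shape = c(48L, 96L))
  stopifnot(sum(p$lesion_mask$data) > 0)
  les_slices <- which(apply(p$lesion_mask$data, 1, sum) > 0)
  out_slices <- setdiff(which(apply(p$cord_mask$data, 1, sum) > 0),
                        les_slices)
  contrast <- function(i) {
    sl <- p$image$data[i, , ]
    cord <- sl[p$cord_mask$data[i, , ] > 0]
    rim <- sl[p$cord_mask$data[i, , ] == 0 & sl > p$intensities$background]
    abs(mean(rim) - mean(cord))
  }
  inside <- mean(vapply(les_slices, contrast, numeric(1)))
  outside <- mean(vapply(out_slices, contrast, numeric(1)))
  expect_lt(inside, outside)
  # with total loss the lesioned slices are near contrast-free at the core
  mid_slice <- les_slices[ceiling(length(les_slices) / 2)]
  expect_lt(contrast(mid_slice), 0.05)
})

test_that("cord mask volume scales quadratically with radius", {
  # fine through-plane sampling so voxel counting approximates the tube
  vol_for <- function(r) {
    p <- small_phantom(11L, cord_radius_mm = r, n_lesions = 0L,
                       noise_sigma = 0, curvature_amplitude_mm = 0,
                       n_sagittal_slices = 40L,
                       slice_thickness_mm = 0.5, slice_gap_mm = 0.2,
                       sagittal_spacing_mm = 0.5)
    sum(p$cord_mask$data)
  }
  v1 <- vol_for(3.5)
  v2 <- vol_for(5.0)
  expect_lt(abs(v2 / v1 - (5.0 / 3.5)^2) / (5.0 / 3.5)^2, 0.1)
})

test_that("spec validation rejects degenerate configurations", {
  expect_error(phantom_spec(1L, sagittal_spacing_mm = -1), "positive")
  expect_error(phantom_spec(1L, lesion_contrast_loss = 1.5), "invalid")
  expect_error(phantom_spec(1L, in_plane_shape = c(4L, 4L)), "shape")
  # sampled parameters stay inside the clinical brackets
  for (s in 1:20) {
    sp <- phantom_spec(s)
    expect_gte(sp$sagittal_spacing_mm, 0.488)
    expect_lte(sp$sagittal_spacing_mm, 0.703)
    expect_gte(sp$slice_thickness_mm, 3.0)
    expect_lte(sp$slice_thickness_mm, 4.0)
    expect_gte(sp$slice_gap_mm, 3.3)
    expect_lte(sp$slice_gap_mm, 5.0)
  }
})

test_that("cohorts carry patient grouping and reproduce exactly", {
  # 94 patients, 12 of them with a second scan: 106 scans
  counts <- rep(1L, 94)
  counts[1:12] <- 2L
  co <- generate_cohort(94, counts, seed = 5L, generate = FALSE)
  expect_length(co, 106L)
  mf <- cohort_manifest(co)
  expect_identical(nrow(mf), 106L)
  expect_identical(length(unique(mf$patient_id)), 94L)

  one <- generate_cohort(1, seed = 2L, generate = FALSE)
  expect_length(one, 1L)

  m1 <- cohort_manifest(generate_cohort(10, rep(1:2, 5), seed = 7L,
                                        generate = FALSE))
  m2 <- cohort_manifest(generate_cohort(10, rep(1:2, 5), seed = 7L,
                                        generate = FALSE))
  expect_identical(m1, m2)
})
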