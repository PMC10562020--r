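test_that("a 32 mm crop at 0.5 mm spacing is a 64x64 patch centred on the cord", {
  p <- small_phantom(20L)
  vr <- resample_axial(p$image)
  cl <- oracle_centerline(p)
  patches <- crop_axial(vr, cl)
  expect_length(patches, sum(cl$valid))
  for (pt in patches[c(1, length(patches))]) {
    expect_identical(dim(pt$image), c(64L, 64L))
  }

  # centring convention: the centerline voxel lands at patch index (32, 32)
  # (0-based) - verify on a delta volume
  d <- dim(vr$data)
  delta <- array(0, d)
  sp <- vr$spacing_mm
  i <- which(cl$valid)[3]
  ctr <- as.integer(round(cl$centers_mm[i, ] / sp[2:3]))
  delta[i, ctr[1] + 1L, ctr[2] + 1L] <- 1
  pd <- crop_axial(volume(delta, sp), cl)
  j <- which(vapply(pd, function(x) x$record$slice_index, 0L) == i - 1L)
  expect_equal(pd[[j]]$image[33L, 33L], 1)
  expect_equal(sum(pd[[j]]$image), 1)
})

test_that("crops at the volume corner are zero-padded with a truthful record", {
  v <- volume(array(1, c(3, 40, 40)), c(0.7, 0.5, 0.5))
  cl <- centerline(matrix(c(0, 0, 0, 0, 0, 0), 3, 2), rep(TRUE, 3),
                   "external_file")
  patches <- crop_axial(v, cl)
  pt <- patches[[1]]
  expect_identical(pt$record$origin_voxel, c(-32L, -32L))
  # only the in-bounds quadrant carries data
  expect_equal(sum(pt$image[1:32, ]), 0)
  expect_equal(sum(pt$image[, 1:32]), 0)
  expect_true(all(pt$image[33:64, 33:64][1:8, 1:8] == 1))
})

test_that("crop then reinsert is the exact inverse inside the corridor", {
  for (s in 1:3) {
    p <- small_phantom(30L + s)
    mr <- resample_axial(p$cord_mask)
    cl <- oracle_centerline(p)
    patches <- crop_axial(mr, cl)
    records <- lapply(patches, function(x) x$record)
    geom <- list(dim = dim(mr$data), spacing_mm = mr$spacing_mm)
    rec <- reconstruct_sagittal(lapply(patches, `[[`, "image"), records,
                                geom)
    corridor <- reconstruct_sagittal(
      lapply(records, function(r) matrix(1, 64, 64)), records, geom)
    expect_identical(rec$data * corridor$data, mr$data * corridor$data)
  }
})

test_that("reconstruction maps single voxels to their recorded position", {
  v <- volume(array(0, c(4, 50, 40)), c(0.7, 0.5, 0.5))
  cl <- centerline(matrix(c(12, 10) * 0.5, 4, 2, byrow = TRUE),
                   rep(TRUE, 4), "external_file")
  patches <- crop_axial(v, cl)
  records <- lapply(patches, function(x) x$record)
  grids <- lapply(records, function(r) matrix(0, 64, 64))
  g <- grids[[2]]
  g[41, 39] <- 1   # patch voxel (40, 38) 0-based, inside the scan bounds
  grids[[2]] <- g
  geom <- list(dim = dim(v$data), spacing_mm = v$spacing_mm)
  rec <- reconstruct_sagittal(grids, records, geom)
  org <- records[[2]]$origin_voxel
  w <- which(rec$data > 0, arr.ind = TRUE)
  expect_identical(nrow(w), 1L)
  expect_identical(as.integer(w),
                   c(2L, org[1] + 40L + 1L, org[2] + 38L + 1L))

  expect_error(reconstruct_sagittal(grids[1:2], records, geom), "mismatch")
})

test_that("percentile normalization clips to [p2, p98] and maps onto [0, 1]", {
  g <- matrix(0:99, 10, 10)
  y <- normalize_intensity(g)
  expect_equal(min(y), 0)
  expect_equal(max(y), 1)

  expect_warning(yc <- normalize_intensity(matrix(5, 4, 4)), "constant")
  expect_true(all(yc == 0))

  # a lone extreme outlier is clipped to exactly 1
  g2 <- matrix(c(1:24, 1e6), 5, 5)
  y2 <- normalize_intensity(g2)
  expect_equal(y2[5, 5], 1)
  # hand-computed type-7 percentiles of the 25 values
  v <- sort(as.vector(g2))
  p2 <- v[1] + (v[2] - v[1]) * (1 + 0.02 * 24 - 1)
  p98 <- v[24] + (v[25] - v[24]) * (1 + 0.98 * 24 - 24)
  expect_equal(y2[2, 1], (g2[2, 1] - p2) / (p98 - p2))

  # idempotence: ties at both extremes make a second pass exact
  g3 <- matrix(c(rep(0, 5), seq(0.1, 0.9, length.out = 90), rep(1, 5)),
               10, 10)
  y3 <- normalize_intensity(g3)
  expect_equal(normalize_intensity(y3), y3, tolerance = 1e-6)
})

test_that("sagittal inputs respect the corridor and canvas mapping", {
  p <- small_phantom(33L)
  ax <- cordcascade:::axial_items_for_scan(p)
  probs <- lapply(ax$items, function(it) matrix(1, 64, 64))
  geom <- list(dim = dim(ax$vr$data), spacing_mm = ax$vr$spacing_mm)
  seg <- reconstruct_sagittal(probs, ax$records, geom)
  inputs <- build_sagittal_input(p$image, seg, ax$records, size = 96)
  expect_length(inputs, dim(p$image$data)[3])
  for (si in inputs) {
    expect_identical(dim(si$x), c(96L, 96L, 2L))
    expect_true(all(si$x >= 0 & si$x <= 1))
  }
  # all-ones axial output: the seg channel reaches 1 inside the corridor
  expect_equal(max(vapply(inputs, function(si) max(si$x[, , 2]),
                          numeric(1))), 1, tolerance = 1e-9)
  # corridor channel is zero where the corridor is absent: slices far from
  # the cord have an empty corridor, hence an all-zero intensity channel
  far <- which(vapply(inputs, function(si) sum(si$x[, , 2]), numeric(1))
               < 1e-9)
  if (length(far) > 0) {
    expect_true(all(vapply(inputs[far],
                           function(si) sum(si$x[, , 1]) < 1e-9,
                           logical(1))))
  }
})

test_that("canvas resize round-trips a smooth grid within tolerance", {
  h <- 32L; w <- 96L
  g <- outer(seq_len(h), seq_len(w),
             function(i, j) 0.5 + 0.4 * sin(i / 6) * cos(j / 9))
  rec <- cordcascade:::canvas_record(h, w, 96L)
  up <- cordcascade:::resize_to_canvas(g, rec)
  back <- cordcascade:::resize_from_canvas(up, rec)
  expect_lt(max(abs(back - g)), 0.02)
})
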