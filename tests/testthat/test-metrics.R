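toy_mask <- function(d, idx, spacing = c(0.5, 0.5, 0.5)) {
  m <- array(0, d)
  m[idx] <- 1
  mask_volume(m, spacing)
}

test_that("Dice matches enumerated toys and its conventions", {
  d <- c(4L, 4L, 2L)
  a <- toy_mask(d, 1:6)
  expect_equal(dice(a, a), 1.0)
  b <- toy_mask(d, 7:12)
  expect_equal(dice(a, b), 0.0)

  # |A| = 4, |B| = 6, |A n B| = 3 -> 0.6
  a2 <- toy_mask(d, c(1, 2, 3, 4))
  b2 <- toy_mask(d, c(2, 3, 4, 5, 6, 7))
  expect_equal(dice(a2, b2), 0.6)
  expect_equal(dice(b2, a2), 0.6)

  # both empty: defined as 1
  expect_equal(dice(toy_mask(d, integer(0)), toy_mask(d, integer(0))), 1.0)
  expect_error(dice(a, toy_mask(c(4L, 4L, 3L), 1:2)), "differ")
})

test_that("both TPR conventions are reported", {
  d <- c(5L, 4L, 1L)
  truth <- toy_mask(d, 1:10)
  expect_equal(tpr(truth, truth), c(tpr_paper = 1, tpr_standard = 1))

  half <- toy_mask(d, 1:5)          # pred strictly inside truth
  expect_equal(tpr(half, truth), c(tpr_paper = 1, tpr_standard = 0.5))
  # swapped: pred twice the size of truth
  expect_equal(tpr(truth, half), c(tpr_paper = 0.5, tpr_standard = 1))

  empty <- toy_mask(d, integer(0))
  expect_true(is.na(tpr(empty, truth)[["tpr_paper"]]))
  expect_true(is.na(tpr(truth, empty)[["tpr_standard"]]))

  # duality: tpr_paper(p, t) == tpr_standard(t, p)
  set.seed(2)
  for (s in 1:5) {
    p1 <- random_small_mask(s)
    p2 <- random_small_mask(s + 50)
    expect_equal(tpr(p1, p2)[["tpr_paper"]], tpr(p2, p1)[["tpr_standard"]])
  }
})

test_that("surface distances match closed forms and mm units", {
  d <- c(8L, 8L, 1L)
  a <- toy_mask(d, NULL); a$data[2, 2, 1] <- 1
  b <- toy_mask(d, NULL); b$data[2, 5, 1] <- 1
  # single voxels 3 voxels apart at 0.5 mm spacing
  expect_equal(mean_surface_distance(a, b), 1.5)
  expect_equal(max_hausdorff(a, b), 1.5)
  expect_equal(mean_surface_distance(a, a), 0)
  expect_equal(max_hausdorff(a, a), 0)

  # anisotropic spacing: distances are physical
  sp <- c(0.7, 0.5, 6.5)
  a3 <- toy_mask(c(4L, 4L, 3L), NULL, sp); a3$data[1, 1, 1] <- 1
  b3 <- toy_mask(c(4L, 4L, 3L), NULL, sp); b3$data[2, 3, 2] <- 1
  expected <- sqrt(0.7^2 + (2 * 0.5)^2 + 6.5^2)
  expect_equal(max_hausdorff(a3, b3), expected)

  # empty masks are undefined
  e <- toy_mask(d, integer(0))
  expect_true(is.na(mean_surface_distance(a, e)))
  expect_true(is.na(max_hausdorff(e, a)))
})

test_that("distances agree with the brute-force all-pairs oracle", {
  # nested squares
  d <- c(20L, 20L, 1L)
  sq <- function(h) {
    m <- array(0, d)
    m[(10 - h):(10 + h), (10 - h):(10 + h), 1] <- 1
    mask_volume(m, c(0.5, 0.5, 0.5))
  }
  a <- sq(5); b <- sq(7)
  pa <- cordcascade:::boundary_points_mm(a)
  pb <- cordcascade:::boundary_points_mm(b)
  msd_oracle <- (mean(oracle_directed_dists(pa, pb)) +
                   mean(oracle_directed_dists(pb, pa))) / 2
  expect_equal(mean_surface_distance(a, b), msd_oracle, tolerance = 1e-12)

  # random mask pairs, anisotropic spacing
  for (s in 1:8) {
    x <- random_small_mask(s)
    y <- random_small_mask(s + 100)
    px <- cordcascade:::boundary_points_mm(x)
    py <- cordcascade:::boundary_points_mm(y)
    expect_equal(max_hausdorff(x, y),
                 max(max(oracle_directed_dists(px, py)),
                     max(oracle_directed_dists(py, px))),
                 tolerance = 1e-12)
    expect_equal(mean_surface_distance(x, y),
                 (mean(oracle_directed_dists(px, py)) +
                    mean(oracle_directed_dists(py, px))) / 2,
                 tolerance = 1e-12)
  }
})

test_that("metric invariants: symmetry, ordering, translation", {
  for (s in 1:5) {
    a <- random_small_mask(s + 10)
    b <- random_small_mask(s + 60)
    expect_equal(mean_surface_distance(a, b), mean_surface_distance(b, a))
    expect_equal(max_hausdorff(a, b), max_hausdorff(b, a))
    expect_lte(mean_surface_distance(a, b), max_hausdorff(a, b) + 1e-12)
  }

  # translated boxes: Hausdorff equals the shift for convex shapes
  d <- c(16L, 16L, 4L)
  sp <- c(0.5, 0.5, 2.0)
  box <- function(r0, c0) {
    m <- array(0, d)
    m[r0:(r0 + 5), c0:(c0 + 5), 2:3] <- 1
    mask_volume(m, sp)
  }
  a <- box(3, 3); b <- box(6, 4)
  shift <- sqrt((3 * 0.5)^2 + (1 * 0.5)^2)
  expect_equal(max_hausdorff(a, b), shift, tolerance = 1e-9)
})

test_that("evaluate_masks assembles the per-scan report", {
  pred <- list(s1 = random_small_mask(1), s2 = random_small_mask(2))
  truth <- list(s1 = random_small_mask(3), s2 = random_small_mask(2))
  rep <- evaluate_masks(pred, truth, method = "net")
  expect_identical(nrow(rep), 2L)
  expect_identical(rep$method, rep("net", 2))
  expect_equal(rep$dice[2], 1)
  expect_equal(rep$msd_mm[2], 0)
})
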