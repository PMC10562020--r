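# Shared fixtures: small phantoms keep the suite fast while exercising the
# same generative model as the full-size defaults.

small_spec_args <- function(...) {
  modifyList(list(
    n_sagittal_slices = 6L,
    in_plane_shape = c(32L, 96L),
    sagittal_spacing_mm = 0.7,
    slice_thickness_mm = 3.0,
    slice_gap_mm = 3.5,
    cord_radius_mm = 4.0,
    curvature_amplitude_mm = 6,
    n_lesions = 1L,
    lesion_contrast_loss = 0.8,
    noise_sigma = 0.02
  ), list(...))
}

small_phantom <- function(seed, ...) {
  generate_phantom(do.call(phantom_spec,
                           c(list(seed = seed), small_spec_args(...))))
}

# Test-side connected-component count (26-connectivity), brute force.
n_components_26 <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  remaining <- new.env(hash = TRUE)
  for (i in seq_len(nrow(idx))) assign(key(idx[i, , drop = FALSE]), idx[i, ],
                                       envir = remaining)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  comps <- 0L
  while (length(ls(remaining)) > 0) {
    comps <- comps + 1L
    start <- get(ls(remaining)[1], envir = remaining)
    frontier <- matrix(start, 1, 3)
    rm(list = ls(remaining)[1], envir = remaining)
    while (nrow(frontier) > 0) {
      nxt <- list()
      for (r in seq_len(nrow(frontier))) {
        nb <- sweep(offs, 2, frontier[r, ], `+`)
        for (q in seq_len(nrow(nb))) {
          k <- key(nb[q, , drop = FALSE])
          if (exists(k, envir = remaining, inherits = FALSE)) {
            nxt[[length(nxt) + 1L]] <- nb[q, ]
            rm(list = k, envir = remaining)
          }
        }
      }
      frontier <- if (length(nxt)) do.call(rbind, nxt) else
        matrix(numeric(0), 0, 3)
    }
  }
  comps
}

# Brute-force directed nearest-neighbour distances (oracle for the metric
# kernels), all pairs in R.
oracle_directed_dists <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i) {
    sqrt(min(colSums((t(B) - A[i, ])^2)))
  }, numeric(1))
}

# Random small mask volume with at least one positive voxel.
random_small_mask <- function(seed, dim = c(6L, 7L, 5L),
                              spacing = c(0.7, 0.5, 3.2), n_max = 50L) {
  set.seed(seed)
  m <- array(0, dim)
  n <- sample(1:n_max, 1)
  pos <- sample(prod(dim), n)
  m[pos] <- 1
  mask_volume(m, spacing)
}
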