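# Orchestration: patient-grouped fold planning, axial-then-sagittal cascade
# inference, the sagittal training-slice filter, the 20-voxel sagittal-slice
# postprocessing rule, and an end-to-end scaled experiment driver used for
# testing on phantom cohorts.

#' Patient-grouped K-fold plan with held-out test set
#'
#' Scans are first split into test and training sets by patient (no patient
#' straddles the split), targeting `test_fraction` of the scans. Training
#' patients are then assigned to `k` validation folds: patients ordered by
#' scan count (ties shuffled under `seed`) are placed greedily into the
#' currently smallest fold, which makes fold sizes as even as patient
#' grouping allows (86 scans over 10 folds give six folds of 9 and four of
#' 8).
#'
#' @param manifest data.frame with columns `scan_id`, `patient_id`.
#' @param k number of validation folds (default 10).
#' @param test_fraction fraction of scans held out for testing (0 for no
#'   test set).
#' @param seed integer seed.
#' @return An object of class `fold_plan`: `fold_assignments` (named fold
#'   index per training scan), `test_scans`, `patient_of`, `k`.
#' @export
make_fold_plan <- function(manifest, k = 10L, test_fraction = 0.2,
                           seed = 1L) {
  stopifnot(all(c("scan_id", "patient_id") %in% names(manifest)))
  patients <- split(manifest$scan_id, manifest$patient_id)
  with_local_seed(derive_seed(seed, 5L), {
    test_scans <- character(0)
    pool <- names(patients)
    if (test_fraction > 0) {
      target <- round(test_fraction * nrow(manifest))
      for (pid in sample(pool)) {
        if (length(test_scans) >= target) break
        test_scans <- c(test_scans, patients[[pid]])
      }
      pool <- setdiff(pool, unique(manifest$patient_id[
        manifest$scan_id %in% test_scans]))
    }
    if (k > length(pool)) {
      stop("k = ", k, " exceeds the number of training patients (",
           length(pool), ")")
    }
    counts <- vapply(patients[pool], length, integer(1))
    ord <- pool[order(-counts, sample.int(length(pool)))]
    sizes <- integer(k)
    fold_of_patient <- setNames(integer(length(ord)), ord)
    for (pid in ord) {
      f <- which.min(sizes)
      fold_of_patient[pid] <- f
      sizes[f] <- sizes[f] + length(patients[[pid]])
    }
    train_scans <- setdiff(manifest$scan_id, test_scans)
    patient_of <- setNames(manifest$patient_id, manifest$scan_id)
    fold_assignments <- setNames(
      fold_of_patient[patient_of[train_scans]], train_scans)
    structure(list(k = as.integer(k), fold_assignments = fold_assignments,
                   test_scans = test_scans, patient_of = patient_of),
              class = "fold_plan")
  })
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k = %d, %d training scans, %d test scans\n",
              x$k, length(x$fold_assignments), length(x$test_scans)))
  print(table(x$fold_assignments))
  invisible(x)
}

#' Keep sagittal slices the axial network segmented
#'
#' Training-only filter: a sagittal input is kept when its axial
#' segmentation channel, binarized at 0.5, contains at least one positive
#' voxel. At inference all slices are processed.
#'
#' @param inputs list of `sagittal_input` objects
#'   ([build_sagittal_input()]).
#' @return The filtered list (possibly empty).
#' @export
filter_sagittal_slices <- function(inputs) {
  keep <- vapply(inputs, function(si) any(si$x[, , 2] >= 0.5), logical(1))
  inputs[keep]
}

#' Postprocess a segmentation mask
#'
#' For each sagittal slice independently: if the slice contains fewer than
#' `min_voxels` positive voxels it is set to zero, otherwise left unchanged.
#'
#' @param m a [mask_volume()].
#' @param min_voxels threshold (default 20).
#' @return The postprocessed [mask_volume()].
#' @export
postprocess_mask <- function(m, min_voxels = 20L) {
  stopifnot(inherits(m, "cc_mask"))
  d <- dim(m$data)
  for (k in seq_len(d[3])) {
    if (sum(m$data[, , k]) < min_voxels) m$data[, , k] <- 0
  }
  m
}

# Map a binary mask living on the resampled grid back onto the original
# scan grid (nearest neighbour; cranio-caudal sampling is shared).
mask_to_original_geometry <- function(mask_res, geom_orig) {
  d_o <- geom_orig$dim; sp_o <- geom_orig$spacing_mm
  sp_r <- mask_res$spacing_mm
  out <- array(0, d_o)
  for (k in seq_len(d_o[3])) {
    kr <- min(max(as.integer(round((k - 1) * sp_o[3] / sp_r[3])) + 1L, 1L),
              dim(mask_res$data)[3])
    out[, , k] <- cc_resize(mask_res$data[, , kr, drop = TRUE],
                            d_o[1], d_o[2], 1, sp_o[2] / sp_r[2], 0, 0,
                            TRUE)
  }
  mask_volume((out > 0.5) * 1, sp_o)
}

#' Cascade inference on one scan
#'
#' Full two-stage inference: resample the axial plane to the working
#' resolution, obtain the centerline, crop and normalize 64x64 axial
#' patches, run the axial network on every slice, rearrange the
#' probabilities sagittally, build the two-channel sagittal inputs for ALL
#' original sagittal slices, run the sagittal network, map each output back
#' onto the original scan grid, binarize at 0.5, restrict to the crop
#' corridor, and apply the 20-voxel slice rule. The returned mask shares
#' the input scan's geometry.
#'
#' @param v the original [volume()].
#' @param axial_net,sagittal_net trained [build_network()] networks.
#' @param centerline_source a [centerline()] for the resampled volume, or a
#'   function `function(v_resampled) -> centerline` (e.g.
#'   [detect_centerline()]).
#' @param target_mm working axial resolution (default 0.5).
#' @param crop_mm axial crop side, mm (default 32).
#' @param return_stages also return the axial-only mask (mapped to original
#'   geometry and postprocessed) and the intermediate volumes.
#' @return A [mask_volume()] — or, with `return_stages`, a list with
#'   `mask`, `axial_mask`, `axial_prob` and `sagittal_inputs`.
#' @export
infer_cascade <- function(v, axial_net, sagittal_net, centerline_source,
                          target_mm = 0.5, crop_mm = 32,
                          return_stages = FALSE) {
  stopifnot(inherits(v, "cc_volume"))
  vr <- resample_axial(v, target_mm, "linear")
  cl <- if (inherits(centerline_source, "cc_centerline")) centerline_source
        else centerline_source(vr)
  patches <- crop_axial(vr, cl, crop_mm)
  records <- lapply(patches, function(p) p$record)
  probs <- lapply(patches, function(p) {
    network_forward(axial_net,
                    suppressWarnings(normalize_intensity(p$image)))$y[, , 1]
  })
  geom_r <- list(dim = dim(vr$data), spacing_mm = vr$spacing_mm)
  seg <- reconstruct_sagittal(probs, records, geom_r)
  size <- sagittal_net$spec$input_size
  inputs <- build_sagittal_input(v, seg, records, size = size)
  d_o <- dim(v$data)
  out <- array(0, d_o)
  for (si in inputs) {
    yo <- network_forward(sagittal_net, si$x)$y[, , 1]
    out[, , si$slice_index + 1L] <- resize_from_canvas(yo, si$record)
  }
  geom_o <- list(dim = d_o, spacing_mm = v$spacing_mm)
  corridor_res <- reconstruct_sagittal(
    lapply(records, function(r) matrix(1, r$extent_voxel[1],
                                       r$extent_voxel[2])),
    records, geom_r)
  corridor_o <- mask_to_original_geometry(
    mask_volume((corridor_res$data > 0.5) * 1, corridor_res$spacing_mm),
    geom_o)
  mask <- mask_volume((out > 0.5) * corridor_o$data, v$spacing_mm)
  mask <- postprocess_mask(mask)
  if (!return_stages) return(mask)
  axial_mask <- postprocess_mask(mask_to_original_geometry(
    mask_volume((seg$data >= 0.5) * 1, seg$spacing_mm), geom_o))
  list(mask = mask, axial_mask = axial_mask, axial_prob = seg,
       sagittal_inputs = inputs, centerline = cl)
}

# ---- scaled end-to-end experiment on a phantom cohort ----

# Axial training items (normalized 64x64 patch + mask crop) for one phantom.
axial_items_for_scan <- function(ph, target_mm = 0.5, crop_mm = 32) {
  vr <- resample_axial(ph$image, target_mm, "linear")
  mr <- resample_axial(ph$cord_mask, target_mm)
  cl <- oracle_centerline(ph)
  pim <- crop_axial(vr, cl, crop_mm)
  pmk <- crop_axial(mr, cl, crop_mm)
  items <- mapply(function(a, b) {
    list(x = suppressWarnings(normalize_intensity(a$image)), y = b$image)
  }, pim, pmk, SIMPLIFY = FALSE)
  list(items = items, records = lapply(pim, function(p) p$record),
       vr = vr)
}

# Sagittal training items for one phantom given the trained axial network.
sagittal_items_for_scan <- function(ph, axial_net, size, target_mm = 0.5,
                                    crop_mm = 32) {
  ax <- axial_items_for_scan(ph, target_mm, crop_mm)
  probs <- lapply(ax$items, function(it) {
    network_forward(axial_net, it$x)$y[, , 1]
  })
  geom_r <- list(dim = dim(ax$vr$data), spacing_mm = ax$vr$spacing_mm)
  seg <- reconstruct_sagittal(probs, ax$records, geom_r)
  inputs <- build_sagittal_input(ph$image, seg, ax$records, size = size)
  lapply(inputs, function(si) {
    gt <- ph$cord_mask$data[, , si$slice_index + 1L]
    y <- (resize_to_canvas(gt, si$record, nearest = TRUE) > 0.5) * 1
    list(x = si$x, y = y, slice_index = si$slice_index)
  })
}

#' Run a scaled two-stage cascade experiment on a phantom cohort
#'
#' Splits the cohort patient-grouped into training and validation scans,
#' trains the axial network on centerline-cropped patches, runs it on every
#' scan to build the sagittal two-channel inputs (training slices filtered
#' to those the axial network segmented), trains the sagittal network, then
#' evaluates both the axial-only and the combined output against ground
#' truth on the validation scans.
#'
#' @param cohort a generated [generate_cohort()].
#' @param axial_cfg,sagittal_cfg [train_config()]s.
#' @param axial_spec,sagittal_spec [network_spec()]s.
#' @param val_patients patient ids held out for validation.
#' @param target_mm,crop_mm working resolution and crop side.
#' @param axial_slice_stride take every n-th axial slice of each training
#'   scan for axial training (validation and inference always use all
#'   slices); > 1 scales training cost down.
#' @param seed integer seed (network init).
#' @param verbose print progress.
#' @return List: `metrics` (per validation scan: Dice of axial-only and
#'   combined output), `axial` and `sagittal` training results, configs.
#' @export
run_cascade_experiment <- function(cohort, axial_cfg, sagittal_cfg,
                                   axial_spec, sagittal_spec, val_patients,
                                   target_mm = 0.5, crop_mm = 32,
                                   axial_slice_stride = 1L, seed = 1L,
                                   verbose = FALSE) {
  pids <- vapply(cohort, `[[`, "", "patient_id")
  is_val <- pids %in% val_patients
  if (!any(is_val) || all(is_val)) stop("validation split is degenerate")

  ax_items <- lapply(cohort, function(e) {
    axial_items_for_scan(e$phantom, target_mm, crop_mm)$items
  })
  take_stride <- function(l) l[seq(1L, length(l), by = axial_slice_stride)]
  ax_data <- list(train = do.call(c, lapply(ax_items[!is_val], take_stride)),
                  val = do.call(c, ax_items[is_val]))
  axial_net <- build_network(axial_spec, seed = derive_seed(seed, 11L))
  ax_res <- train_stage(axial_cfg, ax_data, axial_net, verbose = verbose)

  size <- sagittal_spec$input_size
  sg_items <- lapply(cohort, function(e) {
    sagittal_items_for_scan(e$phantom, ax_res$net, size, target_mm, crop_mm)
  })
  keep_xy <- function(l) lapply(l, function(it) list(x = it$x, y = it$y))
  sg_train <- filter_sagittal_slices(do.call(c, sg_items[!is_val]))
  if (length(sg_train) == 0L) stop("axial network segmented no training slice")
  sg_data <- list(train = keep_xy(sg_train),
                  val = keep_xy(do.call(c, sg_items[is_val])))
  sagittal_net <- build_network(sagittal_spec, seed = derive_seed(seed, 13L))
  sg_res <- train_stage(sagittal_cfg, sg_data, sagittal_net,
                        verbose = verbose)

  metrics <- do.call(rbind, lapply(which(is_val), function(i) {
    e <- cohort[[i]]
    res <- infer_cascade(e$phantom$image, ax_res$net, sg_res$net,
                         oracle_centerline(e$phantom), target_mm, crop_mm,
                         return_stages = TRUE)
    data.frame(scan_id = e$scan_id,
               dice_axial = dice(res$axial_mask, e$phantom$cord_mask),
               dice_combined = dice(res$mask, e$phantom$cord_mask),
               stringsAsFactors = FALSE)
  }))
  list(metrics = metrics, axial = ax_res, sagittal = sg_res,
       axial_cfg = axial_cfg, sagittal_cfg = sagittal_cfg)
}

#' Settings for the scaled desk-top cascade experiment
#'
#' A fixed, deliberately small configuration exercising the full two-stage
#' pipeline on commodity hardware: a 12-phantom cohort (one scan per
#' patient, 48 x 96 sagittal in-plane grid, 6 slices, one traumatic lesion
#' per cord at 80 percent contrast loss), a 64 x 64 axial and a 96 x 96
#' sagittal network with 4 and 8 base feature maps, 10 and 25 training
#' epochs. Learning rates, dropout and the output-bias prior are scaled to
#' the short schedules; the full-size protocol defaults remain those of
#' [train_config()] and [network_spec()].
#'
#' @param seed integer seed controlling training stochasticity (the cohort
#'   itself is pinned to its own seed so the anatomy is the study
#'   condition, not a variable).
#' @return List of arguments for [generate_cohort()] and
#'   [run_cascade_experiment()].
#' @export
scaled_experiment_settings <- function(seed = 1L) {
  list(
    cohort = list(
      n_patients = 12L, seed = 42L,
      spec_args = list(in_plane_shape = c(48L, 96L),
                       n_sagittal_slices = 6L,
                       sagittal_spacing_mm = 0.7,
                       slice_thickness_mm = 3.0, slice_gap_mm = 3.5,
                       cord_radius_mm = 4.5, curvature_amplitude_mm = 8,
                       n_lesions = 1L, lesion_contrast_loss = 0.8,
                       noise_sigma = 0.02)
    ),
    axial_cfg = train_config("axial", epochs = 10L, lr = 2e-3, seed = seed),
    # the 96-canvas inputs are a quarter of the full working size, so the
    # sagittal elastic policy scales down by the same factor
    sagittal_cfg = train_config("sagittal", epochs = 25L, lr = 1e-3,
                                batch_size = 1L, seed = seed,
                                augment = augment_policy(
                                  "sagittal", elastic_range = c(-12, 12),
                                  elastic_sigma = 24,
                                  rng_seed = derive_seed(seed, 99L))),
    axial_spec = network_spec(1L, 64L, base_features = 4L, dropout_p = 0.1,
                              output_bias = -1),
    sagittal_spec = network_spec(2L, 96L, base_features = 8L,
                                 dropout_p = 0.1, output_bias = -1),
    val_patients = c("P0010", "P0011", "P0012"),
    axial_slice_stride = 2L,
    seed = seed
  )
}

#' Run the scaled cascade experiment
#'
#' Convenience wrapper: generates (or reuses) the pinned phantom cohort and
#' calls [run_cascade_experiment()] with [scaled_experiment_settings()].
#'
#' @param seed training seed.
#' @param cohort optionally a pre-generated cohort (to amortize generation
#'   across seeds).
#' @param verbose print progress.
#' @return See [run_cascade_experiment()]; additionally `elapsed_min`.
#' @export
run_scaled_experiment <- function(seed = 1L, cohort = NULL,
                                  verbose = FALSE) {
  st <- scaled_experiment_settings(seed)
  if (is.null(cohort)) cohort <- do.call(generate_cohort, st$cohort)
  t0 <- Sys.time()
  res <- run_cascade_experiment(cohort, st$axial_cfg, st$sagittal_cfg,
                                st$axial_spec, st$sagittal_spec,
                                st$val_patients,
                                axial_slice_stride = st$axial_slice_stride,
                                seed = seed, verbose = verbose)
  res$elapsed_min <- as.numeric(Sys.time() - t0, units = "mins")
  res
}
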