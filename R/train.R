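# Dice-loss training with Adam. One configuration object per cascade stage;
# per-epoch datasets come from the augmentation module (originals + renewed
# augmented copies), iteration count per epoch is floor(n / batch) with the
# last partial batch dropped.

#' Training configuration for one cascade stage
#'
#' Protocol defaults: axial stage batch 4, 50 epochs, augmented copies
#' renewed every epoch; sagittal stage batch 2, 125 epochs, renewal every 10
#' epochs. Both use Dice loss and Adam with learning rate 5e-5 and betas
#' (0.5, 0.999).
#'
#' @param stage `"axial"` or `"sagittal"`.
#' @param batch_size,epochs,lr,adam_betas optimizer settings.
#' @param augment an [augment_policy()] (defaults to the stage's policy).
#' @param seed integer seed for shuffling, dropout and augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(stage = c("axial", "sagittal"),
                         batch_size = NULL, epochs = NULL, lr = 5e-5,
                         adam_betas = c(0.5, 0.999), augment = NULL,
                         seed = 1L) {
  stage <- match.arg(stage)
  cfg <- list(
    stage = stage,
    batch_size = if (is.null(batch_size)) {
      if (stage == "axial") 4L else 2L
    } else as.integer(batch_size),
    epochs = if (is.null(epochs)) {
      if (stage == "axial") 50L else 125L
    } else as.integer(epochs),
    lr = lr,
    adam_betas = adam_betas,
    loss = "dice",
    augment = if (is.null(augment)) {
      augment_policy(stage, rng_seed = derive_seed(seed, 99L))
    } else augment,
    seed = as.integer(seed)
  )
  if (cfg$batch_size < 1L || cfg$epochs < 1L) stop("invalid schedule")
  if (cfg$lr <= 0) stop("`lr` must be positive")
  if (any(cfg$adam_betas <= 0) || any(cfg$adam_betas >= 1)) {
    stop("Adam betas must lie in (0, 1)")
  }
  class(cfg) <- "train_config"
  cfg
}

#' Optimizer steps executed by a schedule
#'
#' `floor(n_items / batch_size)` iterations per epoch (the last partial
#' batch is dropped) times the number of epochs.
#'
#' @param n_items epoch dataset size (after augmentation doubling).
#' @param batch_size,epochs schedule.
#' @return Integer step count.
#' @export
optimizer_steps <- function(n_items, batch_size, epochs) {
  as.integer(floor(n_items / batch_size)) * as.integer(epochs)
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * g) + eps) / (sum(p^2) + sum(g^2) + eps)` with
#' `eps = 1e-6`, computed per sample and averaged when given a list of
#' sample pairs.
#'
#' @param pred probability grid in `[0, 1]`, or list of grids.
#' @param target binary grid of the same shape, or list.
#' @param eps numerical smoothing term.
#' @return The loss (scalar).
#' @export
dice_loss <- function(pred, target, eps = 1e-6) {
  if (is.list(pred)) {
    return(mean(mapply(dice_loss, pred, target, MoreArgs = list(eps = eps))))
  }
  if (!identical(dim(pred), dim(target)) &&
      length(pred) != length(target)) {
    stop("pred/target shape mismatch")
  }
  1 - (2 * sum(pred * target) + eps) / (sum(pred^2) + sum(target^2) + eps)
}

# dL/dpred for the soft Dice loss of a single sample.
dice_loss_grad <- function(pred, target, eps = 1e-6) {
  num <- 2 * sum(pred * target) + eps
  den <- sum(pred^2) + sum(target^2) + eps
  -(2 * target * den - num * 2 * pred) / den^2
}

adam_init <- function(params) {
  flat <- list()
  walk <- function(p, prefix) {
    if (is.list(p) && !is.null(p$w)) {
      flat[[paste0(prefix, ".w")]] <<- array(0, dim(p$w) %||% length(p$w))
      flat[[paste0(prefix, ".b")]] <<- numeric(length(p$b))
    } else if (is.list(p)) {
      for (nm in names(p)) walk(p[[nm]], paste0(prefix, ".", nm))
    }
  }
  for (nm in names(params)) walk(params[[nm]], nm)
  list(m = flat, v = lapply(flat, function(x) x), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam update; params and grads share the same nesting.
adam_step <- function(params, grads, state, lr, betas, eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  upd <- function(p, g, prefix) {
    if (is.list(p) && !is.null(p$w)) {
      for (f in c("w", "b")) {
        key <- paste0(prefix, ".", f)
        state$m[[key]] <<- b1 * state$m[[key]] + (1 - b1) * g[[f]]
        state$v[[key]] <<- b2 * state$v[[key]] + (1 - b2) * g[[f]]^2
        mh <- state$m[[key]] / corr1
        vh <- state$v[[key]] / corr2
        p[[f]] <- p[[f]] - lr * mh / (sqrt(vh) + eps)
      }
      p
    } else if (is.list(p)) {
      for (nm in names(p)) p[[nm]] <- upd(p[[nm]], g[[nm]],
                                          paste0(prefix, ".", nm))
      p
    } else p
  }
  for (nm in names(grads)) params[[nm]] <- upd(params[[nm]], grads[[nm]], nm)
  list(params = params, state = state)
}

# element-wise sum of two grad trees
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.list(b[[nm]]) && is.null(b[[nm]]$w) &&
                   !is.numeric(b[[nm]])) {
      grads_add(a[[nm]], b[[nm]])
    } else if (is.list(b[[nm]])) {
      list(w = a[[nm]]$w + b[[nm]]$w, b = a[[nm]]$b + b[[nm]]$b)
    } else a[[nm]] + b[[nm]]
  }
  a
}

grads_scale <- function(g, s) {
  rapply(g, function(x) x * s, how = "replace")
}

#' Train one cascade stage
#'
#' Trains for exactly `cfg$epochs` epochs. Each epoch the training dataset
#' is rebuilt per the augmentation policy (originals plus augmented copies,
#' renewed on schedule), shuffled, and consumed in `floor(n / batch)`
#' batches; gradients are averaged within a batch. Per-epoch mean training
#' loss and validation loss (dropout off, never augmented) are recorded,
#' along with the epoch of minimum validation loss. The final-epoch weights
#' are the checkpoint.
#'
#' @param cfg a [train_config()].
#' @param data list with `train` and `val`: lists of items
#'   `list(x = input array, y = target grid)`.
#' @param net a [build_network()] network to train (its spec must match the
#'   items).
#' @param verbose print per-epoch losses.
#' @return List: `net` (trained), `train_loss`, `val_loss` (length
#'   `epochs`), `best_epoch` (minimum validation loss), `steps` (total
#'   optimizer steps executed).
#' @export
train_stage <- function(cfg, data, net, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"), inherits(net, "cc_network"))
  train <- data$train
  if (length(train) == 0L) stop("empty training set")
  val <- data$val %||% list()
  state <- adam_init(net$params)
  train_loss <- numeric(cfg$epochs)
  val_loss <- rep(NA_real_, cfg$epochs)
  steps <- 0L
  ds <- NULL
  for (epoch in seq_len(cfg$epochs)) {
    ds <- with_local_seed(derive_seed(cfg$seed, 1000L + epoch),
                          build_epoch_dataset(train, cfg$augment, epoch, ds))
    items <- ds$items
    n_batches <- floor(length(items) / cfg$batch_size)
    if (n_batches == 0L) stop("batch size exceeds epoch dataset size")
    losses <- numeric(n_batches)
    with_local_seed(derive_seed(cfg$seed, 2000L + epoch), {
      ord <- sample.int(length(items))
      for (bi in seq_len(n_batches)) {
        take <- ord[((bi - 1L) * cfg$batch_size + 1L):(bi * cfg$batch_size)]
        gsum <- NULL
        lsum <- 0
        for (t in take) {
          it <- items[[t]]
          fw <- network_forward(net, it$x, training = TRUE)
          pred <- fw$y[, , 1]
          lsum <- lsum + dice_loss(pred, it$y)
          dy <- array(dice_loss_grad(pred, it$y), dim(fw$y))
          gsum <- grads_add(gsum, network_backward(net, fw, dy))
        }
        losses[bi] <- lsum / cfg$batch_size
        gavg <- grads_scale(gsum, 1 / cfg$batch_size)
        res <- adam_step(net$params, gavg, state, cfg$lr, cfg$adam_betas)
        net$params <- res$params
        state <- res$state
        steps <- steps + 1L
      }
    })
    train_loss[epoch] <- mean(losses)
    if (length(val) > 0L) {
      val_loss[epoch] <- mean(vapply(val, function(it) {
        dice_loss(network_forward(net, it$x)$y[, , 1], it$y)
      }, numeric(1)))
    }
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %s", epoch,
                      train_loss[epoch],
                      ifelse(is.na(val_loss[epoch]), "-",
                             sprintf("%.4f", val_loss[epoch]))))
    }
  }
  best <- if (all(is.na(val_loss))) NA_integer_ else which.min(val_loss)
  list(net = net, train_loss = train_loss, val_loss = val_loss,
       best_epoch = best, steps = steps)
}
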