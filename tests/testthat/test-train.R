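test_that("soft Dice loss matches closed forms", {
  g <- (matrix(runif(400), 20, 20) > 0.6) * 1
  expect_lt(dice_loss(g, g), 1e-4)
  expect_gt(dice_loss(1 - g, g), 1 - 1e-4)

  # pred = 0.5 everywhere, target half ones: 1 - (0.5 N)/(0.75 N) = 1/3
  n <- 100
  target <- matrix(rep(c(1, 0), each = n / 2), n / 10, 10)
  pred <- matrix(0.5, n / 10, 10)
  expect_equal(dice_loss(pred, target), 1 / 3, tolerance = 1e-5)

  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")

  # list form averages per-sample losses
  expect_equal(dice_loss(list(g, 1 - g), list(g, g)),
               mean(c(dice_loss(g, g), dice_loss(1 - g, g))))
})

test_that("dice loss gradient matches finite differences", {
  set.seed(5)
  p <- matrix(runif(64), 8, 8)
  g <- (matrix(runif(64), 8, 8) > 0.5) * 1
  an <- cordcascade:::dice_loss_grad(p, g)
  eps <- 1e-7
  for (i in sample(64, 6)) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    num <- (dice_loss(pp, g) - dice_loss(pm, g)) / (2 * eps)
    expect_equal(an[i], num, tolerance = 1e-4)
  }
})

test_that("schedule arithmetic drops the last partial batch", {
  expect_identical(optimizer_steps(696, 2, 125), 43500L)
  expect_identical(optimizer_steps(7, 2, 10), 30L)
  expect_identical(optimizer_steps(71510, 4, 50), 893850L)
})

test_that("training runs the configured schedule and records its curves", {
  set.seed(8)
  mk <- function(n) lapply(seq_len(n), function(i) {
    y <- matrix(0, 16, 16)
    y[6:10, 6:10] <- 1
    list(x = matrix(y + rnorm(256, 0, 0.2), 16, 16), y = y)
  })
  cfg <- train_config("axial", batch_size = 2L, epochs = 3L, lr = 1e-3,
                      seed = 4L)
  net <- build_network(network_spec(1L, 16L, base_features = 2L,
                                    dropout_p = 0.1), 2L)
  data <- list(train = mk(6), val = mk(2))
  res <- train_stage(cfg, data, net)
  expect_length(res$train_loss, 3L)
  expect_length(res$val_loss, 3L)
  # 6 originals doubled -> 12 items, batch 2 -> 6 steps/epoch
  expect_identical(res$steps, optimizer_steps(12, 2, 3))
  expect_identical(res$best_epoch, which.min(res$val_loss))

  # recorded validation loss is the unaugmented loss of the epoch's weights
  manual <- mean(vapply(data$val, function(it) {
    dice_loss(network_forward(res$net, it$x)$y[, , 1], it$y)
  }, numeric(1)))
  expect_equal(res$val_loss[3], manual, tolerance = 1e-12)

  expect_error(train_stage(cfg, list(train = list()), net), "empty")
})

test_that("training is bit-reproducible under a fixed seed", {
  mk <- function(n) lapply(seq_len(n), function(i) {
    y <- matrix(0, 16, 16); y[4:9, 7:12] <- 1
    list(x = matrix(y + rnorm(256, 0, 0.3), 16, 16), y = y)
  })
  set.seed(10); data <- list(train = mk(4), val = mk(2))
  cfg <- train_config("axial", batch_size = 2L, epochs = 2L, lr = 1e-3,
                      seed = 9L)
  net <- build_network(network_spec(1L, 16L, base_features = 2L), 5L)
  r1 <- train_stage(cfg, data, net)
  r2 <- train_stage(cfg, data, net)
  expect_identical(r1$net$params, r2$net$params)
  expect_identical(r1$train_loss, r2$train_loss)
})

test_that("the network can overfit a handful of axial patches", {
  p <- small_phantom(40L, noise_sigma = 0.01)
  ax <- cordcascade:::axial_items_for_scan(p)
  items <- ax$items[seq(2, 30, by = 4)]   # 8 patches
  cfg <- train_config("axial", batch_size = 4L, epochs = 60L, lr = 3e-3,
                      seed = 2L,
                      augment = augment_policy("axial", double_dataset = FALSE,
                                               rng_seed = 1L))
  net <- build_network(network_spec(1L, 64L, base_features = 4L,
                                    dropout_p = 0, output_bias = -2), 6L)
  res <- train_stage(cfg, list(train = items, val = NULL), net)
  expect_lt(tail(res$train_loss, 1), 0.05)
})
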