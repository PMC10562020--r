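test_that("the network is shape-preserving with sigmoid-range outputs", {
  net <- build_network(network_spec(1L, 64L, base_features = 4L), 1L)
  x <- array(runif(64 * 64), c(64, 64, 1))
  y <- network_forward(net, x)$y
  expect_identical(dim(y), c(64L, 64L, 1L))
  expect_true(all(y > 0 & y < 1))

  # two-channel sagittal variant at full working size
  net2 <- build_network(network_spec(2L, 384L, base_features = 4L), 1L)
  x2 <- array(runif(384 * 384 * 2), c(384, 384, 2))
  y2 <- network_forward(net2, x2)$y
  expect_identical(dim(y2), c(384L, 384L, 1L))

  # gates are shape-preserving: disabling them changes nothing structural
  net3 <- build_network(network_spec(1L, 64L, base_features = 4L,
                                     use_attention = FALSE), 1L)
  y3 <- network_forward(net3, x)$y
  expect_identical(dim(y3), dim(y))

  expect_error(network_spec(1L, 63L), "divisible")
  expect_error(network_forward(net, array(runif(60 * 60), c(60, 60, 1))),
               "divisible")
  expect_error(network_forward(net, array(0, c(64, 64, 3))), "channels")
})

test_that("attention gate: zero weights give coefficients 1/2, output skip/2", {
  skip <- array(runif(16 * 16 * 8), c(16, 16, 8))
  gate <- array(runif(8 * 8 * 16), c(8, 8, 16))
  pars <- withr::with_seed(2L, cordcascade:::attention_params(8L, 16L))
  out <- attention_gate(skip, gate, pars)
  expect_identical(dim(out), dim(skip))
  alpha <- attr(out, "alpha")
  expect_true(all(alpha > 0 & alpha < 1))

  zero <- lapply(pars, function(q) {
    q$w <- q$w * 0; q$b <- q$b * 0; q
  })
  out0 <- attention_gate(skip, gate, zero)
  expect_equal(attr(out0, "alpha")[, , 1], matrix(0.5, 16, 16))
  expect_equal(as.numeric(out0), as.numeric(skip / 2), tolerance = 1e-12)

  expect_error(attention_gate(skip, array(0, c(5, 5, 16)), pars),
               "half the skip resolution")
})

test_that("forward passes are deterministic; dropout is seed-reproducible", {
  net <- build_network(network_spec(1L, 32L, base_features = 4L), 7L)
  x <- array(runif(32 * 32), c(32, 32, 1))
  expect_identical(network_forward(net, x)$y, network_forward(net, x)$y)
  y1 <- withr::with_seed(1L, network_forward(net, x, training = TRUE)$y)
  y2 <- withr::with_seed(1L, network_forward(net, x, training = TRUE)$y)
  expect_identical(y1, y2)
})

test_that("the slimmed architecture has far fewer parameters than 4-level U-Net", {
  net <- build_network(network_spec(1L, 64L, base_features = 32L), 1L)
  n_axial <- count_parameters(net)

  # closed-form parameter count of the reference: 4 poolings, 64 base
  # features, plain skips, two 3x3 convs per level, 2x2 transposed-conv
  # upsampling, 1x1 output head
  conv_p <- function(cin, cout) 9 * cin * cout + cout
  up_p <- function(cin, cout) 4 * cin * cout + cout
  enc <- conv_p(1, 64) + conv_p(64, 64) +
    conv_p(64, 128) + conv_p(128, 128) +
    conv_p(128, 256) + conv_p(256, 256) +
    conv_p(256, 512) + conv_p(512, 512) +
    conv_p(512, 1024) + conv_p(1024, 1024)
  dec <- up_p(1024, 512) + conv_p(1024, 512) + conv_p(512, 512) +
    up_p(512, 256) + conv_p(512, 256) + conv_p(256, 256) +
    up_p(256, 128) + conv_p(256, 128) + conv_p(128, 128) +
    up_p(128, 64) + conv_p(128, 64) + conv_p(64, 64)
  ref <- enc + dec + (64 * 1 + 1)
  expect_lt(n_axial, ref)
  expect_lt(n_axial, ref / 4)   # the reduction is drastic, not marginal
})

test_that("analytic gradients match finite differences on a tiny network", {
  spec <- network_spec(2L, 8L, base_features = 2L, dropout_p = 0,
                       use_attention = TRUE)
  net <- build_network(spec, 3L)
  set.seed(1)
  x <- array(runif(8 * 8 * 2), c(8, 8, 2))
  y <- (array(runif(8 * 8), c(8, 8)) > 0.5) * 1

  fw <- network_forward(net, x, training = TRUE)
  dy <- array(cordcascade:::dice_loss_grad(fw$y[, , 1], y), dim(fw$y))
  g <- cordcascade:::network_backward(net, fw, dy)

  getp <- function(l, path) { for (p in path) l <- l[[p]]; l }
  setp <- function(l, path, val) {
    if (length(path) == 1) { l[[path]] <- val; return(l) }
    l[[path[1]]] <- setp(l[[path[1]]], path[-1], val)
    l
  }
  paths <- list(c("e1a", "w"), c("e2b", "w"), c("bta", "w"), c("u3", "w"),
                c("d2a", "w"), c("out", "w"), c("out", "b"),
                c("a3", "theta", "w"), c("a1", "psi", "b"),
                c("a2", "phi", "w"))
  eps <- 1e-6
  for (path in paths) {
    arr <- getp(net$params, path)
    for (probe in 1:2) {
      i <- sample(length(arr), 1)
      f <- function(d) {
        n2 <- net
        a <- getp(n2$params, path)
        a[i] <- a[i] + d
        n2$params <- setp(n2$params, path, a)
        dice_loss(network_forward(n2, x)$y[, , 1], y)
      }
      num <- (f(eps) - f(-eps)) / (2 * eps)
      ana <- getp(g, path)[i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
    }
  }
})
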