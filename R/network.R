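# Attention-gated U-Net shared by both planes: 3 contracting/expanding
# levels, 32 initial feature maps doubling per level, 3x3 zero-padded
# convolutions each followed by ReLU and dropout, 2x2 max pooling, 2x2
# stride-2 transposed-convolution upsampling, additive attention gates on the
# skip connections, 1x1 output convolution and sigmoid. Forward and backward
# passes are explicit; tensors are (H, W, C) arrays.

#' Network specification
#'
#' @param in_channels input channels (axial 1, sagittal 2).
#' @param input_size square input side; must be divisible by `2^depth`.
#' @param base_features feature maps after the first convolution (default
#'   32); channels double at each level.
#' @param depth number of pooling steps; this architecture is defined for
#'   depth 3 (feature-map sides input/1, /2, /4, /8).
#' @param dropout_p dropout probability after each ReLU in the conv blocks.
#' @param use_attention gate the skip connections (default TRUE).
#' @param output_bias initial bias of the final 1x1 convolution (logit
#'   scale). Zero (the default) starts the sigmoid output at 0.5
#'   everywhere; setting it to the logit of the expected foreground
#'   fraction stabilizes early Dice-loss optimization on short schedules.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(in_channels = 1L, input_size = 64L,
                         base_features = 32L, depth = 3L, dropout_p = 0.4,
                         use_attention = TRUE, output_bias = 0) {
  if (depth != 3L) stop("this architecture is defined for depth 3")
  if (input_size %% 2^depth != 0) {
    stop("`input_size` must be divisible by 2^depth")
  }
  if (dropout_p < 0 || dropout_p >= 1) stop("`dropout_p` must be in [0, 1)")
  structure(list(in_channels = as.integer(in_channels),
                 input_size = as.integer(input_size),
                 base_features = as.integer(base_features),
                 depth = as.integer(depth),
                 dropout_p = dropout_p,
                 use_attention = isTRUE(use_attention),
                 output_bias = output_bias),
            class = "network_spec")
}

kaiming_mat <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

conv_par <- function(k, cin, cout) {
  list(w = kaiming_mat(k * k * cin, cout, k * k * cin),
       b = numeric(cout), k = k, pad = (k - 1L) %/% 2L,
       cin = cin, cout = cout)
}

convt_par <- function(cin, cout) {
  list(w = kaiming_mat(4L * cin, cout, cin), b = numeric(cout),
       cin = cin, cout = cout)
}

#' Attention-gate parameters
#'
#' 1x1 projections for an additive attention gate: `theta` maps the skip
#' tensor and `phi` the (coarser) gating signal to `inter` channels
#' (`skip_channels / 2` by default), `psi` maps their rectified sum to one
#' coefficient channel.
#'
#' @param skip_channels,gate_channels channel counts of the two inputs.
#' @return List of three 1x1 convolution parameter sets.
#' @export
attention_params <- function(skip_channels, gate_channels) {
  inter <- max(1L, skip_channels %/% 2L)
  list(theta = conv_par(1L, skip_channels, inter),
       phi = conv_par(1L, gate_channels, inter),
       psi = conv_par(1L, inter, 1L))
}

#' Build an attention-gated U-Net
#'
#' Weights use Kaiming fan-in initialization with a fixed seed; biases start
#' at zero.
#'
#' @param spec a [network_spec()].
#' @param seed integer initialization seed.
#' @return An object of class `cc_network` (spec + named parameter list).
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  F <- spec$base_features
  with_local_seed(seed, {
    p <- list(
      e1a = conv_par(3L, spec$in_channels, F), e1b = conv_par(3L, F, F),
      e2a = conv_par(3L, F, 2L * F), e2b = conv_par(3L, 2L * F, 2L * F),
      e3a = conv_par(3L, 2L * F, 4L * F), e3b = conv_par(3L, 4L * F, 4L * F),
      bta = conv_par(3L, 4L * F, 8L * F), btb = conv_par(3L, 8L * F, 8L * F),
      u3 = convt_par(8L * F, 4L * F),
      d3a = conv_par(3L, 8L * F, 4L * F), d3b = conv_par(3L, 4L * F, 4L * F),
      u2 = convt_par(4L * F, 2L * F),
      d2a = conv_par(3L, 4L * F, 2L * F), d2b = conv_par(3L, 2L * F, 2L * F),
      u1 = convt_par(2L * F, F),
      d1a = conv_par(3L, 2L * F, F), d1b = conv_par(3L, F, F),
      out = conv_par(1L, F, 1L)
    )
    p$out$b[] <- spec$output_bias
    if (spec$use_attention) {
      p$a3 <- attention_params(4L * F, 8L * F)
      p$a2 <- attention_params(2L * F, 4L * F)
      p$a1 <- attention_params(F, 2L * F)
    }
    structure(list(spec = spec, params = p, seed = as.integer(seed)),
              class = "cc_network")
  })
}

#' Number of trainable parameters
#'
#' @param net a [build_network()] result.
#' @return Integer parameter count.
#' @export
count_parameters <- function(net) {
  n <- 0L
  walk <- function(p) {
    if (is.list(p) && !is.null(p$w)) n <<- n + length(p$w) + length(p$b)
    else if (is.list(p)) lapply(p, walk)
    invisible(NULL)
  }
  walk(net$params)
  n
}

as_hwc <- function(x, c_expect) {
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  if (dim(x)[3] != c_expect) {
    stop("input has ", dim(x)[3], " channels, expected ", c_expect)
  }
  x
}

# ---- layer forward/backward pairs (caches carried explicitly) ----

block_fwd <- function(x, pa, pb, drop, training) {
  za <- cc_conv2d_fwd(x, pa$w, pa$b, pa$k, pa$pad)
  ra <- pmax(za, 0)
  ma <- NULL
  ya <- ra
  if (training && drop > 0) {
    ma <- array((runif(length(ra)) >= drop) / (1 - drop), dim(ra))
    ya <- ra * ma
  }
  zb <- cc_conv2d_fwd(ya, pb$w, pb$b, pb$k, pb$pad)
  rb <- pmax(zb, 0)
  mb <- NULL
  yb <- rb
  if (training && drop > 0) {
    mb <- array((runif(length(rb)) >= drop) / (1 - drop), dim(rb))
    yb <- rb * mb
  }
  list(y = yb, cache = list(x = x, ra = ra, ma = ma, ya = ya, rb = rb,
                            mb = mb))
}

block_bwd <- function(dy, cache, pa, pb) {
  if (!is.null(cache$mb)) dy <- dy * cache$mb
  dzb <- dy * (cache$rb > 0)
  gb <- cc_conv2d_bwd(cache$ya, pb$w, dzb, pb$k, pb$pad)
  da <- gb$dx
  if (!is.null(cache$ma)) da <- da * cache$ma
  dza <- da * (cache$ra > 0)
  ga <- cc_conv2d_bwd(cache$x, pa$w, dza, pa$k, pa$pad)
  list(dx = ga$dx,
       grads = list(a = list(w = ga$dw, b = ga$db),
                    b = list(w = gb$dw, b = gb$db)))
}

gate_fwd <- function(skip, gate, pg) {
  tx <- cc_conv2d_fwd(skip, pg$theta$w, pg$theta$b, 1L, 0L)
  pc <- cc_conv2d_fwd(gate, pg$phi$w, pg$phi$b, 1L, 0L)
  pu <- cc_upsample2_fwd(pc)
  s <- tx + pu
  a <- pmax(s, 0)
  psi <- cc_conv2d_fwd(a, pg$psi$w, pg$psi$b, 1L, 0L)
  alpha <- 1 / (1 + exp(-psi))
  y <- skip * as.vector(alpha)
  list(y = y, alpha = alpha,
       cache = list(skip = skip, gate = gate, s = s, a = a, alpha = alpha))
}

gate_bwd <- function(dy, cache, pg) {
  ca <- cache
  H <- dim(ca$skip)[1]; W <- dim(ca$skip)[2]; Cs <- dim(ca$skip)[3]
  dskip <- dy * as.vector(ca$alpha)
  dalpha <- array(rowSums(matrix(dy * ca$skip, H * W, Cs)), c(H, W, 1L))
  dpsi <- dalpha * ca$alpha * (1 - ca$alpha)
  gpsi <- cc_conv2d_bwd(ca$a, pg$psi$w, dpsi, 1L, 0L)
  ds <- gpsi$dx * (ca$s > 0)
  gtheta <- cc_conv2d_bwd(ca$skip, pg$theta$w, ds, 1L, 0L)
  dpc <- cc_upsample2_bwd(ds)
  gphi <- cc_conv2d_bwd(ca$gate, pg$phi$w, dpc, 1L, 0L)
  list(dskip = dskip + gtheta$dx, dgate = gphi$dx,
       grads = list(theta = list(w = gtheta$dw, b = gtheta$db),
                    phi = list(w = gphi$dw, b = gphi$db),
                    psi = list(w = gpsi$dw, b = gpsi$db)))
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

#' Apply an additive attention gate
#'
#' 1x1 projections of the skip tensor and the (upsampled) coarser gating
#' signal are summed, rectified, projected to one channel, squashed to
#' (0, 1) coefficients, and multiplied element-wise into the skip tensor.
#' With all projection weights and biases zero the coefficients are exactly
#' 0.5 everywhere and the output is `skip / 2`.
#'
#' @param skip feature tensor `H x W x Cs`.
#' @param gate_signal feature tensor `H/2 x W/2 x Cg`.
#' @param params gate parameters ([attention_params()]).
#' @return Gated tensor of the same shape as `skip`, with the coefficient
#'   field attached as attribute `"alpha"`.
#' @export
attention_gate <- function(skip, gate_signal, params) {
  if (any(dim(gate_signal)[1:2] * 2L != dim(skip)[1:2])) {
    stop("gate signal must be at half the skip resolution")
  }
  f <- gate_fwd(skip, gate_signal, params)
  structure(f$y, alpha = f$alpha)
}

#' Forward pass of the network
#'
#' @param net a [build_network()] result.
#' @param x input array `H x W x C` (or 2-D grid for one channel).
#' @param training enable dropout (uses R's RNG) and keep caches for
#'   [network_backward()].
#' @return List with `y` (output `H x W x 1`, values in (0, 1)) and, when
#'   `training`, `cache`.
#' @export
network_forward <- function(net, x, training = FALSE) {
  sp <- net$spec
  p <- net$params
  x <- as_hwc(x, sp$in_channels)
  if (dim(x)[1] %% 8L != 0 || dim(x)[2] %% 8L != 0) {
    stop("input sides must be divisible by 2^depth")
  }
  drop <- sp$dropout_p
  att <- sp$use_attention

  c1 <- block_fwd(x, p$e1a, p$e1b, drop, training)
  pl1 <- cc_maxpool2_fwd(c1$y)
  c2 <- block_fwd(pl1$y, p$e2a, p$e2b, drop, training)
  pl2 <- cc_maxpool2_fwd(c2$y)
  c3 <- block_fwd(pl2$y, p$e3a, p$e3b, drop, training)
  pl3 <- cc_maxpool2_fwd(c3$y)
  bt <- block_fwd(pl3$y, p$bta, p$btb, drop, training)

  u3 <- cc_convt2_fwd(bt$y, p$u3$w, p$u3$b)
  g3 <- if (att) gate_fwd(c3$y, bt$y, p$a3) else list(y = c3$y)
  d3 <- block_fwd(concat_c(u3, g3$y), p$d3a, p$d3b, drop, training)

  u2 <- cc_convt2_fwd(d3$y, p$u2$w, p$u2$b)
  g2 <- if (att) gate_fwd(c2$y, d3$y, p$a2) else list(y = c2$y)
  d2 <- block_fwd(concat_c(u2, g2$y), p$d2a, p$d2b, drop, training)

  u1 <- cc_convt2_fwd(d2$y, p$u1$w, p$u1$b)
  g1 <- if (att) gate_fwd(c1$y, d2$y, p$a1) else list(y = c1$y)
  d1 <- block_fwd(concat_c(u1, g1$y), p$d1a, p$d1b, drop, training)

  z <- cc_conv2d_fwd(d1$y, p$out$w, p$out$b, 1L, 0L)
  y <- 1 / (1 + exp(-z))
  if (!training) return(list(y = y))
  list(y = y,
       cache = list(x = x, c1 = c1, pl1 = pl1, c2 = c2, pl2 = pl2, c3 = c3,
                    pl3 = pl3, bt = bt, u3_in = bt$y, g3 = g3, d3 = d3,
                    u2_in = d3$y, g2 = g2, d2 = d2, u1_in = d2$y, g1 = g1,
                    d1 = d1, d1y = d1$y, y = y))
}

# Gradient of every parameter given dL/dy (y = sigmoid output).
network_backward <- function(net, fw, dy) {
  sp <- net$spec
  p <- net$params
  att <- sp$use_attention
  ca <- fw$cache
  g <- list()

  dz <- dy * ca$y * (1 - ca$y)
  go <- cc_conv2d_bwd(ca$d1y, p$out$w, dz, 1L, 0L)
  g$out <- list(w = go$dw, b = go$db)

  b1 <- block_bwd(go$dx, ca$d1$cache, p$d1a, p$d1b)
  g$d1a <- b1$grads$a; g$d1b <- b1$grads$b
  F <- sp$base_features
  du1 <- b1$dx[, , seq_len(F), drop = FALSE]
  dg1 <- b1$dx[, , F + seq_len(F), drop = FALSE]
  gu1 <- cc_convt2_bwd(ca$u1_in, p$u1$w, du1)
  g$u1 <- list(w = gu1$dw, b = gu1$db)
  if (att) {
    a1 <- gate_bwd(dg1, ca$g1$cache, p$a1)
    g$a1 <- a1$grads
    dc1 <- a1$dskip
    dd2y <- gu1$dx + a1$dgate
  } else {
    dc1 <- dg1
    dd2y <- gu1$dx
  }

  b2 <- block_bwd(dd2y, ca$d2$cache, p$d2a, p$d2b)
  g$d2a <- b2$grads$a; g$d2b <- b2$grads$b
  du2 <- b2$dx[, , seq_len(2L * F), drop = FALSE]
  dg2 <- b2$dx[, , 2L * F + seq_len(2L * F), drop = FALSE]
  gu2 <- cc_convt2_bwd(ca$u2_in, p$u2$w, du2)
  g$u2 <- list(w = gu2$dw, b = gu2$db)
  if (att) {
    a2 <- gate_bwd(dg2, ca$g2$cache, p$a2)
    g$a2 <- a2$grads
    dc2 <- a2$dskip
    dd3y <- gu2$dx + a2$dgate
  } else {
    dc2 <- dg2
    dd3y <- gu2$dx
  }

  b3 <- block_bwd(dd3y, ca$d3$cache, p$d3a, p$d3b)
  g$d3a <- b3$grads$a; g$d3b <- b3$grads$b
  du3 <- b3$dx[, , seq_len(4L * F), drop = FALSE]
  dg3 <- b3$dx[, , 4L * F + seq_len(4L * F), drop = FALSE]
  gu3 <- cc_convt2_bwd(ca$u3_in, p$u3$w, du3)
  g$u3 <- list(w = gu3$dw, b = gu3$db)
  if (att) {
    a3 <- gate_bwd(dg3, ca$g3$cache, p$a3)
    g$a3 <- a3$grads
    dc3 <- a3$dskip
    dbty <- gu3$dx + a3$dgate
  } else {
    dc3 <- dg3
    dbty <- gu3$dx
  }

  bb <- block_bwd(dbty, ca$bt$cache, p$bta, p$btb)
  g$bta <- bb$grads$a; g$btb <- bb$grads$b
  dp3 <- cc_maxpool2_bwd(bb$dx, ca$pl3$arg)
  b3e <- block_bwd(dp3 + dc3, ca$c3$cache, p$e3a, p$e3b)
  g$e3a <- b3e$grads$a; g$e3b <- b3e$grads$b
  dp2 <- cc_maxpool2_bwd(b3e$dx, ca$pl2$arg)
  b2e <- block_bwd(dp2 + dc2, ca$c2$cache, p$e2a, p$e2b)
  g$e2a <- b2e$grads$a; g$e2b <- b2e$grads$b
  dp1 <- cc_maxpool2_bwd(b2e$dx, ca$pl1$arg)
  b1e <- block_bwd(dp1 + dc1, ca$c1$cache, p$e1a, p$e1b)
  g$e1a <- b1e$grads$a; g$e1b <- b1e$grads$b
  g
}

#' Save / load a network checkpoint
#'
#' Checkpoints carry the weights together with their [network_spec()], the
#' initialization seed and an optional epoch tag.
#'
#' @param net a [build_network()] (possibly trained) network.
#' @param path checkpoint path (`.rds`).
#' @param epoch optional epoch annotation.
#' @return `path` (save) or the network with `$epoch` set (load).
#' @export
save_checkpoint <- function(net, path, epoch = NA_integer_) {
  stopifnot(inherits(net, "cc_network"))
  net$epoch <- as.integer(epoch)
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "cc_network")) stop("not a network checkpoint: ", path)
  net
}
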