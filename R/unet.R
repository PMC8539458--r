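#' A compact fully convolutional U-Net
#'
#' The segmentation network is a plain encoder--decoder with skip
#' connections: `depth` resolution levels, two 3x3 convolutions per level
#' (each followed by per-image instance normalisation and ReLU), 2x2 max
#' pooling between encoder levels, nearest-neighbour 2x
#' upsampling with skip concatenation between decoder levels, and a final
#' 1x1 convolution with a sigmoid producing a soft mask in `[0, 1]`. The
#' number of filters starts at `base_filters` and doubles per level. The
#' network is fully convolutional, so it can be trained on one frame size
#' and applied to another; inputs whose sides are not multiples of
#' `2^(depth - 1)` are symmetrically zero-padded and the output cropped
#' back.
#'
#' Weights use He-scaled Gaussian initialisation. Forward and backward
#' passes run per image (gradients are accumulated across a batch by the
#' training loop).
#'
#' @param depth number of resolution levels (the default, 5, spans a factor
#'   16 in resolution).
#' @param base_filters filters in the first level.
#' @param in_channels input image channels.
#' @param head_prior prior foreground probability used to initialise the
#'   output bias (`qlogis(head_prior)`). Matching the initial prediction to
#'   the low foreground fraction of particle masks keeps the early dice
#'   gradients balanced and avoids the saturated all-background minimum.
#' @return `unet_init()` returns a `unet` object holding the parameter
#'   list.
#' @export
unet_init <- function(depth = 5L, base_filters = 16L, in_channels = 1L,
                      head_prior = 0.1) {
  stopifnot(depth >= 2, base_filters >= 1)
  filters <- base_filters * 2^(seq_len(depth) - 1L)
  he_conv <- function(cin, cout) {
    list(w = matrix(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                    9 * cin, cout),
         b = rep(0, cout))
  }
  params <- list(enc = list(), dec = list())
  cin <- in_channels
  for (l in seq_len(depth - 1L)) {
    params$enc[[l]] <- list(conv1 = he_conv(cin, filters[l]),
                            conv2 = he_conv(filters[l], filters[l]))
    cin <- filters[l]
  }
  params$bottleneck <- list(conv1 = he_conv(cin, filters[depth]),
                            conv2 = he_conv(filters[depth], filters[depth]))
  for (l in rev(seq_len(depth - 1L))) {
    cat_ch <- filters[l + 1L] + filters[l]
    params$dec[[l]] <- list(conv1 = he_conv(cat_ch, filters[l]),
                            conv2 = he_conv(filters[l], filters[l]))
  }
  stopifnot(head_prior > 0, head_prior < 1)
  params$head <- list(w = matrix(rnorm(filters[1], 0, sqrt(2 / filters[1])),
                                 filters[1], 1),
                      b = stats::qlogis(head_prior))
  structure(list(params = params, depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 in_channels = as.integer(in_channels)),
            class = "unet")
}

as_cube <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

relu <- function(x) {
  x * (x > 0)
}

sigmoid <- function(x) {
  1 / (1 + exp(-x))
}

# Per-image, per-channel instance normalisation (no learnable affine).
# Keeps feature scales stable so the dice loss trains reliably from its
# heavily class-imbalanced gradients.
instnorm_fw <- function(x, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  sd_ <- sqrt(colMeans(xc^2) + eps)
  y <- sweep(xc, 2, sd_, "/")
  list(y = array(y, d), sd = sd_, y_mat = y)
}

instnorm_bw <- function(cache, g_out) {
  d <- dim(g_out)
  g <- matrix(g_out, d[1] * d[2], d[3])
  y <- cache$y_mat
  gx <- sweep(g, 2, colMeans(g)) - sweep(y, 2, colMeans(g * y), "*")
  array(sweep(gx, 2, cache$sd, "/"), d)
}

conv_block_fw <- function(x, block) {
  h1 <- cpp_conv3x3_fw(x, block$conv1$w, block$conv1$b)
  n1 <- instnorm_fw(h1)
  a1 <- relu(n1$y)
  h2 <- cpp_conv3x3_fw(a1, block$conv2$w, block$conv2$b)
  n2 <- instnorm_fw(h2)
  a2 <- relu(n2$y)
  list(x = x, n1 = n1, a1 = a1, n2 = n2, out = a2)
}

conv_block_bw <- function(cache, block, g_out) {
  g_n2 <- instnorm_bw(cache$n2, g_out * (cache$n2$y > 0))
  b2 <- cpp_conv3x3_bw(cache$a1, block$conv2$w, g_n2)
  g_n1 <- instnorm_bw(cache$n1, b2$gx * (cache$n1$y > 0))
  b1 <- cpp_conv3x3_bw(cache$x, block$conv1$w, g_n1)
  list(gx = b1$gx,
       grads = list(conv1 = list(w = b1$gw, b = b1$gb),
                    conv2 = list(w = b2$gw, b = b2$gb)))
}

# Forward pass on one frame; returns the soft mask and (optionally) every
# intermediate needed for the backward pass.
unet_forward <- function(net, image, keep_cache = FALSE) {
  p <- net$params
  depth <- net$depth
  x <- as_cube(image)
  caches <- list(enc = vector("list", depth - 1L),
                 dec = vector("list", depth - 1L))
  skips <- vector("list", depth - 1L)
  h <- x
  for (l in seq_len(depth - 1L)) {
    cb <- conv_block_fw(h, p$enc[[l]])
    skips[[l]] <- cb$out
    if (keep_cache) caches$enc[[l]] <- cb
    h <- cpp_maxpool2_fw(cb$out)
  }
  cb <- conv_block_fw(h, p$bottleneck)
  if (keep_cache) caches$bottleneck <- cb
  h <- cb$out
  for (l in rev(seq_len(depth - 1L))) {
    up <- cpp_upsample2_fw(h)
    cat_in <- array(c(up, skips[[l]]),
                    dim = c(dim(up)[1:2], dim(up)[3] + dim(skips[[l]])[3]))
    cb <- conv_block_fw(cat_in, p$dec[[l]])
    if (keep_cache) {
      caches$dec[[l]] <- cb
      caches$up_ch[[l]] <- dim(up)[3]
    }
    h <- cb$out
  }
  hw <- dim(h)[1:2]
  logits <- matrix(matrix(h, ncol = dim(h)[3]) %*% p$head$w + p$head$b,
                   hw[1], hw[2])
  soft <- sigmoid(logits)
  if (keep_cache) {
    caches$head_in <- h
    caches$logits <- logits
    caches$soft <- soft
    list(soft = soft, cache = caches)
  } else {
    list(soft = soft)
  }
}

# Backward pass: g_soft is dLoss/dsoft (same shape as the soft mask).
# Returns gradients in the same nested structure as net$params.
unet_backward <- function(net, cache, g_soft) {
  p <- net$params
  depth <- net$depth
  g_logits <- g_soft * cache$soft * (1 - cache$soft)
  h <- cache$head_in
  hw <- dim(h)
  h_mat <- matrix(h, ncol = hw[3])
  g_vec <- as.vector(g_logits)
  grads <- list(head = list(w = crossprod(h_mat, g_vec), b = sum(g_vec)))
  g_h <- array(g_vec %*% t(p$head$w), dim = hw)
  for (l in seq_len(depth - 1L)) {
    bb <- conv_block_bw(cache$dec[[l]], p$dec[[l]], g_h)
    grads$dec[[l]] <- bb$grads
    ch_up <- cache$up_ch[[l]]
    g_up <- bb$gx[, , seq_len(ch_up), drop = FALSE]
    grads$skip[[l]] <- bb$gx[, , -seq_len(ch_up), drop = FALSE]
    g_h <- cpp_upsample2_bw(g_up)
  }
  bb <- conv_block_bw(cache$bottleneck, p$bottleneck, g_h)
  grads$bottleneck <- bb$grads
  g_h <- bb$gx
  for (l in rev(seq_len(depth - 1L))) {
    g_pool <- cpp_maxpool2_bw(cache$enc[[l]]$out, g_h)
    g_enc_out <- g_pool + grads$skip[[l]]
    bb <- conv_block_bw(cache$enc[[l]], p$enc[[l]], g_enc_out)
    grads$enc[[l]] <- bb$grads
    g_h <- bb$gx
  }
  grads$skip <- NULL
  grads
}

#' Dice loss between a soft prediction and a binary target
#'
#' `1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)`. The additive
#' smoothing `eps` keeps the loss finite and its gradient stable when both
#' prediction and target are (near) empty.
#'
#' @param prediction numeric matrix in `[0, 1]`.
#' @param target binary matrix of the same shape.
#' @param eps smoothing constant.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(prediction, target, eps = 1) {
  if (!identical(dim(prediction), dim(target))) {
    stop("prediction and target shapes differ")
  }
  1 - (2 * sum(prediction * target) + eps) /
    (sum(prediction) + sum(target) + eps)
}

# dLoss/dprediction for the dice loss above
dice_loss_grad <- function(prediction, target, eps = 1) {
  num <- 2 * sum(prediction * target) + eps
  den <- sum(prediction) + sum(target) + eps
  (num / den^2) - (2 * target) / den
}

# -- nested parameter-list arithmetic (shared by Adam and the train loop) ---

# Apply f(param_leaf, other_leaf) over matching leaves of two nested lists;
# leaves are matched by name where names exist (gradient lists may carry
# their elements in a different order than the parameter list).
map_params <- function(params, other, f) {
  rec <- function(p, g) {
    if (is.list(p)) {
      keys <- if (!is.null(names(p))) names(p) else seq_along(p)
      for (k in keys) p[[k]] <- rec(p[[k]], g[[k]])
      p
    } else {
      f(p, g)
    }
  }
  rec(params, other)
}

params_add <- function(a, b) {
  map_params(a, b, `+`)
}

params_scale <- function(p, s) {
  rapply(p, function(x) x * s, how = "replace")
}

zero_like <- function(params) {
  params_scale(params, 0)
}

adam_state <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  # walk params, m and v in lockstep (all share the params structure)
  rec <- function(p, m, v) {
    if (is.list(p)) {
      keys <- if (!is.null(names(p))) names(p) else seq_along(p)
      for (k in keys) p[[k]] <- rec(p[[k]], m[[k]], v[[k]])
      p
    } else {
      p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  params <- rec(params, state$m, state$v)
  list(params = params, state = state)
}
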