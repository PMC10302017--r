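# Minimal deterministic neural-network core used by the SR, deblurring and
# denoising stages: im2col-based 2D/3D convolution, transposed convolution,
# pixel shuffle, instance-style batch normalization, leaky ReLU, dense and
# global-pool layers, with exact reverse-mode gradients and - for the
# piecewise-linear critic stacks - exact second-order (double-backprop)
# machinery for the Wasserstein gradient penalty. Tensors are plain R arrays:
# (H, W, C) in 2D, (D, H, W, C) in 3D; one sample per forward pass.

he_init <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))

# ---- layer constructors -----------------------------------------------------

nn_conv2d <- function(in_ch, out_ch, k, stride = 1L, w_scale = 1) {
  K <- k * k * in_ch
  structure(list(type = "conv2d", in_ch = in_ch, out_ch = out_ch, k = k,
                 stride = as.integer(stride),
                 W = matrix(he_init(K, K * out_ch) * w_scale, K, out_ch),
                 b = numeric(out_ch)),
            class = "nn_layer")
}

nn_conv3d <- function(in_ch, out_ch, k, stride = 1L, w_scale = 1) {
  K <- k * k * k * in_ch
  structure(list(type = "conv3d", in_ch = in_ch, out_ch = out_ch, k = k,
                 stride = as.integer(stride),
                 W = matrix(he_init(K, K * out_ch) * w_scale, K, out_ch),
                 b = numeric(out_ch)),
            class = "nn_layer")
}

nn_tconv2d <- function(in_ch, out_ch, k, stride = 1L, w_scale = 1) {
  l <- nn_conv2d(in_ch, out_ch, k, 1L, w_scale)
  l$type <- "tconv2d"; l$up <- as.integer(stride)
  l
}

nn_lrelu <- function(alpha = 0.2)
  structure(list(type = "lrelu", alpha = alpha), class = "nn_layer")

nn_bn <- function(ch, eps = 1e-5)
  structure(list(type = "bn", ch = ch, eps = eps,
                 gamma = rep(1, ch), beta = numeric(ch)), class = "nn_layer")

nn_pixel_shuffle <- function(r)
  structure(list(type = "pixel_shuffle", r = as.integer(r)), class = "nn_layer")

nn_global_pool <- function()
  structure(list(type = "global_pool"), class = "nn_layer")

nn_dense <- function(in_n, out_n, w_scale = 1)
  structure(list(type = "dense",
                 W = matrix(he_init(in_n, in_n * out_n) * w_scale, in_n, out_n),
                 b = numeric(out_n)), class = "nn_layer")

# ---- conv geometry ----------------------------------------------------------

same_pad <- function(n, k, s) {
  out <- as.integer(ceiling(n / s))
  tot <- max((out - 1L) * s + k - n, 0L)
  c(lo = as.integer(tot %/% 2L), hi = as.integer(tot - tot %/% 2L), out = out)
}

pad_array <- function(x, lo, hi) {
  d <- dim(x)
  nd <- length(d) - 1L        # spatial dims; channels last
  dp <- d
  dp[seq_len(nd)] <- d[seq_len(nd)] + lo + hi
  xp <- array(0, dp)
  idx <- lapply(seq_len(nd), function(i) lo[i] + seq_len(d[i]))
  idx <- c(idx, list(seq_len(d[length(d)])))
  do.call(`[<-`, c(list(xp), idx, list(value = x)))
}

expand_grid_int <- function(dims) {
  n <- prod(dims)
  out <- matrix(0L, n, length(dims))
  rep_each <- 1L
  for (i in seq_along(dims)) {
    out[, i] <- rep(rep(seq_len(dims[i]), each = rep_each),
                    length.out = n)
    rep_each <- rep_each * dims[i]
  }
  out
}

conv_geom <- function(l, din) {
  nd <- length(din) - 1L
  p <- lapply(seq_len(nd), function(i) same_pad(din[i], l$k, l$stride))
  lo <- vapply(p, `[[`, 0L, "lo"); hi <- vapply(p, `[[`, 0L, "hi")
  outdim <- vapply(p, `[[`, 0L, "out")
  dp <- din; dp[seq_len(nd)] <- din[seq_len(nd)] + lo + hi
  list(lo = lo, hi = hi, outdim = outdim, dp = dp)
}

# ---- forward ---------------------------------------------------------------

# convolution forward evaluated tap-by-tap in compiled code (memory stays
# O(H*W*C); the per-tap GEMMs run on BLAS)
conv_tap_forward <- function(l, x) {
  din <- dim(x)
  gm <- conv_geom(l, din)
  xp <- pad_array(x, gm$lo, gm$hi)
  y <- conv_forward_cpp(as.vector(xp), as.integer(dim(xp)), l$k, l$stride,
                        as.integer(gm$outdim), l$W, l$b)
  list(y = array(y, c(gm$outdim, l$out_ch)),
       cache = list(xp = xp, gm = gm, din = din))
}

nn_forward <- function(l, x) {
  switch(l$type,
    conv2d = , conv3d = conv_tap_forward(l, x),
    tconv2d = {
      din <- dim(x)
      up <- l$up
      dz <- c(din[1] * up, din[2] * up, din[3])
      xz <- array(0, dz)
      xz[seq(1, dz[1], by = up), seq(1, dz[2], by = up), ] <- x
      inner <- l; inner$type <- "conv2d"; inner$stride <- 1L
      r <- nn_forward(inner, xz)
      r$cache$up <- up; r$cache$din0 <- din
      r
    },
    lrelu = {
      m <- ifelse(x > 0, 1, l$alpha)
      list(y = x * m, cache = list(m = m))
    },
    bn = {
      d <- dim(x)
      sp <- prod(d[-length(d)])
      xm <- matrix(x, sp, d[length(d)])
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      v <- colMeans(xc^2)
      ivar <- 1 / sqrt(v + l$eps)
      xhat <- sweep(xc, 2, ivar, "*")
      y <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
      list(y = array(y, d), cache = list(xhat = xhat, ivar = ivar, d = d, sp = sp))
    },
    pixel_shuffle = {
      d <- dim(x); r <- l$r
      C <- d[3] %/% (r * r)
      # y[r(i-1)+a, r(j-1)+b, c] = x[i, j, ((a-1) + (b-1) r) C + c]
      y <- array(0, c(d[1] * r, d[2] * r, C))
      for (a in seq_len(r)) for (b in seq_len(r)) {
        ch <- ((a - 1) + (b - 1) * r) * C + seq_len(C)
        y[seq(a, d[1] * r, by = r), seq(b, d[2] * r, by = r), ] <- x[, , ch]
      }
      list(y = y, cache = list(d = d, r = r, C = C))
    },
    global_pool = {
      d <- dim(x)
      sp <- prod(d[-length(d)])
      list(y = colMeans(matrix(x, sp, d[length(d)])),
           cache = list(d = d, sp = sp))
    },
    dense = {
      xv <- as.vector(x)
      list(y = as.vector(crossprod(l$W, xv)) + l$b,
           cache = list(xv = xv, d = dim(x) %||% length(x)))
    },
    stop("unknown layer type ", l$type))
}

# ---- backward --------------------------------------------------------------

unpad_array <- function(dxp, lo, hi, din) {
  nd <- length(din) - 1L
  idx <- lapply(seq_len(nd), function(i) lo[i] + seq_len(din[i]))
  idx <- c(idx, list(seq_len(din[length(din)])))
  do.call(`[`, c(list(dxp), idx, list(drop = FALSE)))
}

conv_tap_backward <- function(l, cache, dy) {
  gm <- cache$gm
  npos <- prod(gm$outdim)
  dY <- matrix(dy, npos, l$out_ch)
  r <- conv_backward_cpp(as.vector(cache$xp), as.integer(dim(cache$xp)), l$k,
                         l$stride, as.integer(gm$outdim), l$W, dY)
  dx <- unpad_array(array(r$dxp, dim(cache$xp)), gm$lo, gm$hi, cache$din)
  list(dx = dx, grads = list(W = r$dW, b = r$db), dY = dY)
}

nn_backward <- function(l, cache, dy) {
  switch(l$type,
    conv2d = , conv3d = conv_tap_backward(l, cache, dy),
    tconv2d = {
      inner <- l; inner$type <- "conv2d"; inner$stride <- 1L
      r <- nn_backward(inner, cache, dy)
      up <- cache$up; din0 <- cache$din0
      r$dx <- r$dx[seq(1, dim(r$dx)[1], by = up),
                   seq(1, dim(r$dx)[2], by = up), , drop = FALSE]
      dim(r$dx) <- din0
      r
    },
    lrelu = list(dx = dy * cache$m, grads = NULL),
    bn = {
      d <- cache$d; sp <- cache$sp
      dym <- matrix(dy, sp, d[length(d)])
      dgamma <- colSums(dym * cache$xhat)
      dbeta <- colSums(dym)
      dxhat <- sweep(dym, 2, l$gamma, "*")
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
      dx <- sweep(t1 - t2, 2, cache$ivar, "*")
      list(dx = array(dx, d), grads = list(gamma = dgamma, beta = dbeta))
    },
    pixel_shuffle = {
      d <- cache$d; r <- cache$r; C <- cache$C
      dx <- array(0, d)
      for (a in seq_len(r)) for (b in seq_len(r)) {
        ch <- ((a - 1) + (b - 1) * r) * C + seq_len(C)
        dx[, , ch] <- dy[seq(a, d[1] * r, by = r), seq(b, d[2] * r, by = r), ,
                         drop = FALSE]
      }
      list(dx = dx, grads = NULL)
    },
    global_pool = {
      d <- cache$d
      dx <- array(rep(dy / cache$sp, each = cache$sp), d)
      list(dx = dx, grads = NULL)
    },
    dense = {
      dx <- as.vector(l$W %*% dy)
      dim(dx) <- cache$d
      list(dx = dx, grads = list(W = outer(cache$xv, dy), b = dy), dY = dy)
    },
    stop("unknown layer type ", l$type))
}

# ---- double backprop (gradient-penalty support) -----------------------------
# For a piecewise-linear critic the input gradient g = dD/dx is computed by
# the backward pass; a penalty P(g) then needs dP/dparams. Propagating
# s = dP/d(dx) forward through the (locally linear) backward graph yields
# dP/d(dy) per layer plus the explicit weight contributions. Supported for
# conv2d/conv3d, lrelu, global_pool and dense - the critic building blocks.

nn_grad_grad <- function(l, cache, bw, s_in) {
  switch(l$type,
    conv2d = , conv3d = {
      gm <- cache$gm
      sp <- pad_array(array(s_in, cache$din), gm$lo, gm$hi)
      r <- conv_gradgrad_cpp(as.vector(sp), as.integer(dim(sp)), l$k,
                             l$stride, as.integer(gm$outdim), l$W, bw$dY)
      list(s_out = array(r$s_out, c(gm$outdim, l$out_ch)),
           grads = list(W = r$dW, b = numeric(l$out_ch)))
    },
    lrelu = list(s_out = s_in * cache$m, grads = NULL),
    global_pool = {
      d <- cache$d
      list(s_out = colMeans(matrix(s_in, cache$sp, d[length(d)])) / 1,
           grads = NULL)
    },
    dense = {
      sv <- as.vector(s_in)
      list(s_out = as.vector(crossprod(l$W, sv)),
           grads = list(W = outer(sv, bw$dY), b = numeric(length(l$b))))
    },
    stop("gradient penalty unsupported for layer type ", l$type))
}

# ---- sequential containers --------------------------------------------------

seq_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- nn_forward(layers[[i]], x)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

seq_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  bws <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- nn_backward(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[i] <- list(r$grads)   # keep NULL slots for parameter-free layers
    bws[[i]] <- r["dY"]
  }
  list(dx = dy, grads = grads, bws = bws)
}

seq_grad_grad <- function(layers, caches, bws, s) {
  grads <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- nn_grad_grad(layers[[i]], caches[[i]], bws[[i]], s)
    s <- r$s_out
    grads[i] <- list(r$grads)
  }
  list(s_out = s, grads = grads)
}

# ---- parameter utilities ----------------------------------------------------

layer_params <- function(l) {
  switch(l$type,
    conv2d = , conv3d = , tconv2d = , dense = list(W = l$W, b = l$b),
    bn = list(gamma = l$gamma, beta = l$beta),
    NULL)
}

set_layer_params <- function(l, p) {
  for (nm in names(p)) l[[nm]] <- p[[nm]]
  l
}

net_params <- function(net) lapply(net$layers, layer_params)

net_set_params <- function(net, params) {
  for (i in seq_along(net$layers))
    if (!is.null(params[[i]]))
      net$layers[[i]] <- set_layer_params(net$layers[[i]], params[[i]])
  net
}

net_param_count <- function(net)
  sum(vapply(net_params(net), function(p) sum(vapply(p, length, 0L)), 0))

# elementwise combine two nested grad/param lists
nest_map2 <- function(a, b, f) {
  Map(function(x, y) {
    if (is.null(x)) return(NULL)
    Map(f, x, y)
  }, a, b)
}

nest_scale <- function(a, s) {
  lapply(a, function(x) if (is.null(x)) NULL else lapply(x, function(v) v * s))
}

zero_like <- function(p) lapply(p, function(x)
  if (is.null(x)) NULL else lapply(x, function(v) array(0, dim(v) %||% length(v))))

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) list(m = zero_like(params), v = zero_like(params), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nest_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- nest_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- nest_map2(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- nest_map2(params, upd, `-`)
  list(params = params, state = state)
}
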