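# The four network architectures at configurable (desk-scale) width: the
# super-resolution generator (residual trunk + two sub-pixel upsamplers) and
# its 8-layer critic, the encoder-decoder deblurring generator, the 3D
# denoising GAN pair (conv/deconv stages with short skip connections), and
# the pluggable perceptual feature extractor. Critics use only
# conv/leaky-ReLU/pool/dense so the gradient penalty is exactly
# differentiable.

#' Network specification
#'
#' @param role One of `"sr_gen"`, `"sr_disc"`, `"deblur_gen"`,
#'   `"denoise_gen"`, `"denoise_disc"`, `"feature_extractor"`.
#' @param width_multiplier Channel-width scale (1 = full width, 0.25 = toy).
#' @param upscale_factor Super-resolution factor r (4 = two x2 sub-pixel
#'   stages; other values require `allow_nonstandard`).
#' @param input_shape Expected input dimensions (informational).
#' @param seed Integer seed: identical specs build identical initial
#'   parameters.
#' @param n_resblocks Residual blocks in the SR generator trunk.
#' @param residual_upsample,residual_skip Global residual connections
#'   (output = learned correction around a fixed upsample / the input), on by
#'   default so freshly initialized generators start near the identity.
#' @param n_layers Conv blocks in the feature extractor.
#' @param allow_nonstandard Permit `upscale_factor != 4`.
#' @return A `net_spec` list.
#' @export
net_spec <- function(role = c("sr_gen", "sr_disc", "deblur_gen", "denoise_gen",
                              "denoise_disc", "feature_extractor"),
                     width_multiplier = 1, upscale_factor = 4L,
                     input_shape = NULL, seed = 1L, n_resblocks = 8L,
                     residual_upsample = TRUE, residual_skip = TRUE,
                     n_layers = 4L, allow_nonstandard = FALSE) {
  role <- match.arg(role)
  structure(list(role = role, width_multiplier = width_multiplier,
                 upscale_factor = as.integer(upscale_factor),
                 input_shape = input_shape, seed = as.integer(seed),
                 n_resblocks = as.integer(n_resblocks),
                 residual_upsample = isTRUE(residual_upsample),
                 residual_skip = isTRUE(residual_skip),
                 n_layers = as.integer(n_layers),
                 allow_nonstandard = isTRUE(allow_nonstandard)),
            class = "net_spec")
}

ch <- function(base, w) as.integer(max(1, round(base * w)))

new_net <- function(arch, layers, spec) {
  net <- structure(list(arch = arch, layers = layers, spec = spec),
                   class = "dwisr_net")
  net$param_count <- net_param_count(net)
  net
}

#' @export
print.dwisr_net <- function(x, ...) {
  cat(sprintf("dwisr_net <%s>: %d layers, %d parameters (width x%g, seed %d)\n",
              x$arch, length(x$layers), x$param_count,
              x$spec$width_multiplier, x$spec$seed))
  invisible(x)
}

#' Build the super-resolution generator
#'
#' Residual-block trunk with two x2 sub-pixel convolution stages: a stacked
#' pair of low-resolution images (H x W x 2) maps to a single high-resolution
#' image (rH x rW x 1), e.g. 60 x 60 x 2 in, 240 x 240 out at r = 4. A fixed
#' nearest-neighbor x r upsample of the first input channel is added to the
#' learned output (global residual), so the freshly initialized network
#' already reproduces a plain interpolation.
#'
#' @param spec A [net_spec()] with role `"sr_gen"`.
#' @return A `dwisr_net`.
#' @export
build_sr_generator <- function(spec) {
  if (spec$role != "sr_gen") stop("spec role must be sr_gen")
  if (spec$upscale_factor != 4L && !spec$allow_nonstandard)
    stop("upscale_factor must be 4 (two x2 sub-pixel stages); ",
         "set allow_nonstandard to override")
  if (spec$upscale_factor != 4L && spec$upscale_factor != 2L)
    stop("supported upscale factors: 2, 4")
  c0 <- ch(64, spec$width_multiplier)
  n_up <- if (spec$upscale_factor == 4L) 2L else 1L
  with_seed(spec$seed, {
    layers <- list(head_conv = nn_conv2d(2L, c0, 9L), head_act = nn_lrelu())
    for (b in seq_len(spec$n_resblocks)) {
      layers[[paste0("rb", b, "_conv1")]] <- nn_conv2d(c0, c0, 3L)
      layers[[paste0("rb", b, "_bn1")]] <- nn_bn(c0)
      layers[[paste0("rb", b, "_act")]] <- nn_lrelu()
      layers[[paste0("rb", b, "_conv2")]] <- nn_conv2d(c0, c0, 3L)
      layers[[paste0("rb", b, "_bn2")]] <- nn_bn(c0)
    }
    layers$post_conv <- nn_conv2d(c0, c0, 3L)
    layers$post_bn <- nn_bn(c0)
    for (u in seq_len(n_up)) {
      layers[[paste0("up", u, "_conv")]] <- nn_conv2d(c0, 4L * c0, 3L)
      layers[[paste0("up", u, "_shuffle")]] <- nn_pixel_shuffle(2L)
      layers[[paste0("up", u, "_act")]] <- nn_lrelu()
    }
    layers$tail_conv <- nn_conv2d(c0, 1L, 9L, w_scale = 0.1)
    new_net("sr_gen", layers, spec)
  })
}

sr_gen_forward <- function(net, x) {
  if (length(dim(x)) != 3 || dim(x)[3] != 2)
    stop("sr generator input must be H x W x 2")
  L <- net$layers
  rec <- list()
  run <- function(nm, v) {
    r <- nn_forward(L[[nm]], v)
    rec[[nm]] <<- r$cache
    r$y
  }
  h <- run("head_act", run("head_conv", x))
  trunk_in <- h
  for (b in seq_len(net$spec$n_resblocks)) {
    t <- run(paste0("rb", b, "_bn1"), run(paste0("rb", b, "_conv1"), h))
    t <- run(paste0("rb", b, "_act"), t)
    t <- run(paste0("rb", b, "_bn2"), run(paste0("rb", b, "_conv2"), t))
    h <- h + t
  }
  h <- run("post_bn", run("post_conv", h)) + trunk_in
  n_up <- if (net$spec$upscale_factor == 4L) 2L else 1L
  for (u in seq_len(n_up)) {
    h <- run(paste0("up", u, "_act"),
             run(paste0("up", u, "_shuffle"), run(paste0("up", u, "_conv"), h)))
  }
  y <- run("tail_conv", h)
  if (net$spec$residual_upsample) {
    r <- net$spec$upscale_factor
    base <- kronecker(x[, , 1], matrix(1, r, r))
    y <- y + array(base, dim(y))
  }
  list(y = y, rec = rec)
}

sr_gen_backward <- function(net, rec, dy) {
  L <- net$layers
  grads <- stats::setNames(vector("list", length(L)), names(L))
  back <- function(nm, d) {
    r <- nn_backward(L[[nm]], rec[[nm]], d)
    grads[[nm]] <<- r$grads
    r$dx
  }
  dy_out <- dy
  d <- back("tail_conv", dy)
  n_up <- if (net$spec$upscale_factor == 4L) 2L else 1L
  for (u in rev(seq_len(n_up))) {
    d <- back(paste0("up", u, "_conv"),
              back(paste0("up", u, "_shuffle"), back(paste0("up", u, "_act"), d)))
  }
  d_trunk_in <- d                                  # long skip
  d <- back("post_conv", back("post_bn", d))
  for (b in rev(seq_len(net$spec$n_resblocks))) {
    dt <- back(paste0("rb", b, "_conv2"),
               back(paste0("rb", b, "_bn2"), d))
    dt <- back(paste0("rb", b, "_act"), dt)
    dt <- back(paste0("rb", b, "_conv1"),
               back(paste0("rb", b, "_bn1"), dt))
    d <- d + dt                                    # residual skip
  }
  d <- d + d_trunk_in
  dx <- back("head_conv", back("head_act", d))
  if (net$spec$residual_upsample) {
    r <- net$spec$upscale_factor
    # adjoint of the nearest-neighbor upsample skip: block sums of dy
    dx[, , 1] <- dx[, , 1] + block_average(dy_out[, , 1], r) * r^2
  }
  list(dx = dx, grads = grads)
}

#' Build the super-resolution critic (discriminator)
#'
#' Eight 3x3 convolutional layers with channels doubling as depth grows and
#' alternating stride-2 shrinking, global average pooling and a single linear
#' output: a Wasserstein critic, so there is no terminal sigmoid and outputs
#' are unbounded. Doubling the input size changes only the pre-output
#' pooling, not the conv stack.
#'
#' @param spec A [net_spec()] with role `"sr_disc"`.
#' @return A `dwisr_net` (sequential; supports the exact gradient penalty).
#' @export
build_sr_discriminator <- function(spec) {
  if (spec$role != "sr_disc") stop("spec role must be sr_disc")
  c0 <- ch(64, spec$width_multiplier)
  plan <- list(c(1, c0, 1), c(c0, c0, 2), c(c0, 2 * c0, 1), c(2 * c0, 2 * c0, 2),
               c(2 * c0, 4 * c0, 1), c(4 * c0, 4 * c0, 2),
               c(4 * c0, 8 * c0, 1), c(8 * c0, 8 * c0, 2))
  with_seed(spec$seed, {
    layers <- list()
    for (i in seq_along(plan)) {
      p <- plan[[i]]
      layers[[paste0("conv", i)]] <- nn_conv2d(p[1], p[2], 3L, stride = p[3])
      layers[[paste0("act", i)]] <- nn_lrelu()
    }
    layers$pool <- nn_global_pool()
    layers$out <- nn_dense(8L * c0, 1L)
    new_net("sr_disc", layers, spec)
  })
}

#' Build the deblurring generator
#'
#' Five-layer convolutional encoder (stride-2 downsampling at layers 2 and 4)
#' mirrored by a transposed-convolution decoder; blur-to-sharp image-to-image
#' map preserving the input shape, with an optional identity skip so the net
#' learns the sharpening residual.
#'
#' @param spec A [net_spec()] with role `"deblur_gen"`.
#' @return A `dwisr_net`.
#' @export
build_deblur_generator <- function(spec) {
  if (spec$role != "deblur_gen") stop("spec role must be deblur_gen")
  c0 <- ch(64, spec$width_multiplier)
  enc <- list(c(1, c0, 1), c(c0, 2 * c0, 2), c(2 * c0, 2 * c0, 1),
              c(2 * c0, 4 * c0, 2), c(4 * c0, 4 * c0, 1))
  dec <- list(c(4 * c0, 4 * c0, 1), c(4 * c0, 2 * c0, 2), c(2 * c0, 2 * c0, 1),
              c(2 * c0, c0, 2), c(c0, 1, 1))
  with_seed(spec$seed, {
    layers <- list()
    for (i in seq_along(enc)) {
      p <- enc[[i]]
      layers[[paste0("enc", i, "_conv")]] <- nn_conv2d(p[1], p[2], 3L, stride = p[3])
      layers[[paste0("enc", i, "_bn")]] <- nn_bn(p[2])
      layers[[paste0("enc", i, "_act")]] <- nn_lrelu()
    }
    for (i in seq_along(dec)) {
      p <- dec[[i]]
      last <- i == length(dec)
      layers[[paste0("dec", i, "_tconv")]] <-
        nn_tconv2d(p[1], p[2], 3L, stride = p[3], w_scale = if (last) 0.1 else 1)
      if (!last) {
        layers[[paste0("dec", i, "_bn")]] <- nn_bn(p[2])
        layers[[paste0("dec", i, "_act")]] <- nn_lrelu()
      }
    }
    new_net("deblur_gen", layers, spec)
  })
}

deblur_forward <- function(net, x) {
  if (length(dim(x)) != 3) x <- array(x, c(dim(x), 1))
  if (dim(x)[1] %% 4 != 0 || dim(x)[2] %% 4 != 0)
    stop("deblur generator input must be divisible by the total stride (4)")
  r <- seq_forward(net$layers, x)
  y <- r$y
  if (net$spec$residual_skip) y <- y + x
  list(y = y, rec = r$caches, x = x)
}

deblur_backward <- function(net, rec, dy) {
  r <- seq_backward(net$layers, rec, dy)
  dx <- r$dx
  if (net$spec$residual_skip) dx <- dx + dy
  list(dx = dx, grads = stats::setNames(r$grads, names(net$layers)))
}

#' Build the 3D denoising GAN pair
#'
#' Generator: eight 3D stages with the printed channel sequence
#' 32-64-128-256-128-64-32-1 (scaled by `width_multiplier`), uniform 3x3x3
#' kernels, conv -> Leaky-ReLU -> batch-norm on every stage except the last
#' (conv + Leaky-ReLU only), and short skip connections joining conv/deconv
#' pairs symmetrically; a global input skip makes the net predict the noise
#' residual. Critic: three 3D conv layers (32, 64, 128 channels) plus a fully
#' connected single output.
#'
#' @param spec A [net_spec()] with role `"denoise_gen"`.
#' @return List with networks `G` and `D`.
#' @export
build_denoise_gan <- function(spec) {
  if (spec$role != "denoise_gen") stop("spec role must be denoise_gen")
  w <- spec$width_multiplier
  seq_ch <- vapply(c(32, 64, 128, 256, 128, 64, 32), ch, 0L, w = w)
  with_seed(spec$seed, {
    layers <- list()
    prev <- 1L
    for (i in seq_along(seq_ch)) {
      nm <- if (i <= 4) paste0("conv", i) else paste0("deconv", i - 4)
      layers[[paste0(nm, "_conv")]] <- nn_conv3d(prev, seq_ch[i], 3L)
      layers[[paste0(nm, "_act")]] <- nn_lrelu()
      layers[[paste0(nm, "_bn")]] <- nn_bn(seq_ch[i])
      prev <- seq_ch[i]
    }
    layers$out_conv <- nn_conv3d(prev, 1L, 3L, w_scale = 0.1)
    layers$out_act <- nn_lrelu()
    G <- new_net("denoise_gen", layers, spec)

    dlayers <- list()
    dch <- vapply(c(32, 64, 128), ch, 0L, w = w)
    prev <- 1L
    for (i in seq_along(dch)) {
      dlayers[[paste0("conv", i)]] <- nn_conv3d(prev, dch[i], 3L, stride = 2L)
      dlayers[[paste0("act", i)]] <- nn_lrelu()
      prev <- dch[i]
    }
    dlayers$pool <- nn_global_pool()
    dlayers$out <- nn_dense(prev, 1L)
    dspec <- spec; dspec$role <- "denoise_disc"
    D <- new_net("denoise_disc", dlayers, dspec)
    list(G = G, D = D)
  })
}

denoise_forward <- function(net, x) {
  if (length(dim(x)) != 4) {
    if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
    else stop("denoise generator requires a 3D volume (D x H x W[ x 1])")
  }
  L <- net$layers
  rec <- list()
  run <- function(nm, v) {
    r <- nn_forward(L[[nm]], v)
    rec[[nm]] <<- r$cache
    r$y
  }
  stage <- function(nm, v) run(paste0(nm, "_bn"),
                               run(paste0(nm, "_act"), run(paste0(nm, "_conv"), v)))
  y1 <- stage("conv1", x)
  y2 <- stage("conv2", y1)
  y3 <- stage("conv3", y2)
  y4 <- stage("conv4", y3)
  y5 <- stage("deconv1", y4) + y3          # short skips: symmetric pairs
  y6 <- stage("deconv2", y5) + y2
  y7 <- stage("deconv3", y6) + y1
  y <- run("out_act", run("out_conv", y7))
  y <- y + x                               # global residual
  list(y = y, rec = rec, x = x)
}

denoise_backward <- function(net, rec, dy) {
  L <- net$layers
  grads <- stats::setNames(vector("list", length(L)), names(L))
  back <- function(nm, d) {
    r <- nn_backward(L[[nm]], rec[[nm]], d)
    grads[[nm]] <<- r$grads
    r$dx
  }
  bstage <- function(nm, d) back(paste0(nm, "_conv"),
                                 back(paste0(nm, "_act"), back(paste0(nm, "_bn"), d)))
  dx_global <- dy
  d7 <- back("out_conv", back("out_act", dy))
  d6 <- bstage("deconv3", d7); d1s <- d7
  d5 <- bstage("deconv2", d6); d2s <- d6
  d4 <- bstage("deconv1", d5); d3s <- d5
  d3 <- bstage("conv4", d4) + d3s
  d2 <- bstage("conv3", d3) + d2s
  d1 <- bstage("conv2", d2) + d1s
  dx <- bstage("conv1", d1) + dx_global
  list(dx = dx, grads = grads)
}

#' Build the perceptual feature extractor
#'
#' Default: a fixed-seed random convolutional stack (3x3 conv + leaky ReLU
#' blocks) whose features define the perceptual distance; random projections
#' are a documented surrogate when pretrained feature weights are
#' unavailable. `kind = "identity"` builds a single 1x1 identity conv, under
#' which the perceptual loss degenerates to pixel MSE. Externally supplied
#' weights can be loaded into the same structure via [net_set_params()].
#'
#' @param spec A [net_spec()] with role `"feature_extractor"`.
#' @param kind `"random"` or `"identity"`.
#' @param tap_layer Conv block whose post-activation output is returned
#'   (default: the last).
#' @return A `dwisr_net` with a `tap` field.
#' @export
build_feature_extractor <- function(spec, kind = c("random", "identity"),
                                    tap_layer = NULL) {
  if (spec$role != "feature_extractor") stop("spec role must be feature_extractor")
  kind <- match.arg(kind)
  with_seed(spec$seed, {
    if (kind == "identity") {
      l <- nn_conv2d(1L, 1L, 1L)
      l$W[] <- 1; l$b[] <- 0
      layers <- list(conv1 = l)
      net <- new_net("feature_extractor", layers, spec)
      net$tap <- 1L
      net$kind <- "identity"
      return(net)
    }
    c0 <- ch(16, spec$width_multiplier)
    layers <- list()
    prev <- 1L
    for (i in seq_len(spec$n_layers)) {
      layers[[paste0("conv", i)]] <- nn_conv2d(prev, c0, 3L)
      layers[[paste0("act", i)]] <- nn_lrelu()
      prev <- c0
    }
    net <- new_net("feature_extractor", layers, spec)
    net$tap <- tap_layer %||% spec$n_layers
    net$kind <- "random"
    net
  })
}

#' Extract perceptual feature maps from an image
#'
#' Runs the extractor up to its configured tap (after that block's
#' activation) and returns the maps with their dimensions, as needed for
#' normalized perceptual losses.
#'
#' @param image Numeric matrix or H x W x 1 array.
#' @param extractor A [build_feature_extractor()] network.
#' @param layer Optional tap override (conv-block index).
#' @return List with `features` (H x W x C array), `dims`, and `rec`
#'   (caches, for backpropagation).
#' @export
feature_extract <- function(image, extractor, layer = NULL) {
  tap <- layer %||% extractor$tap
  nconv <- sum(grepl("^conv", names(extractor$layers)))
  if (tap < 1 || tap > nconv)
    stop("tap layer ", tap, " beyond extractor depth ", nconv)
  if (is.matrix(image)) image <- array(image, c(dim(image), 1))
  x <- image
  rec <- list()
  used <- character(0)
  for (nm in names(extractor$layers)) {
    r <- nn_forward(extractor$layers[[nm]], x)
    x <- r$y
    rec[[nm]] <- r$cache
    used <- c(used, nm)
    if (nm == paste0("act", tap) ||
        (extractor$kind == "identity" && nm == paste0("conv", tap))) break
  }
  list(features = x, dims = dim(x), rec = rec, used = used)
}

# gradient of a scalar loss wrt the extractor input, given dL/dfeatures
feature_backward <- function(extractor, fx, dfeat) {
  d <- dfeat
  for (nm in rev(fx$used)) {
    r <- nn_backward(extractor$layers[[nm]], fx$rec[[nm]], d)
    d <- r$dx
  }
  d
}

#' Run a generator network on an input
#'
#' Dispatches on architecture and drops the trailing singleton channel.
#'
#' @param net A generator `dwisr_net`.
#' @param x Input array.
#' @return Output array (2D matrix or 3D volume).
#' @export
net_predict <- function(net, x) {
  r <- switch(net$arch,
              sr_gen = sr_gen_forward(net, x),
              deblur_gen = deblur_forward(net, x),
              denoise_gen = denoise_forward(net, x),
              stop("net_predict supports generator networks"))
  y <- r$y
  if (dim(y)[length(dim(y))] == 1) {
    d <- dim(y)[-length(dim(y))]
    dim(y) <- d
  }
  y
}

#' Evaluate a critic network
#'
#' @param net A critic `dwisr_net` (`sr_disc` or `denoise_disc`).
#' @param x Input array (channel dimension added if missing).
#' @param record Keep caches for backpropagation.
#' @return Scalar critic value, or (with `record`) a list `y`, `rec`.
#' @export
critic_value <- function(net, x, record = FALSE) {
  nd <- if (net$arch == "denoise_disc") 4L else 3L
  if (length(dim(x)) == nd - 1L) x <- array(x, c(dim(x), 1))
  r <- seq_forward(net$layers, x)
  if (record) list(y = as.numeric(r$y), rec = r$caches) else as.numeric(r$y)
}
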