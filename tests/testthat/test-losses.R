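# Loss algebra, Lipschitz mechanics, and the training loop contracts.

test_that("Wasserstein losses follow their defining arithmetic", {
  expect_equal(wasserstein_losses(c(1, 1), c(1, 1))$d_loss, 0)
  expect_equal(wasserstein_losses(c(1, 1), c(0, 0))$d_loss, -1)
  # translation invariance of the critic gap
  r <- with_seed(1, stats::rnorm(8)); f <- with_seed(2, stats::rnorm(8))
  base <- wasserstein_losses(r, f)$d_loss
  expect_equal(wasserstein_losses(r + 17.3, f + 17.3)$d_loss, base,
               tolerance = 1e-12)
  expect_error(wasserstein_losses(numeric(0), 1), "empty")
})

test_that("weight clipping saturates every parameter at the bound", {
  D <- build_sr_discriminator(net_spec("sr_disc", width_multiplier = 0.1, seed = 1))
  D$layers$conv1$W[1] <- 5
  Dc <- clip_weights(D, 0.01)
  p <- unlist(dwisr:::net_params(Dc))
  expect_lte(max(abs(p)), 0.01)
  expect_equal(Dc$layers$conv1$W[1], 0.01)
  # parameters already inside the bound are untouched
  small <- clip_weights(D, 1e6)
  expect_identical(dwisr:::net_params(small), dwisr:::net_params(D))
  expect_error(clip_weights(D, 0), "positive")
})

test_that("the SR composite loss equals its weighted components", {
  hr <- textured_image(16, seed = 1)
  # exact zeros when SR matches HR and neighbors match the target
  l0 <- sr_losses(hr, hr, registered_neighbors = list(hr * 0 + 1),
                  lr_target = hr * 0 + 1)
  expect_equal(l0$components$lmse, 0)
  expect_equal(l0$components$rlt, 0)
  # 2x2 difference of one everywhere: lMSE = 1
  l1 <- sr_losses(matrix(1, 2, 2), matrix(2, 2, 2))
  expect_equal(l1$components$lmse, 1)
  # weighted-sum identity against an independent scalar loop
  D <- build_sr_discriminator(net_spec("sr_disc", width_multiplier = 0.1, seed = 2))
  sr <- textured_image(16, seed = 3)
  nb <- list(textured_image(16, seed = 4), textured_image(16, seed = 5))
  lt <- textured_image(16, seed = 6)
  w <- loss_weights()
  bd <- sr_losses(sr, hr, critic = D, registered_neighbors = nb, lr_target = lt,
                  weights = w)
  lmse_ind <- 0
  for (i in seq_along(sr)) lmse_ind <- lmse_ind + (hr[i] - sr[i])^2
  lmse_ind <- lmse_ind / length(sr)
  rlt_ind <- 0
  for (k in 1:2) for (i in seq_along(lt)) rlt_ind <- rlt_ind + (nb[[k]][i] - lt[i])^2
  lgen_ind <- critic_value(D, sr) - critic_value(D, hr)
  expect_equal(bd$total,
               lmse_ind + w$adv_weight * lgen_ind + w$rlt_weight * rlt_ind,
               tolerance = 1e-12)
  expect_error(sr_losses(matrix(0, 2, 2), matrix(0, 3, 3)), "differ")
})

test_that("the deblurring loss combines adversarial and perceptual terms", {
  Db <- build_deblur_generator(net_spec("deblur_gen", width_multiplier = 0.1,
                                        seed = 1))
  Db$layers$dec5_tconv$W[] <- 0; Db$layers$dec5_tconv$b[] <- 0  # identity G
  D <- build_sr_discriminator(net_spec("sr_disc", width_multiplier = 0.1, seed = 2))
  fid <- build_feature_extractor(net_spec("feature_extractor", seed = 1),
                                 kind = "identity")
  sharp <- textured_image(32, seed = 3)
  # G(sharp) == sharp: content term vanishes, total is pure adversarial
  bd <- deblur_loss(sharp, sharp, Db, D, fid)
  expect_equal(bd$components$l_x, 0, tolerance = 1e-12)
  expect_equal(bd$total, bd$components$l_gan, tolerance = 1e-12)
  # lambda ablation
  blurred <- gaussian_blur(sharp, 2)
  w0 <- loss_weights(deblur_lambda = 0)
  bd0 <- deblur_loss(blurred, sharp, Db, D, fid, weights = w0)
  expect_equal(bd0$total, bd0$components$l_gan, tolerance = 1e-12)
  # identity extractor: content term equals pixel MSE of the G output
  bdi <- deblur_loss(blurred, sharp, Db, D, fid)
  expect_equal(bdi$components$l_x, mean((blurred - sharp)^2), tolerance = 1e-12)
  # weighted-sum identity
  w <- loss_weights()
  bdw <- deblur_loss(blurred, sharp, Db, D, fid, weights = w)
  expect_equal(bdw$total,
               bdw$components$l_gan + w$deblur_lambda * bdw$components$l_x,
               tolerance = 1e-12)
})

test_that("the gradient penalty is exact for linear critics", {
  n <- 8
  w <- with_seed(1, stats::rnorm(n * n))
  make_linear_critic <- function(scale) {
    l <- dwisr:::nn_dense(n * n, 1L)
    l$W[] <- scale * w / sqrt(sum(w^2))
    l$b[] <- 0
    net <- structure(list(arch = "linear_critic", layers = list(out = l),
                          spec = list()), class = "dwisr_net")
    net
  }
  real <- with_seed(2, matrix(stats::rnorm(n * n), n))
  fake <- with_seed(3, matrix(stats::rnorm(n * n), n))
  # unit-norm linear critic: penalty exactly zero
  u <- make_linear_critic(1)
  lu <- wgan_gp_d_loss(u, real, fake, psi = 10, seed = 4)
  expect_equal(attr(lu, "components")$penalty, 0, tolerance = 1e-12)
  expect_equal(as.numeric(lu), attr(lu, "components")$d_loss, tolerance = 1e-12)
  # double-norm critic: penalty psi * (2 - 1)^2
  d2 <- make_linear_critic(2)
  l2 <- wgan_gp_d_loss(d2, real, fake, psi = 10, seed = 4)
  expect_equal(attr(l2, "components")$penalty, 1, tolerance = 1e-12)
  expect_equal(as.numeric(l2), attr(l2, "components")$d_loss + 10,
               tolerance = 1e-12)
  # the interpolation endpoints reproduce the inputs exactly
  for (e in c(0, 1)) {
    xh <- e * real + (1 - e) * fake
    expect_identical(xh, if (e == 1) real else fake)
  }
})

test_that("the denoising composite equals its delta-weighted parts", {
  gan <- build_denoise_gan(net_spec("denoise_gen", width_multiplier = 0.1,
                                    seed = 1))
  G <- gan$G
  G$layers$out_conv$W[] <- 0; G$layers$out_conv$b[] <- 0   # G(x) = x
  fid <- build_feature_extractor(net_spec("feature_extractor", seed = 1),
                                 kind = "identity")
  v <- clean_volume_16(1)[1:8, 1:8, 1:8]
  # G(x) == y: both fidelity terms vanish
  bd0 <- denoise_losses(v, v, G, gan$D, fid)
  expect_equal(bd0$components$l_mse, 0)
  expect_equal(bd0$components$l_perc, 0)
  # constant offset of 2: L_MSE = 4 (2x2x2 volume)
  v2 <- array(1, c(2, 2, 2))
  g2 <- build_denoise_gan(net_spec("denoise_gen", width_multiplier = 0.1,
                                   seed = 2))$G
  g2$layers$out_conv$W[] <- 0; g2$layers$out_conv$b[] <- 0
  bd2 <- denoise_losses(v2 + 2, v2, g2)
  expect_equal(bd2$components$l_mse, 4, tolerance = 1e-12)
  # weighted-sum identity with independently evaluated components
  noisy <- add_rician_noise(v, 0.1, seed = 5)
  w <- loss_weights(denoise_deltas = c(1, 0.1, 1e-3))
  bd <- denoise_losses(noisy, v, G, gan$D, fid, weights = w)
  d <- w$denoise_deltas
  expect_equal(bd$total,
               d[1] * bd$components$l_mse + d[2] * bd$components$l_perc +
                 d[3] * bd$components$l_wgan,
               tolerance = 1e-12)
  expect_error(denoise_losses(v, v[1:4, , ], G), "differ")
})

test_that("adversarial training is reproducible and leaves G untouched at 0 steps", {
  cleans <- lapply(1:2, clean_volume_16)
  stream <- function(i) {
    cl <- cleans[[(i %% 2) + 1]]
    list(input = add_rician_noise(cl, 0.1, seed = 100 + i), target = cl)
  }
  gan <- build_denoise_gan(net_spec("denoise_gen", width_multiplier = 0.1,
                                    seed = 7))
  cfg0 <- train_config(steps = 0, seed = 1, gan_mode = "wgan_gp")
  r0 <- train_adversarial(gan$G, gan$D, stream, config = cfg0)
  expect_identical(dwisr:::net_params(r0$G), dwisr:::net_params(gan$G))
  cfg <- train_config(learning_rate = 1e-3, steps = 6, seed = 2,
                      gan_mode = "wgan_gp")
  ra <- train_adversarial(gan$G, gan$D, stream, config = cfg)
  rb <- train_adversarial(gan$G, gan$D, stream, config = cfg)
  expect_identical(ra$history, rb$history)
  expect_false(ra$aborted)
  # clipping mode: the bound holds after every critic step
  cfgc <- train_config(learning_rate = 1e-3, steps = 3, seed = 3,
                       gan_mode = "wgan_clip", critic_updates_per_gen = 2)
  rc <- train_adversarial(gan$G, gan$D, stream, config = cfgc)
  expect_lte(max(abs(unlist(dwisr:::net_params(rc$D)))), loss_weights()$clip_c)
})
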