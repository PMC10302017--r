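# Architecture contracts: shapes, layer counts, channel sequences,
# determinism, and the perceptual extractor.

test_that("the SR generator honors its shape contract", {
  G <- build_sr_generator(net_spec("sr_gen", width_multiplier = 0.25, seed = 1))
  y <- net_predict(G, array(stats::rnorm(16 * 16 * 2), c(16, 16, 2)))
  expect_equal(dim(y), c(64, 64))
  # determinism of initialization
  G2 <- build_sr_generator(net_spec("sr_gen", width_multiplier = 0.25, seed = 1))
  expect_identical(dwisr:::net_params(G), dwisr:::net_params(G2))
  G3 <- build_sr_generator(net_spec("sr_gen", width_multiplier = 0.25, seed = 2))
  expect_false(identical(dwisr:::net_params(G), dwisr:::net_params(G3)))
  expect_error(build_sr_generator(net_spec("sr_gen", upscale_factor = 3)),
               "override")
  y2 <- net_predict(build_sr_generator(net_spec("sr_gen", width_multiplier = 0.25,
                                                upscale_factor = 2,
                                                allow_nonstandard = TRUE, seed = 1)),
                    array(0, c(16, 16, 2)))
  expect_equal(dim(y2), c(32, 32))
})

test_that("the SR critic is an 8-conv unbounded-output network", {
  D <- build_sr_discriminator(net_spec("sr_disc", width_multiplier = 0.25, seed = 3))
  expect_equal(sum(grepl("^conv", names(D$layers))), 8)
  # no terminal sigmoid: critic values are not squashed into (0, 1)
  vals <- vapply(1:12, function(i)
    critic_value(D, with_seed(i, matrix(stats::rnorm(32 * 32, sd = 3), 32))), 0)
  expect_true(any(vals < 0 | vals > 1))
  # and the map is homogeneous-ish, not saturating: scaling the input scales
  # the response well beyond a sigmoid's range
  x <- with_seed(99, matrix(stats::rnorm(32 * 32), 32))
  expect_gt(abs(critic_value(D, 100 * x)), 1)
  # doubling the input size changes only pre-output pooling: same layer count,
  # both sizes accepted
  expect_length(critic_value(D, matrix(0, 64, 64)), 1)
  expect_length(critic_value(D, matrix(0, 32, 32)), 1)
})

test_that("the deblurring encoder-decoder preserves shape and supports identity", {
  Db <- build_deblur_generator(net_spec("deblur_gen", width_multiplier = 0.25,
                                        seed = 4))
  expect_equal(dim(net_predict(Db, matrix(stats::rnorm(64^2), 64))), c(64, 64))
  expect_equal(sum(grepl("^enc.*_conv$", names(Db$layers))), 5)
  expect_equal(sum(grepl("^dec.*_tconv$", names(Db$layers))), 5)
  # zero final layer + identity skip: exact identity map
  Db$layers$dec5_tconv$W[] <- 0
  Db$layers$dec5_tconv$b[] <- 0
  x <- matrix(stats::runif(64^2), 64)
  expect_equal(net_predict(Db, x), x, tolerance = 1e-12)
  expect_error(net_predict(Db, matrix(0, 30, 30)), "divisible")
})

test_that("the denoising GAN follows the printed 3D architecture", {
  gan <- build_denoise_gan(net_spec("denoise_gen", width_multiplier = 1, seed = 5))
  convs <- gan$G$layers[grep("_conv$", names(gan$G$layers))]
  expect_equal(unname(vapply(convs, `[[`, 0L, "out_ch")),
               c(32L, 64L, 128L, 256L, 128L, 64L, 32L, 1L))
  expect_true(all(vapply(convs, `[[`, 0L, "k") == 3L))
  # all-but-last stages carry batch norm; the last is conv + activation only
  expect_true("deconv3_bn" %in% names(gan$G$layers))
  expect_false("out_bn" %in% names(gan$G$layers))
  # critic: three 3D convs (32, 64, 128) + single dense output
  dch <- vapply(gan$D$layers[grep("^conv", names(gan$D$layers))], `[[`, 0L,
                "out_ch")
  expect_equal(unname(dch), c(32L, 64L, 128L))
  expect_equal(length(gan$D$layers$out$b), 1L)
  # shape preservation at toy width within the runtime contract
  g4 <- build_denoise_gan(net_spec("denoise_gen", width_multiplier = 0.25,
                                   seed = 5))
  vol <- array(abs(stats::rnorm(16^3)), c(16, 16, 16))
  t0 <- Sys.time()
  out <- net_predict(g4$G, vol)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  expect_equal(dim(out), c(16, 16, 16))
  expect_error(dwisr:::denoise_forward(g4$G, matrix(0, 8, 8)), "3D")
})

test_that("feature extraction is deterministic, continuous, and degenerates to MSE", {
  fe <- build_feature_extractor(net_spec("feature_extractor",
                                         width_multiplier = 0.5, seed = 6))
  img <- textured_image(32, seed = 7)
  fa <- feature_extract(img, fe)
  fb <- feature_extract(img, fe)
  expect_identical(fa$features, fb$features)
  # perceptual distance shrinks with perturbation size
  d_at <- function(eps) {
    fp <- feature_extract(img + eps, fe)
    mean((fp$features - fa$features)^2)
  }
  dists <- vapply(c(1e-3, 1e-2, 1e-1), d_at, 0)
  expect_true(all(diff(dists) > 0))
  expect_lt(dists[1], 1e-4)
  # identity extractor: perceptual loss reduces to pixel MSE
  fid <- build_feature_extractor(net_spec("feature_extractor", seed = 1),
                                 kind = "identity")
  other <- textured_image(32, seed = 8)
  f1 <- feature_extract(img, fid)
  f2 <- feature_extract(other, fid)
  expect_equal(mean((f1$features - f2$features)^2), mean((img - other)^2),
               tolerance = 1e-12)
  expect_error(feature_extract(img, fe, layer = 99), "depth")
})

test_that("parameter counts are reproducible at full and quarter width", {
  counts <- c(
    sr_gen_w1 = build_sr_generator(net_spec("sr_gen", seed = 1))$param_count,
    sr_gen_w025 = build_sr_generator(net_spec("sr_gen", width_multiplier = 0.25,
                                              seed = 1))$param_count,
    denoise_g_w1 = build_denoise_gan(net_spec("denoise_gen", seed = 1))$G$param_count,
    denoise_g_w025 = build_denoise_gan(net_spec("denoise_gen",
                                                width_multiplier = 0.25,
                                                seed = 1))$G$param_count)
  expect_equal(unname(counts), c(940993, 62449, 2326273, 146113))
})
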