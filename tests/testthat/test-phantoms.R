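# Analytic phantoms and degradation operators.

test_that("Shepp-Logan phantom matches its analytic ellipse definition", {
  img <- make_shepp_logan(phantom_spec("shepp_logan", 256))
  expect_equal(dim(img), c(256, 256))
  # background (outside the outer ellipse) is exactly zero
  expect_identical(img[1, 1], 0)
  expect_identical(img[256, 256], 0)
  expect_true(all(img >= 0 & img <= 1))

  # independent oracle: evaluate the standard ellipse table at the origin
  tab <- rbind(c(1, .69, .92, 0, 0, 0), c(-.8, .6624, .874, 0, -.0184, 0),
               c(-.2, .11, .31, .22, 0, -18), c(-.2, .16, .41, -.22, 0, 18),
               c(.1, .21, .25, 0, .35, 0), c(.1, .046, .046, 0, .1, 0),
               c(.1, .046, .046, 0, -.1, 0), c(.1, .046, .023, -.08, -.605, 0),
               c(.1, .023, .023, 0, -.606, 0), c(.1, .023, .046, .06, -.605, 0))
  inside0 <- function(e) {
    phi <- e[6] * pi / 180
    u <- cos(phi) * (0 - e[4]) + sin(phi) * (0 - e[5])
    v <- -sin(phi) * (0 - e[4]) + cos(phi) * (0 - e[5])
    (u / e[2])^2 + (v / e[3])^2 <= 1
  }
  center_value <- sum(tab[apply(tab, 1, inside0), 1])
  img64 <- make_shepp_logan(phantom_spec("shepp_logan", 64))
  expect_equal(img64[33, 33], center_value, tolerance = 1e-12) # pixel at (0,0)

  expect_identical(make_shepp_logan(phantom_spec("shepp_logan", 64)), img64)
  expect_error(phantom_spec("shepp_logan", 48), "power of 2")
  expect_error(phantom_spec("shepp_logan", 8), "power of 2")
})

test_that("DWI tensor phantom has the q-space correlation structure", {
  sp <- phantom_spec("dwi_tensor", 32, 8, b_value = 1000, seed = 1)
  st <- make_dwi_phantom(sp)
  expect_equal(dim(st$images), c(32, 32, 8))
  expect_equal(colSums(st$bvecs^2), rep(1, 8), tolerance = 1e-12)

  # b = 0: every direction image equals S0
  st0 <- make_dwi_phantom(phantom_spec("dwi_tensor", 32, 4, b_value = 0))
  for (d in 1:4) expect_equal(st0$images[, , d], st0$s0)

  # isotropic tensor: direction independence
  sti <- make_dwi_phantom(sp, lambda_par = 1e-3, lambda_perp = 1e-3)
  for (d in 2:8) expect_equal(sti$images[, , d], sti$images[, , 1])

  # correlation decreases with angular distance (antipodally symmetric)
  ang <- function(a, b) acos(min(1, abs(sum(st$bvecs[, a] * st$bvecs[, b]))))
  mask <- st$s0 > 0
  pairs <- t(utils::combn(8, 2))
  angs <- apply(pairs, 1, function(p) ang(p[1], p[2]))
  cors <- apply(pairs, 1, function(p)
    stats::cor(st$images[, , p[1]][mask], st$images[, , p[2]][mask]))
  expect_gt(cors[which.min(angs)], cors[which.max(angs)])
  expect_lt(stats::cor(angs, cors, method = "kendall"), 0)

  expect_error(make_dwi_phantom(phantom_spec("dwi_tensor", 32, 2, b_value = -5)),
               "non-negative")
})

test_that("deformations warp correctly and report the exact ground truth", {
  img <- shepp64()
  # zero displacement: identity, zero field
  z <- apply_deformation(img, deformation_spec("affine"))
  expect_equal(z$image, img, tolerance = 1e-12)
  expect_true(all(z$field$f == 0) && all(z$field$g == 0))

  # pure integer shift: interior equals the rolled image
  sh <- apply_deformation(img, deformation_spec("affine", subpixel_shift = c(3, 0)))
  expect_equal(sh$image[1:61, ], img[4:64, ], tolerance = 1e-10)
  expect_true(all(sh$field$f == 3))

  # RBF warp round-trip via a numeric fixed-point inverse (independent oracle)
  def <- deformation_spec("rbf_nonrigid", max_displacement = 3, seed = 5)
  wr <- apply_deformation(img, def)
  f <- wr$field$f; g <- wr$field$g
  fi <- -f; gi <- -g                       # fixed-point iteration for inverse
  for (it in 1:30) {
    qi <- as.vector(row(f)) + as.vector(fi)
    qj <- as.vector(col(f)) + as.vector(gi)
    fi <- -matrix(interp_image(f, qi, qj, "linear"), 64, 64)
    gi <- -matrix(interp_image(g, qi, qj, "linear"), 64, 64)
  }
  back <- warp(wr$image, displacement_field(fi, gi))
  expect_gt(psnr_of(back, img), psnr_of(wr$image, img))

  expect_error(apply_deformation(matrix(c(1, NA, 1, 1), 2), def), "finite")
})

test_that("degradation applies blur, block decimation and noise in order", {
  img <- shepp64()
  # identity settings
  id <- degrade_to_lr(img, degradation_spec(blur_sigma = 0, downsample_factor = 1L,
                                            noise_sigma = 0))
  expect_identical(id, img)
  # DC preservation: constant image stays constant under blur, no noise
  cimg <- matrix(0.4, 64, 64)
  out <- degrade_to_lr(cimg, degradation_spec(blur_sigma = 2, downsample_factor = 2L,
                                              noise_sigma = 0))
  expect_equal(out, matrix(0.4, 32, 32), tolerance = 1e-12)
  # 240 x 240 at factor 4 -> 60 x 60
  big <- matrix(stats::runif(240 * 240), 240)
  lr <- degrade_to_lr(big, degradation_spec(blur_sigma = 1, downsample_factor = 4L,
                                            noise_sigma = 0))
  expect_equal(dim(lr), c(60, 60))
  # determinism of the noise draw
  a <- degrade_to_lr(img, degradation_spec(), seed = 9)
  b <- degrade_to_lr(img, degradation_spec(), seed = 9)
  expect_identical(a, b)
})

test_that("Rician noise has the Rayleigh and Gaussian limiting statistics", {
  expect_identical(add_rician_noise(matrix(0.5, 4, 4), 0), matrix(0.5, 4, 4))
  expect_error(add_rician_noise(matrix(1, 2, 2), -1), "non-negative")

  n <- 1e6
  zero <- matrix(0, 1000, 1000)
  r <- add_rician_noise(zero, 1, seed = 3)
  expect_true(all(r >= 0))
  rayleigh_mean <- sqrt(pi / 2)
  se <- sqrt((4 - pi) / 2) / sqrt(n)
  expect_lt(abs(mean(r) - rayleigh_mean), 3 * se)

  big <- matrix(100, 500, 500)
  rb <- add_rician_noise(big, 1, seed = 4)
  expect_lt(abs(stats::sd(rb) - 1), 0.05)
})
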