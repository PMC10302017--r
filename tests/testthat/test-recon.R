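# Sparse-to-image reconstruction: NUFFT, zero filling, Hermitian completion,
# POCS, data-consistency cascade, neighbor-direction composite.

cartesian_traj <- function(n) {
  g <- expand.grid(i = 0:(n - 1), j = 0:(n - 1))
  trajectory(cbind((g$i - n / 2) / n, (g$j - n / 2) / n), n)
}

test_that("NUFFT matches the dense DFT and satisfies the adjoint identity", {
  # delta at the (centered) origin: constant-magnitude samples
  n <- 32
  delta <- matrix(0, n, n); delta[n / 2 + 1, n / 2 + 1] <- 1
  tr <- with_seed(1, trajectory(matrix(stats::runif(200, -0.5, 0.4999), 100), n))
  s <- nufft(delta, tr, "forward")
  expect_equal(Mod(s), rep(1, 100), tolerance = 1e-12)

  # full Cartesian trajectory equals the centered FFT; cross-check against a
  # dense DFT matrix built independently at 16 x 16
  n <- 16
  x <- with_seed(2, matrix(stats::rnorm(n * n), n))
  tr <- cartesian_traj(n)
  s <- nufft(x, tr, "forward")
  expect_equal(max(Mod(s - as.vector(fft2c(x)))) / max(Mod(s)), 0,
               tolerance = 1e-8)
  p <- (0:(n - 1)) - n / 2
  E <- exp(-2i * pi * (outer(tr$coords[, 1], rep(p, each = n)) +
                       outer(tr$coords[, 2], rep(p, times = n))))
  # note: pixel index order (row fastest) => row coordinate pairs with kx
  E2 <- exp(-2i * pi * (outer(tr$coords[, 1], rep(p, times = n)) +
                        outer(tr$coords[, 2], rep(p, each = n))))
  dense <- E2 %*% as.vector(x)
  expect_equal(max(Mod(s - dense)), 0, tolerance = 1e-8)

  # adjoint identity <Ax, y> = <x, A'y> over random trajectories
  errs <- vapply(1:10, function(t) {
    tr <- with_seed(t, trajectory(matrix(stats::runif(128, -0.5, 0.4999), 64), 32))
    xi <- with_seed(t + 100, matrix(stats::rnorm(32 * 32), 32))
    y <- with_seed(t + 200, complex(real = stats::rnorm(64),
                                    imaginary = stats::rnorm(64)))
    ax <- nufft(xi, tr, "forward")
    aty <- nufft(y, tr, "adjoint")
    Mod(sum(Conj(y) * ax) - sum(Conj(as.vector(aty)) * as.vector(xi))) /
      (sqrt(sum(Mod(ax)^2)) * sqrt(sum(Mod(y)^2)))
  }, 0)
  expect_lt(max(errs), 1e-6)
  expect_error(nufft(matrix(0, 8, 8), cartesian_traj(16), "forward"), "grid")
})

test_that("zero filling doubles the matrix by sinc interpolation", {
  k <- kspace_from_image(matrix(stats::rnorm(256^2), 256), full_mask(256))
  expect_equal(dim(zero_fill(k, 2L)), c(512, 512))
  img <- shepp64()
  ksp <- kspace_from_image(img, full_mask(64))
  expect_equal(zero_fill(ksp, 1L), img, tolerance = 1e-10)
  z2 <- zero_fill(ksp, 2L)
  expect_equal(z2[seq(1, 128, 2), seq(1, 128, 2)], img, tolerance = 1e-6)
  tr3 <- trajectory(matrix(c(0.1, -0.3, 0.25, 0.2, 0, 0.11), 3), 16)
  expect_error(zero_fill(kspace(c(1, 2, 3) + 0i, tr3), 1L), "on-grid")
})

test_that("Hermitian completion recovers real objects exactly", {
  img <- shepp64()
  full <- full_mask(64)
  pf <- partial_fourier_mask(full, 0.625)
  ksp <- kspace_from_image(img, pf)
  hf <- hermitian_fill(ksp, pf)
  expect_equal(attr(hf, "unrecoverable"), 0)
  rec <- zero_fill(hf, 1L)
  expect_gt(psnr_of(rec, img), 100)
  # full mask: identity
  kfull <- kspace_from_image(img, sampling_mask(full$mask, hermitian_half = TRUE))
  expect_equal(hermitian_fill(kfull)$values, kfull$values)
  # also exact for a random real image under a random hermitian-half mask
  rimg <- with_seed(7, matrix(stats::rnorm(64 * 64), 64))
  rec2 <- zero_fill(hermitian_fill(kspace_from_image(rimg, pf), pf), 1L)
  expect_lt(max(abs(rec2 - Mod(rimg))), max(abs(rimg)) * 1e-10)
  expect_error(hermitian_fill(kspace_from_image(img, full), full), "hermitian")
})

test_that("POCS reconstruction honors phase and data constraints", {
  img <- shepp64()
  pf <- partial_fourier_mask(full_mask(64), 0.625)
  ksp <- kspace_from_image(img, pf)
  # zero-phase object: converges to the hermitian_fill answer fast
  pr <- pocs_pf_recon(ksp, pf, recon_config(pocs_iterations = 5))
  hfr <- zero_fill(hermitian_fill(ksp, pf), 1L)
  expect_lt(max(abs(pr - hfr)), 1e-6)
  # measured k-space entries are exact after the final data projection
  kout <- attr(pr, "kspace")
  expect_lt(max(Mod(kout[pf$mask] - ksp$values[pf$mask])), 1e-9)
  # smooth linear-phase object: beats plain zero filling
  ph <- exp(1i * (0.02 * outer(1:64, rep(1, 64)) + 0.015 * outer(rep(1, 64), 1:64)))
  kc <- kspace(fft2c(img * ph) * pf$mask, pf)
  prc <- pocs_pf_recon(kc, pf, recon_config(pocs_iterations = 8))
  expect_gte(psnr_of(prc, img), psnr_of(zero_fill(kc, 1L), img))
  # residuals non-increasing over the final half
  res <- attr(prc, "residuals")
  tail_half <- res[(length(res) %/% 2):length(res)]
  expect_true(all(diff(tail_half) <= 1e-12))
  expect_error(pocs_pf_recon(kspace(matrix(0i, 64, 64),
                                    sampling_mask(matrix(FALSE, 64, 64))),
                             sampling_mask(matrix(FALSE, 64, 64))),
               "center band")
})

test_that("the data-consistency cascade respects measured data", {
  img <- shepp64()
  full <- full_mask(64)
  ksp <- kspace_from_image(img, full)
  # identity refiner + full mask: equals direct inverse transform, and is a
  # fixed point after one iteration
  r1 <- dc_cascade_recon(ksp, full, recon_config(n_dc_iterations = 1))
  r5 <- dc_cascade_recon(ksp, full, recon_config(n_dc_iterations = 5))
  expect_equal(r1, img, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(r1, r5, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(r5, "residuals")[2:5], rep(0, 4), tolerance = 1e-10)
  # edge-preserving smoother hook on 4x-undersampled data beats zero filling
  prof <- variable_density_profile(core_frac = 0.12, boost_start = 0.7,
                                   boost = 1.5)
  ps <- poisson_subsample(matrix(TRUE, 64, 64), 0.25, 0, prof, seed = 5)
  ku <- kspace_from_image(img, ps)
  dcr <- dc_cascade_recon(ku, ps, recon_config(n_dc_iterations = 10,
                                               denoiser_hook = median_filter3))
  expect_gte(psnr_of(dcr, img), psnr_of(zero_fill(ku, 1L), img))
  # hard data consistency (dc_weight = 1): the final complex iterate's
  # k-space equals the measured data at every sampled position
  kfin <- attr(dcr, "kspace")
  expect_lt(max(Mod(kfin[ps$mask] - ku$values[ps$mask])) / max(Mod(ku$values)),
            1e-10)
})

test_that("neighbor-direction sharing improves sparse blade reconstruction", {
  st <- make_dwi_phantom(phantom_spec("dwi_tensor", 64, 8, seed = 1))
  bl <- propeller_blades(8, 12, 64, 64)
  kd <- lapply(1:8, function(d)
    kspace_from_image(st$images[, , d], rasterize_trajectory(bl[[d]])))
  # b = 0 stack: composite equals reconstruction from the union of all blades
  st0 <- make_dwi_phantom(phantom_spec("dwi_tensor", 64, 8, b_value = 0))
  kd0 <- lapply(1:8, function(d)
    kspace_from_image(st0$images[, , d], rasterize_trajectory(bl[[d]])))
  sch <- kq_schedule(8, 8, 7)
  comp0 <- rosa_composite(st0, kd0, sch)
  union_mask <- sampling_mask(Reduce(`|`, lapply(bl, function(b)
    rasterize_trajectory(b)$mask)))
  union_rec <- zero_fill(kspace_from_image(st0$images[, , 1], union_mask), 1L)
  expect_equal(comp0$images[, , 1], union_rec, tolerance = 1e-8)
  # neighbor_window 0 falls back to per-direction zero filling (with warning)
  k1 <- kd[1]
  expect_warning(rosa_composite(NULL, k1, kq_schedule(1, 1, 0)), "empty")
  c0 <- suppressWarnings(rosa_composite(st, kd, kq_schedule(8, 8, 0)))
  expect_equal(c0$images[, , 3], zero_fill(kd[[3]], 1L), tolerance = 1e-10)
  # the premise: window-2 sharing beats window-0 in mean PSNR
  c2 <- rosa_composite(st, kd, kq_schedule(8, 8, 2))
  p2 <- mean(vapply(1:8, function(d) psnr_of(c2$images[, , d], st$images[, , d]), 0))
  p0 <- mean(vapply(1:8, function(d) psnr_of(c0$images[, , d], st$images[, , d]), 0))
  expect_gt(p2, p0)
})
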