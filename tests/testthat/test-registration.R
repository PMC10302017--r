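# MST construction, exact tree labeling, warping, and TRE.

test_that("the block graph's spanning tree is minimal and deterministic", {
  # constant image: all costs zero, edge-count invariant
  g0 <- build_mst(matrix(1, 32, 32), 8)
  expect_equal(nrow(g0$tree_edges), prod(g0$n_blocks) - 1)
  # 3x3 block grid with hand-set block intensities: tree cost equals the
  # exhaustive minimum over all spanning trees (union-find oracle)
  vals <- matrix(c(0, 5, 1, 9, 2, 7, 3, 8, 4), 3)
  img <- kronecker(vals, matrix(1, 4, 4))
  g <- build_mst(img, 4)
  tree_cost <- sum(g$tree_costs)
  best <- spanning_tree_min_cost(9, g$edges, g$edge_costs)
  expect_equal(tree_cost, best, tolerance = 1e-12)
  # determinism
  g2 <- build_mst(img, 4)
  expect_identical(g$tree_edges, g2$tree_edges)
  expect_error(build_mst(matrix(1, 8, 8), 8), "degenerate")
})

test_that("tree dynamic programming attains the exhaustive minimum", {
  set.seed(11)
  offs <- as.matrix(expand.grid(-1:1, -1:1))
  pc <- 0.4 * (outer(offs[, 1], offs[, 1], "-")^2 +
               outer(offs[, 2], offs[, 2], "-")^2)
  # 4-node path with hand-built tables: independent R enumeration
  nc <- matrix(stats::runif(9 * 4), 9, 4)
  edges <- cbind(1:3, 2:4)
  dp <- dwisr:::tree_dp(nc, edges, pc)
  grid <- as.matrix(expand.grid(1:9, 1:9, 1:9, 1:9))
  all_e <- apply(grid, 1, function(l)
    sum(nc[cbind(l, 1:4)]) + pc[l[1], l[2]] + pc[l[2], l[3]] + pc[l[3], l[4]])
  expect_equal(dp$energy, min(all_e), tolerance = 1e-12)
  # random 6-node trees with 27 labels against the exhaustive C++ oracle
  offs3 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  pc27 <- 0.25 * as.matrix(stats::dist(offs3))^2
  for (t in 1:10) {
    tr <- random_tree(6)
    nc6 <- matrix(stats::runif(27 * 6), 27, 6)
    dp6 <- dwisr:::tree_dp(nc6, tr, pc27)
    expect_equal(dp6$energy, mrf_bruteforce_min(nc6, tr, pc27),
                 tolerance = 1e-10)
  }
})

test_that("registration recovers known displacements", {
  img <- textured_image(64, seed = 3)
  # identical images: zero data energy
  r0 <- mrf_register(img, img, label_range = 2, kappa = 0.5, levels = 1,
                     block_size = 8)
  expect_equal(r0$energy$data_term, 0, tolerance = 1e-8)
  expect_true(all(abs(r0$field$f) < 1e-8))
  # label_range 0: identity field with its energy
  rz <- mrf_register(img, img + 0.1, label_range = 0, kappa = 1)
  expect_true(all(rz$field$f == 0))
  # integer shift, kappa = 0: exact block-matching recovery
  moving <- rbind(img[3:64, ], img[1:2, ])       # moving(x) = img(x + 2) rows
  rs <- mrf_register(img, moving, label_range = 3, label_step = 1, kappa = 0,
                     levels = 1, block_size = 8)
  # interior blocks recover displacement (-2, 0): moving(x + (-2,0)) = img(x)
  expect_true(all(abs(rs$field$block_f[2:7, 2:7] + 2) < 1e-8))
  expect_true(all(abs(rs$field$block_g[2:7, 2:7]) < 1e-8))
  # energy identity: total = data + reg exactly
  expect_identical(rs$energy$total, rs$energy$data_term + rs$energy$reg_term)
})

test_that("warping is exact for trivial fields and reduces the match error", {
  img <- shepp64()
  zf <- displacement_field(matrix(0, 64, 64), matrix(0, 64, 64))
  expect_equal(warp(img, zf), img, tolerance = 1e-14)
  sf <- displacement_field(matrix(2, 64, 64), matrix(0, 64, 64))
  w <- warp(img, sf)
  expect_equal(w[1:62, ], img[3:64, ], tolerance = 1e-10)
  # estimated field reduces MSE on a synthetic deformation
  def <- deformation_spec("rbf_nonrigid", max_displacement = 3, seed = 8)
  wr <- apply_deformation(img, def)
  est <- mrf_register(wr$image, img, label_range = 3, kappa = 0.1, levels = 2,
                      block_size = 8)
  mse_before <- mean((img - wr$image)^2)
  mse_after <- mean((warp(img, est$field) - wr$image)^2)
  expect_lt(mse_after, mse_before)
})

test_that("TRE equals its closed form at landmarks", {
  n <- 64
  z <- matrix(0, n, n)
  fld0 <- displacement_field(z, z)
  lm <- with_seed(4, cbind(stats::runif(20, 5, 60), stats::runif(20, 5, 60)))
  expect_equal(tre(fld0, fld0, lm), 0)
  # constant (3, 4) truth vs zero estimate: 3-4-5 triangle
  fld34 <- displacement_field(matrix(3, n, n), matrix(4, n, n))
  expect_equal(tre(fld34, fld0, lm), 5, tolerance = 1e-12)
  # random fields against a direct recomputation from coordinate lists
  f1 <- displacement_field(with_seed(1, matrix(stats::rnorm(n * n), n)),
                           with_seed(2, matrix(stats::rnorm(n * n), n)))
  f2 <- displacement_field(with_seed(3, matrix(stats::rnorm(n * n), n)),
                           with_seed(4, matrix(stats::rnorm(n * n), n)))
  lmi <- cbind(sample(5:60, 20, TRUE), sample(5:60, 20, TRUE))   # integer voxels
  direct <- mean(sqrt((f1$f[lmi] - f2$f[lmi])^2 + (f1$g[lmi] - f2$g[lmi])^2))
  expect_equal(tre(f1, f2, lmi), direct, tolerance = 1e-10)
  expect_error(tre(f1, f2, cbind(0, 5)), "outside")
})

test_that("regularization weight and pyramid behave monotonically", {
  img <- textured_image(64, seed = 5)
  def <- deformation_spec("rbf_nonrigid", max_displacement = 3, seed = 6)
  wr <- apply_deformation(img, def)
  # kappa: higher weight never increases the field's tree-edge variation
  tv <- vapply(c(0, 0.05, 0.5, 5), function(k) {
    r <- mrf_register(wr$image, img, label_range = 3, kappa = k, levels = 1,
                      block_size = 8)
    sum(abs(diff(r$field$f)) + abs(diff(r$field$g)))
  }, 0)
  expect_true(all(diff(tv) <= 1e-8))
  # pyramid: full-resolution energy non-increasing across levels
  r <- mrf_register(wr$image, img, label_range = 3, kappa = 0.1, levels = 3,
                    block_size = 8)
  le <- r$energy$level_energies
  expect_true(all(diff(le) <= 1e-8 * le[1]))
})
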