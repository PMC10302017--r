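# Shared in-code fixtures and small independent oracles.

psnr_of <- function(test, ref) {
  mse <- mean((test - ref)^2)
  if (mse == 0) Inf else 10 * log10(max(ref)^2 / mse)
}

# a textured random image (every block has structure, so block matching is
# unambiguous)
textured_image <- function(n, seed = 1) {
  with_seed(seed, {
    img <- matrix(stats::rnorm(n * n), n)
    gaussian_blur(img, 1.2)
  })
}

shepp64 <- function() make_shepp_logan(phantom_spec("shepp_logan", 64))

full_mask <- function(n) sampling_mask(matrix(TRUE, n, n))

# random spanning tree on n nodes (edge list), uniform-ish
random_tree <- function(n) {
  perm <- sample(n)
  cbind(perm[2:n], perm[vapply(2:n, function(i) sample.int(i - 1L, 1), 0L)])
}

# independent spanning-tree enumeration via union-find (for MST checks)
spanning_tree_min_cost <- function(n_nodes, edges, costs) {
  m <- nrow(edges)
  best <- Inf
  for (sel in utils::combn(m, n_nodes - 1, simplify = FALSE)) {
    parent <- seq_len(n_nodes)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in sel) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) best <- min(best, sum(costs[sel]))
  }
  best
}

# toy clean volume generator for denoise training fixtures
clean_volume_16 <- function(seed) {
  with_seed(seed, {
    v <- array(stats::rnorm(16^3), c(16, 16, 16))
    for (s in 1:16) v[s, , ] <- gaussian_blur(v[s, , ], 2)
    v <- v - min(v)
    v / max(v)
  })
}
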