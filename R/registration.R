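# Deformable motion estimation by discrete displacement labeling: a 4-neighbor
# block graph is reduced to its minimum spanning tree, on which the
# data + pairwise-regularization energy
#   E(w) = sum_i S(w_i) + kappa * sum_(l,m) R(w_l, w_m)
# is minimized EXACTLY by two-pass dynamic programming, coarse-to-fine over an
# image pyramid. Includes backward warping and target registration error.

#' Build the block-graph minimum spanning tree of an image
#'
#' Pixels are grouped into square blocks (the MRF nodes); 4-neighbor block
#' pairs are connected with edge cost equal to the mean absolute intensity
#' difference between the two blocks, and the minimum spanning tree of that
#' graph is extracted (ties broken lexicographically by edge index, so the
#' result is deterministic).
#'
#' @param image Numeric matrix.
#' @param block_size Block side in pixels; the block grid must be at least
#'   2 x 2.
#' @return An `mrf_graph`: node block coordinates, all neighbor pairs with
#'   costs, the tree edge list, and a pixel-to-node index map.
#' @export
build_mst <- function(image, block_size = 8L) {
  n <- nrow(image); m <- ncol(image)
  block_size <- as.integer(block_size)
  if (n %% block_size != 0 || m %% block_size != 0)
    stop("block_size must divide the image dimensions")
  bi <- n %/% block_size; bj <- m %/% block_size
  if (bi < 2 || bj < 2) stop("degenerate block grid: need at least 2 x 2 blocks")
  nb <- bi * bj
  node_id <- function(i, j) (j - 1L) * bi + i
  # pixel -> node map (column-major blocks)
  pix_i <- (seq_len(n) - 1L) %/% block_size + 1L
  pix_j <- (seq_len(m) - 1L) %/% block_size + 1L
  block_index <- outer(pix_i, pix_j, node_id)
  # 4-neighbor edges with mean-absolute-difference costs
  blocks <- lapply(seq_len(nb), function(id) {
    i <- (id - 1L) %% bi + 1L; j <- (id - 1L) %/% bi + 1L
    image[(i - 1L) * block_size + seq_len(block_size),
          (j - 1L) * block_size + seq_len(block_size)]
  })
  from <- integer(0); to <- integer(0)
  for (j in seq_len(bj)) for (i in seq_len(bi)) {
    if (i < bi) { from <- c(from, node_id(i, j)); to <- c(to, node_id(i + 1L, j)) }
    if (j < bj) { from <- c(from, node_id(i, j)); to <- c(to, node_id(i, j + 1L)) }
  }
  cost <- vapply(seq_along(from),
                 function(e) mean(abs(blocks[[from[e]]] - blocks[[to[e]]])),
                 numeric(1))
  g <- igraph::make_graph(rbind(from, to), n = nb, directed = FALSE)
  # infinitesimal lexicographic perturbation => deterministic tie-break
  eps <- (max(cost) + 1) * 1e-12
  tr <- igraph::mst(g, weights = cost + eps * seq_along(cost))
  te <- igraph::as_edgelist(tr, names = FALSE)
  storage.mode(te) <- "integer"
  tree_cost <- cost[match(paste(pmin(te[, 1], te[, 2]), pmax(te[, 1], te[, 2])),
                          paste(pmin(from, to), pmax(from, to)))]
  structure(list(n_blocks = c(bi, bj), block_size = block_size,
                 edges = cbind(from = from, to = to), edge_costs = cost,
                 tree_edges = te, tree_costs = tree_cost,
                 block_index = block_index),
            class = "mrf_graph")
}

# children/parent arrays for a rooted tree given an edge list
root_tree <- function(tree_edges, n_nodes, root = 1L) {
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree_edges))) {
    a <- tree_edges[e, 1]; b <- tree_edges[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  parent <- integer(n_nodes); parent[root] <- 0L
  order <- integer(n_nodes); order[1] <- root
  seen <- logical(n_nodes); seen[root] <- TRUE
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- order[head]
    for (u in adj[[v]]) if (!seen[u]) {
      tail <- tail + 1L; order[tail] <- u
      parent[u] <- v; seen[u] <- TRUE
    }
    head <- head + 1L
  }
  if (tail != n_nodes) stop("tree edges do not span all nodes")
  list(order = order, parent = parent)
}

# exact min-sum two-pass DP on a tree; returns chosen label index per node and
# the minimum energy. node_costs: n_labels x n_nodes; pair_cost: L x L
tree_dp <- function(node_costs, tree_edges, pair_cost) {
  nl <- nrow(node_costs); nn <- ncol(node_costs)
  rt <- root_tree(tree_edges, nn)
  cost <- node_costs                      # running upward costs
  argmin_tab <- matrix(0L, nl, nn)        # child argmin per parent label
  for (v in rev(rt$order)) {
    p <- rt$parent[v]
    if (p == 0L) next
    tot <- pair_cost + cost[, v]          # L_child x L_parent (column recycling)
    a <- max.col(-t(tot), ties.method = "first")    # argmin over child labels
    argmin_tab[, v] <- a
    cost[, p] <- cost[, p] + tot[cbind(a, seq_len(nl))]
  }
  lab <- integer(nn)
  root <- rt$order[1]
  lab[root] <- which.min(cost[, root])
  for (v in rt$order[-1]) lab[v] <- argmin_tab[lab[rt$parent[v]], v]
  list(labels = lab, energy = min(cost[, root]))
}

# data cost table: sum of squared (or absolute) differences per block per label
mrf_data_costs <- function(fixed, moving, graph, offsets, data_cost = "ssd") {
  n <- nrow(fixed); m <- ncol(fixed)
  qi <- as.vector(row(fixed)); qj <- as.vector(col(fixed))
  bix <- as.vector(graph$block_index)
  nb <- prod(graph$n_blocks)
  nl <- nrow(offsets)
  S <- matrix(0, nl, nb)
  for (l in seq_len(nl)) {
    shifted <- interp_image(moving, qi + offsets[l, 1], qj + offsets[l, 2])
    d <- shifted - as.vector(fixed)
    d <- if (data_cost == "sad") abs(d) else d * d
    S[l, ] <- rowsum(d, bix)[, 1]
  }
  S
}

#' Deformable registration by exact MRF labeling on a spanning tree
#'
#' Estimates a block-wise displacement field aligning `moving` to `fixed`.
#' Each block chooses a discrete 2D displacement from
#' `{-label_range, ..., +label_range}^2` at `label_step` resolution (refined
#' to half the step on the finest pyramid level); the energy - block sum of
#' squared differences plus `kappa` times the squared Euclidean difference of
#' neighboring labels, accumulated over tree edges - is minimized exactly by
#' dynamic programming on the minimum spanning tree. Coarse-to-fine: each
#' level registers the residual after warping `moving` by the upsampled field.
#'
#' @param fixed,moving Same-size numeric matrices.
#' @param graph Optional [build_mst()] graph for single-level registration;
#'   rebuilt per level otherwise.
#' @param label_range Maximum displacement per axis, in that level's voxels.
#' @param label_step Label quantum in voxels.
#' @param kappa Regularization weight (`>= 0`).
#' @param levels Pyramid levels (1 = single scale).
#' @param block_size Block side in pixels.
#' @param data_cost `"ssd"` (default) or `"sad"`.
#' @return List with `field` (a dense [displacement_field()] carrying the
#'   block `labels`) and `energy` (an `energy_breakdown`: `data_term`,
#'   `reg_term`, `total = data_term + reg_term`, `kappa`, plus the per-level
#'   full-resolution energies in `level_energies`).
#' @export
mrf_register <- function(fixed, moving, graph = NULL, label_range = 3,
                         label_step = 1, kappa = 1, levels = 2L,
                         block_size = 8L, data_cost = c("ssd", "sad")) {
  data_cost <- match.arg(data_cost)
  if (!all(dim(fixed) == dim(moving))) stop("images must have the same size")
  n <- nrow(fixed); m <- ncol(fixed)
  f <- matrix(0, n, m); g <- matrix(0, n, m)
  if (label_range == 0) {
    fld <- displacement_field(f, g)
    eb <- energy_breakdown(sum((fixed - moving)^2), 0, kappa)
    return(list(field = fld, energy = eb))
  }
  level_energies <- numeric(levels)
  labs <- NULL; eb <- NULL
  for (lev in seq_len(levels)) {
    s <- 2^(levels - lev)
    step <- if (lev == levels) label_step / 2 else label_step
    offs <- seq(-label_range, label_range, by = step)
    offsets <- as.matrix(expand.grid(di = offs, dj = offs))
    pair_cost <- kappa * (outer(offsets[, 1], offsets[, 1], "-")^2 +
                          outer(offsets[, 2], offsets[, 2], "-")^2)
    fx <- block_average(fixed, s)
    mv <- block_average(warp(moving, displacement_field(f, g)), s)
    gr <- if (lev == 1L && levels == 1L && !is.null(graph)) graph
          else build_mst(fx, block_size = block_size)
    S <- mrf_data_costs(fx, mv, gr, offsets, data_cost)
    dp <- tree_dp(S, gr$tree_edges, pair_cost)
    labs <- dp$labels
    # energy breakdown at this level (identity: total = data + reg)
    dsel <- S[cbind(labs, seq_along(labs))]
    te <- gr$tree_edges
    rsel <- (offsets[labs[te[, 1]], 1] - offsets[labs[te[, 2]], 1])^2 +
            (offsets[labs[te[, 1]], 2] - offsets[labs[te[, 2]], 2])^2
    eb <- energy_breakdown(sum(dsel), kappa * sum(rsel), kappa)
    # accumulate the field at full resolution (level voxels -> full voxels)
    bi <- gr$n_blocks[1]; bj <- gr$n_blocks[2]
    lf <- matrix(offsets[labs, 1], bi, bj) * s
    lg <- matrix(offsets[labs, 2], bi, bj) * s
    f <- f + upsample_bilinear(lf, n, m)
    g <- g + upsample_bilinear(lg, n, m)
    level_energies[lev] <- sum((fixed - warp(moving, displacement_field(f, g)))^2)
  }
  fld <- displacement_field(f, g)
  fld$labels <- labs
  fld$block_f <- lf          # finest-level per-block displacements (voxels)
  fld$block_g <- lg
  fld$label_range <- label_range
  fld$label_step <- label_step
  eb$level_energies <- level_energies
  list(field = fld, energy = eb)
}

#' Energy breakdown record
#'
#' @param data_term,reg_term Non-negative energy components.
#' @param kappa Regularization weight.
#' @return An `energy_breakdown` with `total = data_term + reg_term` exactly.
#' @export
energy_breakdown <- function(data_term, reg_term, kappa) {
  structure(list(data_term = data_term, reg_term = reg_term,
                 total = data_term + reg_term, kappa = kappa),
            class = "energy_breakdown")
}

#' Backward-warp an image by a displacement field
#'
#' `out(x) = image(x + u(x))`, cubic interpolation with reflected boundary;
#' the zero field is the exact identity.
#'
#' @param image Numeric matrix.
#' @param field A [displacement_field()] (dense, same size as `image`).
#' @return Warped matrix.
#' @export
warp <- function(image, field) {
  qi <- as.vector(row(image)) + as.vector(field$f)
  qj <- as.vector(col(image)) + as.vector(field$g)
  matrix(interp_image(image, qi, qj), nrow(image), ncol(image))
}

#' Target registration error at landmarks
#'
#' Mean Euclidean distance between the ground-truth and estimated
#' displacements evaluated at landmark positions (the through-plane component
#' is zero in 2D):
#' `TRE = (1/N) sum_i sqrt((TLx-TDx)^2 + (TLy-TDy)^2 + (TLz-TDz)^2)`.
#'
#' @param truth_field,est_field [displacement_field()] objects on the same
#'   grid.
#' @param landmarks N x 2 matrix of 1-based voxel coordinates (fractional
#'   allowed; fields are interpolated bilinearly).
#' @return TRE in voxels.
#' @export
tre <- function(truth_field, est_field, landmarks) {
  landmarks <- as.matrix(landmarks)
  if (nrow(landmarks) < 1) stop("at least one landmark required")
  n <- nrow(truth_field$f); m <- ncol(truth_field$f)
  if (any(landmarks[, 1] < 1 | landmarks[, 1] > n |
          landmarks[, 2] < 1 | landmarks[, 2] > m))
    stop("landmark outside the field domain")
  df <- interp_image(truth_field$f, landmarks[, 1], landmarks[, 2], "linear") -
        interp_image(est_field$f, landmarks[, 1], landmarks[, 2], "linear")
  dg <- interp_image(truth_field$g, landmarks[, 1], landmarks[, 2], "linear") -
        interp_image(est_field$g, landmarks[, 1], landmarks[, 2], "linear")
  mean(sqrt(df^2 + dg^2))
}
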