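# k-q sampling pattern generators: PROPELLER blade trajectories, Poisson-disc
# subsampling with variable-density profiles, Hermitian partial-Fourier masks,
# radial masks, and the direction-to-blade schedule (one blade per diffusion
# direction with q-space neighbor lists).

#' Non-Cartesian trajectory container
#'
#' @param coords M x 2 matrix of (kx, ky) in cycles/FOV, each within the
#'   half-open Nyquist box \[-0.5, 0.5).
#' @param grid_size Target Cartesian matrix side.
#' @param density_weights Per-sample density-compensation weights (`> 0`);
#'   defaults to uniform.
#' @return A `trajectory` list.
#' @export
trajectory <- function(coords, grid_size, density_weights = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("coords must be an M x 2 matrix")
  if (any(coords < -0.5 | coords >= 0.5))
    stop("trajectory coordinates must lie in [-0.5, 0.5)")
  if (is.null(density_weights)) density_weights <- rep(1, nrow(coords))
  if (any(density_weights <= 0)) stop("density weights must be positive")
  structure(list(coords = coords, grid_size = as.integer(grid_size),
                 density_weights = density_weights),
            class = "trajectory")
}

#' Binary Cartesian sampling mask
#'
#' `fraction_sampled` is always the literal mean of the mask.
#'
#' @param mask Logical matrix on the Cartesian grid.
#' @param hermitian_half Whether every unsampled point's conjugate mirror is
#'   guaranteed present (partial-Fourier construction).
#' @return A `sampling_mask` list with fields `mask`, `fraction_sampled`,
#'   `hermitian_half`.
#' @export
sampling_mask <- function(mask, hermitian_half = FALSE) {
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  structure(list(mask = mask, fraction_sampled = mean(mask),
                 hermitian_half = isTRUE(hermitian_half)),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("sampling_mask %dx%d, fraction %.4f%s\n", nrow(x$mask),
              ncol(x$mask), x$fraction_sampled,
              if (x$hermitian_half) ", hermitian half" else ""))
  invisible(x)
}

#' PROPELLER blade trajectories
#'
#' Each blade is a rectangular strip of `lines_per_blade` parallel
#' phase-encoded lines through the k-space center, sampled at
#' `samples_per_line` points along the readout; blade `b` (1-based) is rotated
#' by `(b-1) * 180 / n_blades` degrees (Cartesian lines are undirected, so
#' increments cover 180 rather than 360 degrees). Samples rotated outside the
#' Nyquist box are discarded.
#'
#' @param n_blades Number of blades (`>= 1`).
#' @param lines_per_blade Phase-encode lines per blade (`<= grid_size`).
#' @param samples_per_line Readout samples per line.
#' @param grid_size Cartesian matrix side.
#' @return List of [trajectory()] objects, one per blade.
#' @export
propeller_blades <- function(n_blades, lines_per_blade, samples_per_line,
                             grid_size) {
  if (n_blades < 1) stop("n_blades must be >= 1")
  if (lines_per_blade > grid_size)
    stop("lines_per_blade (", lines_per_blade, ") exceeds grid_size (",
         grid_size, ")")
  kx <- ((seq_len(samples_per_line) - 1) - floor(samples_per_line / 2)) /
    samples_per_line
  ky <- ((seq_len(lines_per_blade) - 1) - floor(lines_per_blade / 2)) /
    grid_size
  base <- cbind(kx = rep(kx, times = lines_per_blade),
                ky = rep(ky, each = samples_per_line))
  lapply(seq_len(n_blades), function(b) {
    th <- (b - 1) * pi / n_blades
    rot <- cbind(cos(th) * base[, 1] - sin(th) * base[, 2],
                 sin(th) * base[, 1] + cos(th) * base[, 2])
    keep <- rot[, 1] >= -0.5 & rot[, 1] < 0.5 & rot[, 2] >= -0.5 & rot[, 2] < 0.5
    trajectory(rot[keep, , drop = FALSE], grid_size)
  })
}

#' Rasterize a trajectory onto the Cartesian grid
#'
#' Nearest-grid-point binning; used to form on-grid blade masks.
#'
#' @param traj A [trajectory()].
#' @return A [sampling_mask()] on `traj$grid_size`.
#' @export
rasterize_trajectory <- function(traj) {
  n <- traj$grid_size
  c0 <- floor(n / 2)
  i <- round(traj$coords[, 1] * n) + c0 + 1
  j <- round(traj$coords[, 2] * n) + c0 + 1
  keep <- i >= 1 & i <= n & j >= 1 & j <= n
  m <- matrix(FALSE, n, n)
  m[cbind(i[keep], j[keep])] <- TRUE
  sampling_mask(m)
}

#' Density profiles for variable-density Poisson-disc sampling
#'
#' A profile maps normalized k-space radius (0 at DC, 1 at the corner of the
#' Nyquist box) to a relative sampling rate. `uniform_profile` is constant;
#' `variable_density_profile` fully samples a low-frequency core (infinite
#' rate, i.e. zero exclusion radius) and boosts a high-frequency band, the
#' band where edge information lives.
#'
#' @param core_frac Fully sampled core radius as a fraction of k-max.
#' @param boost_start Radius where the high-frequency boost begins.
#' @param boost Rate multiplier in the boosted band.
#' @return A function of normalized radius.
#' @export
uniform_profile <- function() function(rho) rep(1, length(rho))

#' @rdname uniform_profile
#' @export
variable_density_profile <- function(core_frac = 0.08, boost_start = 0.6,
                                     boost = 2) {
  function(rho) ifelse(rho <= core_frac, Inf,
                       ifelse(rho >= boost_start, boost, 1))
}

#' Poisson-disc subsampling of a mask or trajectory support
#'
#' Dart throwing in a seeded random order: a candidate is retained when its
#' distance to every previously retained sample is at least the local
#' exclusion radius `r_min / profile(|k|)` (the density-warped metric; an
#' infinite profile rate, as in the fully sampled core, means no exclusion).
#' Acceptance decisions do not depend on `target_fraction`, so masks drawn at
#' increasing fractions under the same seed are nested.
#'
#' @param x A [sampling_mask()], logical matrix, or [trajectory()] giving the
#'   candidate support.
#' @param target_fraction Fraction of the support to retain, in (0, 1\].
#' @param r_min Minimum pairwise distance in grid pixels (`>= 0`).
#' @param density_profile Profile function from [uniform_profile()] /
#'   [variable_density_profile()]; default uniform.
#' @param seed Integer RNG seed.
#' @return A [sampling_mask()]; errors if the (fraction, r_min) pair is
#'   infeasible (achieved count below 90% of target after exhausting all
#'   candidates).
#' @export
poisson_subsample <- function(x, target_fraction, r_min,
                              density_profile = uniform_profile(), seed = 1L) {
  if (target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must be in (0, 1]")
  if (inherits(x, "trajectory")) x <- rasterize_trajectory(x)
  m <- if (inherits(x, "sampling_mask")) x$mask else matrix(as.logical(x), nrow(x), ncol(x))
  n <- nrow(m); mm <- ncol(m)
  idx <- which(m, arr.ind = TRUE)
  nc <- nrow(idx)
  if (nc == 0) stop("empty candidate support")
  target <- max(1L, round(target_fraction * nc))
  c0 <- floor(n / 2) + 1; c1 <- floor(mm / 2) + 1
  kmax <- sqrt((n / 2)^2 + (mm / 2)^2)
  rho <- sqrt((idx[, 1] - c0)^2 + (idx[, 2] - c1)^2) / kmax
  rate <- density_profile(rho)
  rloc <- r_min / rate                        # Inf rate -> 0 radius
  rloc[!is.finite(rloc)] <- 0
  # rate-weighted priority sampling without replacement (u^(1/rate)): higher
  # local rate -> earlier retention; infinite-rate core goes first
  ord <- with_seed(seed, {
    u <- stats::runif(nc)
    prio <- ifelse(is.finite(rate), u^(1 / rate), 1)
    order(prio, decreasing = TRUE)
  })
  if (r_min <= 0) {
    sel <- ord[seq_len(target)]
    out <- matrix(FALSE, n, mm)
    out[idx[sel, , drop = FALSE]] <- TRUE
    return(sampling_mask(out))
  }
  cell <- max(rloc, r_min)
  grid <- new.env(hash = TRUE, parent = emptyenv())
  acc_i <- numeric(0); acc_j <- numeric(0); acc_r <- numeric(0)
  taken <- integer(0)
  for (cand in ord) {
    pi_ <- idx[cand, 1]; pj <- idx[cand, 2]; pr <- rloc[cand]
    ci <- floor(pi_ / cell); cj <- floor(pj / cell)
    ok <- TRUE
    for (a in -1:1) {
      for (b in -1:1) {
        key <- paste0(ci + a, ",", cj + b)
        members <- grid[[key]]
        if (!is.null(members)) {
          d2 <- (acc_i[members] - pi_)^2 + (acc_j[members] - pj)^2
          lim <- pmin(acc_r[members], pr)
          if (any(d2 < lim^2)) { ok <- FALSE; break }
        }
      }
      if (!ok) break
    }
    if (ok) {
      acc_i <- c(acc_i, pi_); acc_j <- c(acc_j, pj); acc_r <- c(acc_r, pr)
      taken <- c(taken, cand)
      key <- paste0(ci, ",", cj)
      grid[[key]] <- c(grid[[key]], length(acc_i))
      if (length(taken) >= target) break
    }
  }
  if (length(taken) < ceiling(0.9 * target))
    stop(sprintf(
      "infeasible (target_fraction, r_min): achieved %d of %d target samples",
      length(taken), target))
  out <- matrix(FALSE, n, mm)
  out[idx[taken, , drop = FALSE]] <- TRUE
  sampling_mask(out)
}

#' Asymmetric-echo (partial Fourier) restriction of a mask
#'
#' Keeps the first `ceil(fraction * N)` phase-encode rows: one half-plane plus
#' the full symmetric center band. Every removed point's conjugate mirror
#' (modulo-N negation of 0-based indices) lies in the kept row set, so the
#' removed region is recoverable from Hermitian symmetry wherever the input
#' mask sampled the mirror.
#'
#' @param mask A [sampling_mask()].
#' @param fraction Kept fraction of phase encodes, in (0.5, 1\].
#' @return A [sampling_mask()] with `hermitian_half = TRUE` (unless
#'   `fraction = 1`, which returns the input unchanged).
#' @export
partial_fourier_mask <- function(mask, fraction) {
  if (!inherits(mask, "sampling_mask")) stop("mask must be a sampling_mask")
  if (fraction <= 0.5)
    stop("fraction must exceed 0.5: the symmetric center band is unrecoverable")
  if (fraction > 1) stop("fraction must be <= 1")
  if (fraction == 1) return(mask)
  n <- nrow(mask$mask)
  keep_rows <- seq_len(ceiling(fraction * n))
  m <- mask$mask
  m[setdiff(seq_len(n), keep_rows), ] <- FALSE
  sampling_mask(m, hermitian_half = TRUE)
}

#' Radial sampling mask
#'
#' `n_lines` diameters through the k-space center, equally spaced by
#' `aperture_deg / n_lines` starting at 0 degrees (so a 180-degree aperture
#' with n lines gives 180/n spacing), rasterized at half-pixel steps.
#'
#' @param n_lines Number of lines (`>= 1`).
#' @param aperture_deg Angular aperture in (0, 180\].
#' @param grid_size Matrix side.
#' @return A [sampling_mask()]; the DC pixel is always set.
#' @export
radial_mask <- function(n_lines, aperture_deg, grid_size) {
  if (n_lines < 1) stop("n_lines must be >= 1")
  if (aperture_deg <= 0 || aperture_deg > 180)
    stop("aperture_deg must be in (0, 180]")
  n <- grid_size
  c0 <- floor(n / 2) + 1
  m <- matrix(FALSE, n, n)
  t <- seq(-n / 2, n / 2, by = 0.5)
  for (l in seq_len(n_lines)) {
    th <- (l - 1) * aperture_deg / n_lines * pi / 180
    i <- round(c0 + t * cos(th)); j <- round(c0 + t * sin(th))
    keep <- i >= 1 & i <= n & j >= 1 & j <= n
    m[cbind(i[keep], j[keep])] <- TRUE
  }
  m[c0, c0] <- TRUE
  sampling_mask(m)
}

#' Direction-to-blade schedule with q-space neighbor lists
#'
#' One blade per diffusion direction (the rotating single-shot acquisition):
#' direction `d` (1-based) gets blade angle `(d-1) * 180 / n_directions` mod
#' 180, and its neighbor list holds the `neighbor_window` angularly nearest
#' directions on the q-sphere (antipodally symmetric distance
#' `acos(|g_d . g_n|)`; ties broken by lowest index).
#'
#' @param n_directions Number of diffusion directions (`>= 1`).
#' @param n_blades Number of distinct blade orientations available.
#' @param neighbor_window Neighbors shared per direction
#'   (`< n_directions`).
#' @return A `q_scheme` list: `q_vectors` (3 x n), `blade_angles` (degrees),
#'   `neighbors` (list of index vectors), `neighbor_window`.
#' @export
kq_schedule <- function(n_directions, n_blades = n_directions,
                        neighbor_window = 2L) {
  if (n_directions < 1) stop("n_directions must be >= 1")
  if (neighbor_window >= n_directions)
    stop("neighbor_window must be smaller than n_directions")
  g <- fibonacci_directions(n_directions)
  angles <- ((seq_len(n_directions) - 1) * 180 / n_directions) %% 180
  neighbors <- lapply(seq_len(n_directions), function(d) {
    if (neighbor_window == 0) return(integer(0))
    dots <- abs(colSums(g * g[, d]))
    dist <- acos(pmin(1, dots))
    dist[d] <- Inf
    order(dist, seq_len(n_directions))[seq_len(neighbor_window)]
  })
  structure(list(q_vectors = g, blade_angles = angles, neighbors = neighbors,
                 neighbor_window = as.integer(neighbor_window),
                 n_blades = as.integer(n_blades)),
            class = "q_scheme")
}
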