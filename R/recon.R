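# Sparse k-space to low-resolution image reconstruction: NUFFT forward/adjoint
# via direct evaluation of the non-uniform Fourier sum (separable in kx/ky to
# keep memory at O(M*N)), zero filling, Hermitian (partial-Fourier)
# completion, POCS phase-constrained reconstruction, a data-consistency
# cascade with a pluggable image refiner, and the neighbor-direction (RoSA)
# composite reconstruction.

#' k-space data container
#'
#' On-grid data: `values` is a full complex matrix with zeros off the mask
#' support. Off-grid data: `values` is a complex vector bound to a
#' [trajectory()].
#'
#' @param values Complex matrix (on-grid) or vector (off-grid).
#' @param support A [sampling_mask()] or [trajectory()].
#' @return A `kspace` list with fields `values`, `support`, `grid_size`.
#' @export
kspace <- function(values, support) {
  if (inherits(support, "sampling_mask")) {
    if (!all(dim(values) == dim(support$mask)))
      stop("values and mask dimensions differ")
    values[!support$mask] <- 0
    gs <- nrow(support$mask)
  } else if (inherits(support, "trajectory")) {
    if (length(values) != nrow(support$coords))
      stop("one value per trajectory sample required")
    gs <- support$grid_size
  } else stop("support must be a sampling_mask or trajectory")
  if (!all(is.finite(Re(values)) & is.finite(Im(values))))
    stop("k-space values must be finite")
  structure(list(values = values, support = support, grid_size = gs),
            class = "kspace")
}

#' Measure on-grid k-space from an image
#'
#' @param img Numeric or complex matrix.
#' @param mask A [sampling_mask()] of the same size.
#' @return A [kspace()] holding `fft2c(img)` restricted to the mask.
#' @export
kspace_from_image <- function(img, mask) {
  kspace(fft2c(img) * mask$mask, mask)
}

#' Reconstruction configuration
#'
#' @param n_dc_iterations Data-consistency cascade iterations (`>= 1`).
#' @param dc_weight Data-consistency weight in (0, 1\]; 1 means hard
#'   replacement of measured k-space samples.
#' @param pocs_iterations POCS iterations (`>= 1`).
#' @param phase_ref_radius Low-frequency phase-reference radius as a fraction
#'   of k-max.
#' @param denoiser_hook Image-to-image refiner used inside the cascade
#'   (applied to real and imaginary channels separately); default identity.
#' @return A `recon_config` list.
#' @export
recon_config <- function(n_dc_iterations = 10L, dc_weight = 1,
                         pocs_iterations = 8L, phase_ref_radius = 0.12,
                         denoiser_hook = NULL) {
  if (n_dc_iterations < 1 || pocs_iterations < 1) stop("iteration counts must be >= 1")
  if (dc_weight <= 0 || dc_weight > 1) stop("dc_weight must be in (0, 1]")
  structure(list(n_dc_iterations = as.integer(n_dc_iterations),
                 dc_weight = dc_weight,
                 pocs_iterations = as.integer(pocs_iterations),
                 phase_ref_radius = phase_ref_radius,
                 denoiser_hook = denoiser_hook %||% identity),
            class = "recon_config")
}

# separable phase matrices for the direct non-uniform DFT
nufft_phase <- function(traj, n) {
  p <- (seq_len(n) - 1) - floor(n / 2)
  list(S = exp(-2i * pi * outer(traj$coords[, 1], p)),
       T = exp(-2i * pi * outer(traj$coords[, 2], p)))
}

#' Non-uniform discrete Fourier transform (type 2/1 pair)
#'
#' Direct evaluation of the Fourier sum at arbitrary trajectory points
#' (exact; the pair satisfies the adjoint identity to machine precision).
#' `forward` maps an N x N image to complex samples at the trajectory;
#' `adjoint` is the exact conjugate-transpose map back to the grid, with
#' optional density-compensation weighting for gridding-style reconstruction.
#'
#' @param x Image matrix (forward) or complex sample vector (adjoint).
#' @param traj A [trajectory()].
#' @param direction `"forward"` or `"adjoint"`.
#' @param density_compensate Apply `traj$density_weights` before the adjoint
#'   (breaks the pure adjoint identity; used for image reconstruction).
#' @return Complex vector (forward) or complex matrix (adjoint).
#' @export
nufft <- function(x, traj, direction = c("forward", "adjoint"),
                  density_compensate = FALSE) {
  direction <- match.arg(direction)
  n <- traj$grid_size
  ph <- nufft_phase(traj, n)
  if (direction == "forward") {
    if (!is.matrix(x) || nrow(x) != n || ncol(x) != n)
      stop("image size does not match trajectory grid")
    # s_m = sum_uv x[u,v] S[m,u] T[m,v]
    b <- x %*% t(ph$T)                       # N x M
    rowSums(ph$S * t(b))
  } else {
    if (length(x) != nrow(traj$coords))
      stop("sample count does not match trajectory")
    s <- if (density_compensate) x * traj$density_weights else x
    t(Conj(ph$S)) %*% (s * Conj(ph$T))       # N x N
  }
}

#' Zero-filled reconstruction with optional matrix doubling
#'
#' Embeds the centered k-space in a `factor`-times larger zero matrix and
#' inverse transforms: sinc interpolation of the image (the pixel count
#' doubles, e.g. 256 to 512, without adding information).
#'
#' @param ksp A [kspace()] with on-grid support.
#' @param factor 1 (plain inverse transform) or 2.
#' @return Magnitude image of side `factor * N`.
#' @export
zero_fill <- function(ksp, factor = 1L) {
  if (!inherits(ksp$support, "sampling_mask"))
    stop("zero_fill requires on-grid k-space; grid the data first")
  if (!factor %in% c(1L, 2L)) stop("factor must be 1 or 2")
  k <- ksp$values
  n <- nrow(k)
  if (factor == 1L) return(Mod(ifft2c(k)))
  n2 <- 2L * n
  big <- matrix(0i, n2, n2)
  off <- floor(n2 / 2) - floor(n / 2)
  big[off + seq_len(n), off + seq_len(n)] <- k
  Mod(ifft2c(big)) * factor^2
}

#' Hermitian (conjugate-symmetry) completion of half k-space
#'
#' Every unsampled point `(i, j)` (0-based) is filled with the conjugate of
#' the value at its mirror `((-i) mod N, (-j) mod N)`; sampled values are
#' untouched. For a real-valued object this recovers the missing half
#' exactly. Points whose mirror is also unsampled are left zero and counted
#' in the `unrecoverable` attribute.
#'
#' @param ksp A [kspace()] with on-grid support.
#' @param mask The sampling mask (must have `hermitian_half` set).
#' @return A [kspace()] on the full grid, with attribute `unrecoverable`.
#' @export
hermitian_fill <- function(ksp, mask = ksp$support) {
  if (!inherits(mask, "sampling_mask")) stop("mask must be a sampling_mask")
  if (!mask$hermitian_half)
    stop("hermitian_fill requires a mask flagged hermitian_half")
  k <- ksp$values
  n <- nrow(k); m <- ncol(k)
  miss <- which(!mask$mask, arr.ind = TRUE)
  mi <- mirror_index(miss[, 1], n)
  mj <- mirror_index(miss[, 2], m)
  have <- mask$mask[cbind(mi, mj)]
  k[miss[have, , drop = FALSE]] <- Conj(k[cbind(mi[have], mj[have])])
  full <- mask$mask
  full[miss[have, , drop = FALSE]] <- TRUE
  out <- kspace(k, sampling_mask(full))
  attr(out, "unrecoverable") <- sum(!have)
  out
}

#' Edge-preserving 3x3 median refiner
#'
#' An analytic image refiner suitable as the cascade's `denoiser_hook`:
#' suppresses incoherent aliasing speckle while preserving edges (replicated
#' boundary).
#'
#' @param x Numeric matrix.
#' @return Median-filtered matrix of the same size.
#' @export
median_filter3 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  cl <- function(p, nn) pmin(pmax(p, 1), nn)
  arr <- array(0, c(n, m, 9))
  t <- 0
  for (a in -1:1) for (b in -1:1) {
    t <- t + 1
    arr[, , t] <- x[cl(seq_len(n) + a, n), cl(seq_len(m) + b, m)]
  }
  apply(arr, c(1, 2), stats::median)
}

# smooth radial low-pass window for the POCS phase reference
phase_ref_window <- function(n, m, radius_frac) {
  c0 <- floor(n / 2) + 1; c1 <- floor(m / 2) + 1
  kmax <- min(n, m) / 2
  r <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(m) - c1)^2, "+")) / kmax
  w <- ifelse(r < radius_frac, cos(pi * r / (2 * radius_frac))^2, 0)
  w
}

#' POCS partial-Fourier reconstruction
#'
#' Alternating projections exploiting the slowly varying object phase: a
#' smooth reference phase is estimated from the symmetric low-frequency band
#' (windowed, radius `phase_ref_radius` of k-max), then the iteration
#' alternates (a) forcing the image phase onto the reference and (b) restoring
#' the measured k-space samples. The final step is the data projection, so
#' measured entries of the output k-space equal the input data exactly.
#'
#' @param ksp A [kspace()] with on-grid support.
#' @param mask The sampling mask.
#' @param config A [recon_config()].
#' @return Magnitude image with attribute `residuals` (per-iteration update
#'   norms).
#' @export
pocs_pf_recon <- function(ksp, mask = ksp$support, config = recon_config()) {
  k <- ksp$values
  n <- nrow(k); m <- ncol(k)
  w <- phase_ref_window(n, m, config$phase_ref_radius)
  if (!any(mask$mask & w > 0)) stop("empty center band: cannot estimate phase")
  phase <- Arg(ifft2c(k * w))
  ephase <- exp(1i * phase)
  # conjugate-symmetry initialization (exact already for zero-phase objects)
  x <- ifft2c(if (mask$hermitian_half) hermitian_fill(ksp, mask)$values else k)
  res <- numeric(config$pocs_iterations)
  for (it in seq_len(config$pocs_iterations)) {
    xp <- Re(x * Conj(ephase)) * ephase      # phase projection
    kk <- fft2c(xp)
    kk[mask$mask] <- k[mask$mask]            # data projection
    xn <- ifft2c(kk)
    res[it] <- sqrt(sum(Mod(xn - x)^2))
    x <- xn
  }
  out <- Mod(x)
  attr(out, "residuals") <- res
  attr(out, "kspace") <- fft2c(x)
  out
}

#' Data-consistency cascade reconstruction
#'
#' The unrolled iterative scheme `x <- DC(denoise(x))`: each iteration applies
#' the configured image refiner (to real and imaginary channels separately)
#' and then re-imposes the measured k-space data at sampled positions with
#' weight `dc_weight` (1 = hard replacement). A learned refiner recovers the
#' recurrent-network reading of the iteration; the default identity refiner
#' reduces it to pure data consistency.
#'
#' @param ksp A [kspace()] with on-grid support.
#' @param mask The sampling mask.
#' @param config A [recon_config()].
#' @return Magnitude image with attribute `residuals`.
#' @export
dc_cascade_recon <- function(ksp, mask = ksp$support, config = recon_config()) {
  k <- ksp$values
  hook <- config$denoiser_hook
  lam <- config$dc_weight
  x <- ifft2c(k)
  res <- numeric(config$n_dc_iterations)
  init <- NULL
  for (it in seq_len(config$n_dc_iterations)) {
    xd <- hook(Re(x)) + 1i * hook(Im(x))
    kk <- fft2c(xd)
    kk[mask$mask] <- (1 - lam) * kk[mask$mask] + lam * k[mask$mask]
    xn <- ifft2c(kk)
    res[it] <- sqrt(sum(Mod(xn - x)^2))
    if (it == 1) init <- res[1]
    if (it > 1 && init > 0 && res[it] > 10 * init)
      stop("dc_cascade_recon diverged: residual ", res[it],
           " exceeds 10x the initial residual")
    x <- xn
  }
  out <- Mod(x)
  attr(out, "residuals") <- res
  attr(out, "kspace") <- fft2c(x)
  out
}

#' Neighbor-direction composite (RoSA) reconstruction
#'
#' Each diffusion direction acquires a single blade; directions with nearby
#' q-vectors show near-identical diffusion contrast, so k-space positions a
#' direction did not sample are borrowed from its q-space neighbors' blades.
#' Own-blade data are kept exactly; borrowed values are weighted by
#' `cos^2` of the angular distance between q-vectors, normalized over
#' contributors.
#'
#' @param stacks A `dwi_stack` of per-direction zero-filled images (metadata
#'   and fallback source), or `NULL`.
#' @param kspaces List of on-grid [kspace()] objects, one blade per direction.
#' @param scheme A [kq_schedule()] q-scheme with neighbor lists.
#' @return A `dwi_stack` whose `images` are the composite magnitude
#'   reconstructions.
#' @export
rosa_composite <- function(stacks, kspaces, scheme) {
  nd <- length(kspaces)
  if (nd != length(scheme$neighbors))
    stop("one blade k-space per direction required")
  n <- kspaces[[1]]$grid_size
  g <- scheme$q_vectors
  images <- array(0, c(n, n, nd))
  for (d in seq_len(nd)) {
    own <- kspaces[[d]]
    ownmask <- own$support$mask
    comp <- own$values
    nbs <- scheme$neighbors[[d]]
    if (length(nbs) == 0) {
      if (!all(ownmask))
        warning("direction ", d, ": empty neighbor set with incomplete ",
                "coverage; falling back to own data")
    } else {
      acc <- matrix(0i, n, n)
      wsum <- matrix(0, n, n)
      for (nb in nbs) {
        w <- min(1, abs(sum(g[, d] * g[, nb])))^2   # cos^2 angular weight
        nbmask <- kspaces[[nb]]$support$mask
        use <- (!ownmask) & nbmask
        acc[use] <- acc[use] + w * kspaces[[nb]]$values[use]
        wsum[use] <- wsum[use] + w
      }
      fill <- wsum > 0
      comp[fill] <- acc[fill] / wsum[fill]
    }
    images[, , d] <- Mod(ifft2c(comp))
  }
  structure(list(images = images,
                 bvecs = if (!is.null(stacks)) stacks$bvecs else g,
                 bval = if (!is.null(stacks)) stacks$bval else NA_real_,
                 s0 = if (!is.null(stacks)) stacks$s0 else NULL),
            class = "dwi_stack")
}
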