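# Synthetic test-object generators: the analytic Shepp-Logan phantom, a
# diffusion-tensor DWI phantom whose contrast varies smoothly across q-space
# directions, and the degradation operators (deformation, blur, decimation,
# Gaussian/Rician noise) that produce low-resolution inputs from them.

#' Phantom specification
#'
#' @param name `"shepp_logan"` or `"dwi_tensor"`.
#' @param matrix_size Pixels per side; must be a power of 2, at least 16.
#' @param n_directions Number of q-space diffusion directions (`>= 1`).
#' @param b_value Diffusion weighting in s/mm^2 (`>= 0`).
#' @param seed Integer RNG seed; a fixed seed gives bit-identical output.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(name = c("shepp_logan", "dwi_tensor"), matrix_size = 64,
                         n_directions = 1L, b_value = 1000, seed = 1L) {
  name <- match.arg(name)
  stopifnot_power_of_two(matrix_size, "matrix_size")
  if (n_directions < 1) stop("n_directions must be >= 1")
  if (b_value < 0) stop("b_value must be non-negative")
  structure(list(name = name, matrix_size = as.integer(matrix_size),
                 n_directions = as.integer(n_directions),
                 b_value = b_value, seed = as.integer(seed)),
            class = "phantom_spec")
}

# the standard modified 10-ellipse table: intensity, a, b, x0, y0, phi (deg)
shepp_logan_ellipses <- function() {
  matrix(c(
     1.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.80, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.20, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.20, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.10, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.10, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.10, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.10, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.10, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.10, 0.0230, 0.0460,  0.06, -0.6050,   0), ncol = 6, byrow = TRUE,
    dimnames = list(NULL, c("A", "a", "b", "x0", "y0", "phi")))
}

# normalized pixel coordinates: 0-based index i maps to (i - N/2) * 2/N, so the
# pixel at index N/2 sits exactly at 0 (consistent with the centered-FFT DC)
phantom_coords <- function(n) ((seq_len(n) - 1) - n / 2) * (2 / n)

#' Analytic Shepp-Logan phantom
#'
#' Evaluates the standard modified 10-ellipse head phantom on the requested
#' grid. Intensities lie in \[0, 1\] and the background is exactly 0.
#'
#' @param spec A [phantom_spec()] with `name = "shepp_logan"`.
#' @return Numeric `matrix_size` x `matrix_size` matrix; rows index x,
#'   columns index y on \[-1, 1).
#' @export
make_shepp_logan <- function(spec) {
  if (!inherits(spec, "phantom_spec") || spec$name != "shepp_logan")
    stop("make_shepp_logan requires a phantom_spec with name 'shepp_logan'")
  n <- spec$matrix_size
  x <- phantom_coords(n)
  xg <- outer(x, rep(1, n)); yg <- outer(rep(1, n), x)
  img <- matrix(0, n, n)
  e <- shepp_logan_ellipses()
  for (k in seq_len(nrow(e))) {
    phi <- e[k, "phi"] * pi / 180
    dx <- xg - e[k, "x0"]; dy <- yg - e[k, "y0"]
    u <- cos(phi) * dx + sin(phi) * dy
    v <- -sin(phi) * dx + cos(phi) * dy
    img <- img + e[k, "A"] * ((u / e[k, "a"])^2 + (v / e[k, "b"])^2 <= 1)
  }
  pmax(img, 0)   # clear float dust where ellipse intensities cancel exactly
}

#' Quasi-uniform diffusion directions on the unit hemisphere
#'
#' Fibonacci-lattice points on the upper hemisphere (DWI directions are
#' antipodally symmetric, so a hemisphere covers q-space).
#'
#' @param n Number of directions.
#' @return 3 x n matrix of unit column vectors.
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 1
  z <- (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Diffusion-tensor DWI phantom
#'
#' A three-tissue-class mono-exponential tensor phantom
#' `S = S0 * exp(-b g' D g)`: an isotropic (CSF-like) outer ring, an annulus of
#' circumferential fibers (principal eigenvector tangential), and a central
#' band of linear fibers along x. Because the signal depends smoothly on the
#' direction `g`, images for nearby q-space directions are strongly
#' correlated - the redundancy that neighbor-direction sharing exploits.
#'
#' @param spec A [phantom_spec()] with `name = "dwi_tensor"`.
#' @param lambda_par,lambda_perp Principal/transverse tensor eigenvalues in
#'   mm^2/s; equal values give an isotropic tensor everywhere.
#' @param d_iso Isotropic diffusivity of the outer ring (mm^2/s).
#' @return A `dwi_stack`: list with `images` (N x N x n_directions array),
#'   `bvecs` (3 x n_directions), `bval`, and `s0` (the b = 0 image).
#' @export
make_dwi_phantom <- function(spec, lambda_par = 1.7e-3, lambda_perp = 0.3e-3,
                             d_iso = 2.5e-3) {
  if (!inherits(spec, "phantom_spec") || spec$name != "dwi_tensor")
    stop("make_dwi_phantom requires a phantom_spec with name 'dwi_tensor'")
  if (spec$b_value < 0) stop("b_value must be non-negative")
  n <- spec$matrix_size
  x <- phantom_coords(n)
  xg <- outer(x, rep(1, n)); yg <- outer(rep(1, n), x)
  rad <- sqrt(xg^2 + yg^2)
  ring  <- rad <= 0.92 & rad > 0.72                    # isotropic CSF-like
  band  <- abs(yg) < 0.18 & abs(xg) <= 0.55            # linear fibers along x
  annul <- rad <= 0.72 & !band                         # circumferential fibers
  s0 <- 1.0 * ring + 0.9 * band + 0.8 * annul
  # per-voxel principal direction e1 (3-vector); tensor is
  # lambda_perp * I + (lambda_par - lambda_perp) * e1 e1'
  theta <- atan2(yg, xg)
  e1x <- -sin(theta) * annul + 1 * band
  e1y <-  cos(theta) * annul
  g <- fibonacci_directions(spec$n_directions)
  images <- array(0, c(n, n, spec$n_directions))
  for (d in seq_len(spec$n_directions)) {
    dot <- e1x * g[1, d] + e1y * g[2, d]               # e1z = 0 in-plane
    adc <- d_iso * ring + (lambda_perp + (lambda_par - lambda_perp) * dot^2) *
      (annul | band)
    images[, , d] <- s0 * exp(-spec$b_value * adc)
  }
  structure(list(images = images, bvecs = g, bval = spec$b_value, s0 = s0),
            class = "dwi_stack")
}

#' Deformation specification
#'
#' @param kind `"affine"` (rotation + shift) or `"rbf_nonrigid"` (smooth random
#'   field from a linear combination of Gaussian radial basis functions).
#' @param max_displacement Peak displacement magnitude in voxels.
#' @param rotation_deg Affine rotation about the image center, degrees.
#' @param subpixel_shift Length-2 translation in voxels (may be fractional).
#' @param control_points Number of RBF control points.
#' @param rbf_sigma RBF width as a fraction of the image side.
#' @param seed Integer RNG seed for the RBF weights.
#' @return A `deformation_spec` list.
#' @export
deformation_spec <- function(kind = c("rbf_nonrigid", "affine"),
                             max_displacement = 3, rotation_deg = 0,
                             subpixel_shift = c(0, 0), control_points = 6L,
                             rbf_sigma = 0.18, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, max_displacement = max_displacement,
                 rotation_deg = rotation_deg, subpixel_shift = subpixel_shift,
                 control_points = as.integer(control_points),
                 rbf_sigma = rbf_sigma, seed = as.integer(seed)),
            class = "deformation_spec")
}

#' Dense displacement field container
#'
#' @param f,g Matrices of per-pixel displacements along rows / columns
#'   (voxels); the through-plane component is identically 0 in 2D.
#' @return A `displacement_field` list.
#' @export
displacement_field <- function(f, g) {
  stopifnot(all(dim(f) == dim(g)))
  structure(list(f = f, g = g), class = "displacement_field")
}

# build the dense ground-truth field for a deformation_spec on an n x m grid
deformation_field <- function(def, n, m) {
  if (def$kind == "affine") {
    th <- def$rotation_deg * pi / 180
    ci <- (n + 1) / 2; cj <- (m + 1) / 2
    ig <- outer(seq_len(n), rep(1, m)); jg <- outer(rep(1, n), seq_len(m))
    di <- ig - ci; dj <- jg - cj
    f <- (cos(th) * di - sin(th) * dj) - di + def$subpixel_shift[1]
    g <- (sin(th) * di + cos(th) * dj) - dj + def$subpixel_shift[2]
  } else {
    fld <- with_seed(def$seed, {
      cp_i <- stats::runif(def$control_points, 0.15 * n, 0.85 * n)
      cp_j <- stats::runif(def$control_points, 0.15 * m, 0.85 * m)
      wf <- stats::rnorm(def$control_points)
      wg <- stats::rnorm(def$control_points)
      list(cp_i = cp_i, cp_j = cp_j, wf = wf, wg = wg)
    })
    s2 <- (def$rbf_sigma * n)^2
    ig <- outer(seq_len(n), rep(1, m)); jg <- outer(rep(1, n), seq_len(m))
    f <- matrix(0, n, m); g <- matrix(0, n, m)
    for (k in seq_len(def$control_points)) {
      phi <- exp(-((ig - fld$cp_i[k])^2 + (jg - fld$cp_j[k])^2) / (2 * s2))
      f <- f + fld$wf[k] * phi
      g <- g + fld$wg[k] * phi
    }
    peak <- max(sqrt(f^2 + g^2))
    if (peak > 0) {
      f <- f * def$max_displacement / peak
      g <- g * def$max_displacement / peak
    }
  }
  if (max(abs(c(f, g))) >= min(n, m))
    stop("deformation displacement exceeds the image extent")
  displacement_field(f, g)
}

#' Warp an image by a known deformation, returning the ground-truth field
#'
#' The warped image is `image(x + u(x))` (backward warping, cubic
#' interpolation, reflected boundary); the returned field `u` is the exact
#' ground truth used for target-registration-error evaluation.
#'
#' @param image Numeric matrix with finite entries.
#' @param def A [deformation_spec()].
#' @return List with `image` (warped matrix) and `field`
#'   (a [displacement_field()]).
#' @export
apply_deformation <- function(image, def) {
  if (!all(is.finite(image))) stop("image must be finite")
  fld <- deformation_field(def, nrow(image), ncol(image))
  list(image = warp(image, fld), field = fld)
}

#' Degradation specification
#'
#' The low-resolution observation model `I_B = k_M * I_S + N`: Gaussian blur
#' standing in for the motion-determined kernel, integer decimation, then
#' additive noise. The default noise level corresponds to a standard deviation
#' of 25 on a 0-255 intensity scale, expressed here on the unit scale.
#'
#' @param blur_sigma Gaussian kernel std in pixels.
#' @param downsample_factor Integer decimation factor `r >= 1`.
#' @param noise_sigma Noise std in the image's intensity units (`>= 0`).
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param motion Optional [deformation_spec()] applied before blurring.
#' @return A `degradation_spec` list.
#' @export
degradation_spec <- function(blur_sigma = 1, downsample_factor = 2L,
                             noise_sigma = 25 / 255,
                             noise_model = c("gaussian", "rician"),
                             motion = NULL) {
  noise_model <- match.arg(noise_model)
  if (downsample_factor < 1) stop("downsample_factor must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  structure(list(blur_sigma = blur_sigma,
                 downsample_factor = as.integer(downsample_factor),
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 motion = motion),
            class = "degradation_spec")
}

#' Degrade a high-resolution image to a low-resolution observation
#'
#' Applies, in order: optional motion, Gaussian blur, block-average decimation
#' by `downsample_factor`, and additive Gaussian or Rician noise. With all
#' parameters at identity settings this is the identity map.
#'
#' @param image Numeric matrix; `downsample_factor` must divide its size.
#' @param deg A [degradation_spec()].
#' @param seed Integer seed for the noise draw.
#' @return The degraded low-resolution matrix.
#' @export
degrade_to_lr <- function(image, deg, seed = 1L) {
  if (!inherits(deg, "degradation_spec")) stop("deg must be a degradation_spec")
  x <- image
  if (!is.null(deg$motion)) x <- apply_deformation(x, deg$motion)$image
  x <- gaussian_blur(x, deg$blur_sigma)
  x <- block_average(x, deg$downsample_factor)
  if (deg$noise_sigma > 0) {
    if (deg$noise_model == "gaussian") {
      x <- x + with_seed(seed, matrix(stats::rnorm(length(x), 0, deg$noise_sigma),
                                      nrow(x), ncol(x)))
    } else {
      x <- add_rician_noise(x, deg$noise_sigma, seed)
    }
  }
  x
}

#' Add Rician noise to a magnitude image
#'
#' Models magnitude-MRI noise: `sqrt((x + n1)^2 + n2^2)` with `n1`, `n2`
#' independent Gaussian(0, sigma). In the zero-signal limit the output is
#' Rayleigh with mean `sigma * sqrt(pi/2)`; for signal much larger than sigma
#' it approaches additive Gaussian noise.
#'
#' @param image Non-negative numeric matrix or array.
#' @param sigma Noise standard deviation (`>= 0`).
#' @param seed Integer RNG seed.
#' @return Non-negative noisy array of the same shape.
#' @export
add_rician_noise <- function(image, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(image)
  if (any(image < 0)) stop("image must be non-negative for Rician noise")
  ns <- with_seed(seed, list(n1 = stats::rnorm(length(image), 0, sigma),
                             n2 = stats::rnorm(length(image), 0, sigma)))
  out <- sqrt((as.vector(image) + ns$n1)^2 + ns$n2^2)
  array(out, dim = dim(image) %||% length(image))
}
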