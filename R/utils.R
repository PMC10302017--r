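# Shared numeric helpers: centered FFTs, interpolation, blurring, resampling,
# seed scoping. Conventions used throughout the package:
#   * images are numeric matrices indexed [i, j], 0-based pixel p is (i-1, j-1)
#   * k-space is stored centered: DC sits at index floor(N/2) (0-based)
#   * the conjugate mirror of 0-based index i is (-i) mod N, which is the same
#     map in centered and uncentered storage

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package route their draws through this so
#' that a seed argument makes them bit-reproducible without disturbing the
#' global RNG stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

circshift2 <- function(x, s1, s2) {
  d <- dim(x)
  i <- ((seq_len(d[1]) - 1 - s1) %% d[1]) + 1
  j <- ((seq_len(d[2]) - 1 - s2) %% d[2]) + 1
  x[i, j, drop = FALSE]
}

fftshift2 <- function(x) circshift2(x, floor(nrow(x) / 2), floor(ncol(x) / 2))
ifftshift2 <- function(x) circshift2(x, -floor(nrow(x) / 2), -floor(ncol(x) / 2))

#' Centered 2D Fourier transforms
#'
#' `fft2c` maps an image (DC convention: pixel 0 at 0-based index floor(N/2))
#' to centered k-space; `ifft2c` inverts it (normalized by 1/N^2).
#'
#' @param x Numeric or complex matrix.
#' @return Complex matrix of the same size.
#' @export
fft2c <- function(x) fftshift2(stats::fft(ifftshift2(x)))

#' @rdname fft2c
#' @export
ifft2c <- function(x) fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / length(x)

# 0-based conjugate-mirror index as 1-based R subscript
mirror_index <- function(i1, n) ((n - (i1 - 1)) %% n) + 1

# reflect (mirror-at-edge, period 2n-2) an arbitrary integer index into [1, n]
reflect_index <- function(p, n) {
  if (n == 1) return(rep(1L, length(p)))
  q <- (p - 1) %% (2 * n - 2)
  ifelse(q >= n, 2 * n - 2 - q, q) + 1
}

catmull_rom_weights <- function(t) {
  # rows: taps at offsets -1, 0, 1, 2
  t2 <- t * t; t3 <- t2 * t
  rbind(-0.5 * t + t2 - 0.5 * t3,
        1 - 2.5 * t2 + 1.5 * t3,
        0.5 * t + 2 * t2 - 1.5 * t3,
        -0.5 * t2 + 0.5 * t3)
}

#' Sample an image at fractional coordinates
#'
#' Backward-warping workhorse: evaluates `img` at (possibly fractional)
#' 1-based row/column coordinates with cubic (Catmull-Rom) or bilinear
#' interpolation and reflected boundaries.
#'
#' @param img Numeric matrix.
#' @param qi,qj Query row/column coordinates (same length, 1-based).
#' @param method `"cubic"` (default) or `"linear"`.
#' @return Numeric vector of sampled values.
#' @export
interp_image <- function(img, qi, qj, method = c("cubic", "linear")) {
  method <- match.arg(method)
  n <- nrow(img); m <- ncol(img)
  i0 <- floor(qi); j0 <- floor(qj)
  ti <- qi - i0; tj <- qj - j0
  out <- numeric(length(qi))
  if (method == "cubic") {
    wi <- catmull_rom_weights(ti); wj <- catmull_rom_weights(tj)
    for (a in -1:2) {
      ia <- reflect_index(i0 + a, n)
      for (b in -1:2) {
        jb <- reflect_index(j0 + b, m)
        out <- out + wi[a + 2, ] * wj[b + 2, ] * img[cbind(ia, jb)]
      }
    }
  } else {
    for (a in 0:1) {
      ia <- reflect_index(i0 + a, n)
      wa <- if (a == 0) 1 - ti else ti
      for (b in 0:1) {
        jb <- reflect_index(j0 + b, m)
        wb <- if (b == 0) 1 - tj else tj
        out <- out + wa * wb * img[cbind(ia, jb)]
      }
    }
  }
  out
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur with reflected boundaries
#'
#' Separable Gaussian filtering; the kernel is normalized to unit sum so flat
#' regions (and the DC level) are preserved exactly.
#'
#' @param img Numeric matrix.
#' @param sigma Kernel standard deviation in pixels; `sigma <= 0` is identity.
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  conv_axis <- function(x) { # filter along rows of x
    n <- nrow(x)
    idx <- reflect_index(seq_len(n + 2 * r) - r, n)
    xp <- x[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (t in seq_along(k)) out <- out + k[t] * xp[(t - 1) + seq_len(n), , drop = FALSE]
    out
  }
  t(conv_axis(t(conv_axis(img))))
}

#' Decimate an image by block averaging
#'
#' @param img Numeric matrix whose dimensions are divisible by `r`.
#' @param r Integer decimation factor (`r = 1` is identity).
#' @return Matrix of size `dim(img) / r`.
#' @export
block_average <- function(img, r) {
  r <- as.integer(r)
  if (r == 1L) return(img)
  n <- nrow(img); m <- ncol(img)
  if (n %% r != 0 || m %% r != 0)
    stop("block_average: factor ", r, " does not divide image size ", n, "x", m)
  a <- matrix(colMeans(matrix(img, nrow = r)), nrow = n / r)         # rows
  t(matrix(colMeans(matrix(t(a), nrow = r)), nrow = m / r))          # cols
}

# bilinear upsample a coarse matrix to n x m (block centers aligned)
upsample_bilinear <- function(coarse, n, m) {
  bi <- nrow(coarse); bj <- ncol(coarse)
  # block centers of a bi x bj partition of an n x m grid
  ci <- (seq_len(bi) - 0.5) * (n / bi) + 0.5
  cj <- (seq_len(bj) - 0.5) * (m / bj) + 0.5
  qi <- outer(seq_len(n), rep(1, m))
  qj <- outer(rep(1, n), seq_len(m))
  # map fine coords into coarse index space
  fi <- (qi - 0.5) / (n / bi) + 0.5
  fj <- (qj - 0.5) / (m / bj) + 0.5
  matrix(interp_image(coarse, pmin(pmax(as.vector(fi), 1), bi),
                      pmin(pmax(as.vector(fj), 1), bj), method = "linear"), n, m)
}

psnr_db <- function(test, reference, peak) {
  mse <- mean((test - reference)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

stopifnot_power_of_two <- function(n, what) {
  if (n < 16 || bitwAnd(n, n - 1L) != 0L)
    stop(what, " must be >= 16 and a power of 2, got ", n)
  invisible(n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
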