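# Quantitative image-quality evaluation: MSE, PSNR and windowed SSIM, with
# mean/std aggregation over repeated reconstructions.

# uniform window local means via separable valid-region convolution
local_mean <- function(img, win) {
  k <- rep(1 / win, win)
  n <- nrow(img); m <- ncol(img)
  roll <- function(x) {
    nn <- nrow(x)
    out <- matrix(0, nn - win + 1L, ncol(x))
    for (t in seq_len(win)) out <- out + x[(t - 1L) + seq_len(nn - win + 1L), , drop = FALSE] / win
    out
  }
  t(roll(t(roll(img))))
}

#' Structural similarity index (uniform window)
#'
#' Standard windowed SSIM with a `window`-pixel uniform filter and stability
#' constants `C1 = (0.01 peak)^2`, `C2 = (0.03 peak)^2`, averaged over the
#' valid (fully overlapping) region. Symmetric in its arguments.
#'
#' @param a,b Same-size numeric matrices.
#' @param peak Dynamic range; the default is symmetric in the arguments so
#'   `ssim(a, b) == ssim(b, a)` exactly.
#' @param window Window side in pixels (default 7).
#' @return SSIM in \[-1, 1\].
#' @export
ssim <- function(a, b, peak = max(abs(a), abs(b)), window = 7L) {
  if (!all(dim(a) == dim(b))) stop("images must have the same size")
  c1 <- (0.01 * peak)^2; c2 <- (0.03 * peak)^2
  mu_a <- local_mean(a, window); mu_b <- local_mean(b, window)
  va <- local_mean(a * a, window) - mu_a^2
  vb <- local_mean(b * b, window) - mu_b^2
  cab <- local_mean(a * b, window) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
       ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(s)
}

#' Image-quality metrics between a reconstruction and its reference
#'
#' Computes MSE, `PSNR = 10 log10(peak^2 / MSE)` and SSIM, optionally over a
#' list of repeated reconstructions (e.g. across noise seeds), reporting mean
#' and standard deviation per metric. A perfect match is reported with
#' `psnr = Inf` (serialized as null plus an `infinite_psnr` flag by the JSON
#' writers).
#'
#' @param test Matrix, or list of matrices for repeated measurements.
#' @param reference Reference matrix.
#' @param peak Peak intensity for PSNR/SSIM constants; defaults to the
#'   reference maximum.
#' @return A `metrics_report`: `mse`, `psnr`, `ssim` (means), `n_repeats`,
#'   and `sd` (per-metric standard deviations, 0 when `n_repeats = 1`).
#' @export
compute_metrics <- function(test, reference, peak = NULL) {
  if (length(reference) == 0) stop("zero-size input")
  if (is.null(peak)) peak <- max(abs(reference))
  if (peak <= 0) stop("peak must be positive")
  tests <- if (is.list(test)) test else list(test)
  one <- function(tt) {
    if (!all(dim(tt) == dim(reference))) stop("shape mismatch")
    mse <- mean((tt - reference)^2)
    c(mse = mse,
      psnr = if (mse == 0) Inf else 10 * log10(peak^2 / mse),
      ssim = ssim(tt, reference, peak))
  }
  vals <- vapply(tests, one, numeric(3))
  nr <- length(tests)
  structure(list(mse = mean(vals["mse", ]), psnr = mean(vals["psnr", ]),
                 ssim = mean(vals["ssim", ]), peak = peak, n_repeats = nr,
                 sd = if (nr == 1) c(mse = 0, psnr = 0, ssim = 0)
                      else apply(vals, 1, stats::sd)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics: PSNR %.2f dB, SSIM %.4f, MSE %.3g (n = %d)\n",
              x$psnr, x$ssim, x$mse, x$n_repeats))
  invisible(x)
}

# JSON-safe serialization of a metrics report (Inf PSNR -> null + flag)
metrics_to_list <- function(x) {
  list(mse = x$mse,
       psnr = if (is.finite(x$psnr)) x$psnr else NULL,
       infinite_psnr = !is.finite(x$psnr),
       ssim = x$ssim, peak = x$peak, n_repeats = x$n_repeats,
       sd = as.list(x$sd))
}
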