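# End-to-end orchestration: phantom -> degradation -> k-q sampling ->
# low-resolution reconstruction (with optional neighbor-direction sharing) ->
# denoise -> deblur -> register -> super-resolve -> evaluate, from a single
# config, deterministic under (config, seed). Also generates the canonical
# small fixture set used by the test suite.

#' Pipeline configuration
#'
#' @param phantom A [phantom_spec()] (the high-resolution ground truth).
#' @param degradation A [degradation_spec()] (blur / decimation / noise).
#' @param sampling List: `type` ("poisson" or "blades"), `sparsity_rate`
#'   (percent of samples retained, one of 20/40/60/80/100),
#'   `partial_fourier` (fraction or NULL), `r_min`, `lines_per_blade`,
#'   `density_profile`.
#' @param recon List: `method` ("zf", "pocs", "dc"), `config`
#'   (a [recon_config()]), `neighbor_window` (RoSA sharing; 0 disables).
#' @param registration List: `enabled`, `kappa`, `label_range`, `levels`,
#'   `block_size`.
#' @param networks List: `denoise`, `deblur`, `sr` - each either
#'   `"identity"`, `"smoother"` (denoise only), `"zero_fill"` (sr only), or
#'   a trained `dwisr_net`.
#' @param weights A [loss_weights()].
#' @param seed Integer master seed.
#' @return A `pipeline_config` list (serializable; hashed into manifests).
#' @export
pipeline_config <- function(phantom = phantom_spec("dwi_tensor", 64, 8),
                            degradation = degradation_spec(),
                            sampling = list(),
                            recon = list(),
                            registration = list(),
                            networks = list(),
                            weights = loss_weights(),
                            seed = 1L) {
  sampling <- utils::modifyList(
    list(type = "poisson", sparsity_rate = 100, partial_fourier = NULL,
         r_min = 0, lines_per_blade = 12L), sampling)
  recon <- utils::modifyList(
    list(method = "zf", config = recon_config(), neighbor_window = 0L), recon)
  registration <- utils::modifyList(
    list(enabled = FALSE, kappa = 0.1, label_range = 3, levels = 2L,
         block_size = 8L), registration)
  networks <- utils::modifyList(
    list(denoise = "identity", deblur = "identity", sr = "zero_fill"), networks)
  if (!sampling$sparsity_rate %in% c(20, 40, 60, 80, 100))
    stop("sparsity_rate must be one of 20, 40, 60, 80, 100")
  structure(list(phantom = phantom, degradation = degradation,
                 sampling = sampling, recon = recon,
                 registration = registration, networks = networks,
                 weights = weights, seed = as.integer(seed)),
            class = "pipeline_config")
}

apply_denoise_stage <- function(img, net) {
  if (identical(net, "identity")) return(img)
  if (identical(net, "smoother")) return(gaussian_blur(img, 0.8))
  if (inherits(net, "dwisr_net") && net$arch == "denoise_gen") {
    vol <- array(rep(img, 2), c(2, dim(img)))     # minimal through-plane extent
    vol <- aperm(vol, c(1, 2, 3))
    out <- net_predict(net, vol)
    return(out[1, , ])
  }
  stop("unsupported denoise stage")
}

apply_deblur_stage <- function(img, net) {
  if (identical(net, "identity")) return(img)
  if (inherits(net, "dwisr_net") && net$arch == "deblur_gen")
    return(net_predict(net, array(img, c(dim(img), 1))))
  stop("unsupported deblur stage")
}

apply_sr_stage <- function(img, net, factor) {
  if (identical(net, "zero_fill")) {
    if (factor == 1) return(img)
    x <- img
    for (i in seq_len(round(log2(factor))))
      x <- zero_fill(kspace(fft2c(x), sampling_mask(matrix(TRUE, nrow(x), ncol(x)))), 2L)
    return(x)
  }
  if (inherits(net, "dwisr_net") && net$arch == "sr_gen") {
    stacked <- array(c(img, img), c(dim(img), 2))
    return(net_predict(net, stacked))
  }
  stop("unsupported sr stage")
}

#' Run the full reconstruction pipeline
#'
#' Executes every stage in order on the configured phantom: per-direction
#' degradation to low resolution, k-q mask generation and k-space
#' measurement, sparse reconstruction (optionally with neighbor-direction
#' composite sharing), denoising, deblurring, registration to the first
#' direction, super-resolution back to the phantom grid, and PSNR/SSIM
#' evaluation per stage. Deterministic given (config, seed).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for per-stage images, a metrics
#'   JSON and a run manifest.
#' @return A `run_result`: per-stage image stacks, `metrics` (per-stage
#'   [compute_metrics()] reports), and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  ph <- config$phantom
  r <- config$degradation$downsample_factor
  hr <- if (ph$name == "dwi_tensor") make_dwi_phantom(ph)
        else {
          img <- make_shepp_logan(ph)
          structure(list(images = array(img, c(dim(img), 1)),
                         bvecs = matrix(c(0, 0, 1)), bval = 0, s0 = img),
                    class = "dwi_stack")
        }
  nd <- dim(hr$images)[3]
  nlr <- ph$matrix_size %/% r
  scheme <- if (nd > 1) kq_schedule(nd, nd, min(config$recon$neighbor_window, nd - 1L))
            else NULL

  lr <- array(0, c(nlr, nlr, nd))
  for (d in seq_len(nd))
    lr[, , d] <- degrade_to_lr(hr$images[, , d], config$degradation,
                               seed = seed + d)

  # per-direction sampling masks and measured k-space
  masks <- vector("list", nd)
  kdata <- vector("list", nd)
  frac <- config$sampling$sparsity_rate / 100
  for (d in seq_len(nd)) {
    base <- if (config$sampling$type == "blades") {
      bl <- propeller_blades(nd, config$sampling$lines_per_blade, nlr, nlr)
      # one blade per direction, rotated per the k-q schedule
      rasterize_trajectory(bl[[d]])
    } else sampling_mask(matrix(TRUE, nlr, nlr))
    msk <- if (frac < 1)
      poisson_subsample(base, frac, config$sampling$r_min,
                        config$sampling$density_profile %||% uniform_profile(),
                        seed = seed + 100 + d)
      else base
    if (!is.null(config$sampling$partial_fourier))
      msk <- partial_fourier_mask(msk, config$sampling$partial_fourier)
    masks[[d]] <- msk
    kdata[[d]] <- kspace_from_image(lr[, , d], msk)
  }

  # low-resolution reconstruction
  recon_one <- function(ksp, msk) {
    switch(config$recon$method,
           zf = {
             k2 <- if (msk$hermitian_half) hermitian_fill(ksp, msk) else ksp
             zero_fill(k2, 1L)
           },
           pocs = pocs_pf_recon(ksp, msk, config$recon$config),
           dc = dc_cascade_recon(ksp, msk, config$recon$config),
           stop("unknown recon method"))
  }
  if (!is.null(scheme) && config$recon$neighbor_window > 0) {
    stack0 <- structure(list(images = lr, bvecs = hr$bvecs, bval = hr$bval,
                             s0 = hr$s0), class = "dwi_stack")
    rec_stack <- rosa_composite(stack0, kdata, scheme)
    recon_imgs <- rec_stack$images
  } else {
    recon_imgs <- array(0, c(nlr, nlr, nd))
    for (d in seq_len(nd)) recon_imgs[, , d] <- recon_one(kdata[[d]], masks[[d]])
  }

  den <- array(0, dim(recon_imgs))
  for (d in seq_len(nd))
    den[, , d] <- apply_denoise_stage(recon_imgs[, , d], config$networks$denoise)
  deb <- array(0, dim(den))
  for (d in seq_len(nd))
    deb[, , d] <- apply_deblur_stage(den[, , d], config$networks$deblur)

  reg <- deb
  if (config$registration$enabled && nd > 1) {
    for (d in 2:nd) {
      rr <- mrf_register(deb[, , 1], deb[, , d],
                         label_range = config$registration$label_range,
                         kappa = config$registration$kappa,
                         levels = config$registration$levels,
                         block_size = config$registration$block_size)
      reg[, , d] <- warp(deb[, , d], rr$field)
    }
  }

  sr <- array(0, c(ph$matrix_size, ph$matrix_size, nd))
  for (d in seq_len(nd))
    sr[, , d] <- apply_sr_stage(reg[, , d], config$networks$sr, r)

  # per-stage evaluation against the ground-truth phantom
  ref_lr <- array(0, c(nlr, nlr, nd))
  for (d in seq_len(nd))
    ref_lr[, , d] <- block_average(gaussian_blur(hr$images[, , d],
                                                 config$degradation$blur_sigma), r)
  stage_metrics <- function(stack, ref) {
    reps <- lapply(seq_len(nd), function(d) stack[, , d])
    refs <- lapply(seq_len(nd), function(d) ref[, , d])
    ms <- Map(compute_metrics, reps, refs)
    list(psnr = mean(vapply(ms, `[[`, 0, "psnr")),
         ssim = mean(vapply(ms, `[[`, 0, "ssim")),
         mse = mean(vapply(ms, `[[`, 0, "mse")))
  }
  metrics <- list(recon = stage_metrics(recon_imgs, ref_lr),
                  denoise = stage_metrics(den, ref_lr),
                  final = stage_metrics(sr, hr$images))
  manifest <- list(config_hash = config_hash(config), seed = seed,
                   phantom = ph$name, matrix_size = ph$matrix_size,
                   n_directions = nd,
                   sparsity_rate = config$sampling$sparsity_rate,
                   recon_method = config$recon$method,
                   neighbor_window = config$recon$neighbor_window)
  res <- structure(list(hr = hr$images, lr = lr, recon = recon_imgs,
                        denoised = den, deblurred = deb, registered = reg,
                        sr = sr, masks = masks, metrics = metrics,
                        manifest = manifest),
                   class = "run_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_image_nifti(sr, file.path(out_dir, "sr.nii"))
    write_image_nifti(recon_imgs, file.path(out_dir, "recon_lr.nii"))
    jsonlite::write_json(list(metrics = metrics, manifest = manifest),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Generate the canonical small fixture set
#'
#' Writes the inputs the test suite and worked examples rely on: a 64 x 64
#' Shepp-Logan phantom, an 8-direction 32 x 32 DWI tensor stack with b-vector
#' and b-value sidecars, clean/noisy 16^3 denoising volumes (Rician noise), a
#' smooth nonrigid deformation with its warped image and ground-truth field,
#' landmark coordinates, and Poisson masks at sparsity rates
#' 20/40/60/80/100%. A JSON manifest lists the inventory.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the manifest list.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inv <- list()
  sl <- make_shepp_logan(phantom_spec("shepp_logan", 64))
  write_image_nifti(sl, file.path(out_dir, "shepp_logan_64.nii"))
  inv$shepp_logan_64 <- dim(sl)
  stack <- make_dwi_phantom(phantom_spec("dwi_tensor", 32, 8, seed = seed))
  write_image_nifti(stack$images, file.path(out_dir, "dwi_stack_32.nii"))
  write_bvecs(stack$bvecs, file.path(out_dir, "dwi_stack_32.bvec"))
  write_bvals(rep(stack$bval, 8), file.path(out_dir, "dwi_stack_32.bval"))
  inv$dwi_stack_32 <- dim(stack$images)
  vol <- array(0.5 + 0.4 * sin(seq_len(16) / 3), c(16, 16, 16))
  vol <- vol * array(rep(sl[seq(1, 64, by = 4), seq(1, 64, by = 4)], 16),
                     c(16, 16, 16))
  noisy <- add_rician_noise(vol, 25 / 255, seed = seed)
  write_image_nifti(vol, file.path(out_dir, "denoise_clean_16.nii"))
  write_image_nifti(noisy, file.path(out_dir, "denoise_noisy_16.nii"))
  inv$denoise_volumes <- dim(vol)
  def <- deformation_spec("rbf_nonrigid", max_displacement = 3, seed = seed)
  wr <- apply_deformation(sl, def)
  write_image_nifti(wr$image, file.path(out_dir, "shepp_logan_64_warped.nii"))
  write_array_archive(wr$field, file.path(out_dir, "deformation_field.rds"),
                      meta = list(kind = def$kind,
                                  max_displacement = def$max_displacement))
  lm <- with_seed(seed, cbind(stats::runif(20, 10, 54), stats::runif(20, 10, 54)))
  write_landmarks(lm, file.path(out_dir, "landmarks.txt"))
  inv$deformation <- def$max_displacement
  rates <- c(20, 40, 60, 80, 100)
  for (rt in rates) {
    m <- if (rt == 100) sampling_mask(matrix(TRUE, 64, 64))
         else poisson_subsample(matrix(TRUE, 64, 64), rt / 100, 0, seed = seed)
    write_array_archive(m, file.path(out_dir, sprintf("mask_rate%03d.rds", rt)),
                        meta = list(declared_rate = rt / 100))
    inv[[sprintf("mask_rate%03d", rt)]] <- m$fraction_sampled
  }
  manifest <- list(seed = seed, inventory = inv)
  jsonlite::write_json(manifest, file.path(out_dir, "fixtures_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
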