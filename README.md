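# dwisr: super-resolution reconstruction of diffusion-weighted MRI from sparse k-q space data

`dwisr` is an R toolkit for accelerated diffusion-weighted MRI (DWI)
reconstruction. Scan time in DWI is dominated by the product of k-space
sampling and the number of q-space diffusion directions; `dwisr` implements a
reconstruction chain that cuts both axes at once and then restores image
quality with model-based and adversarially trained enhancement stages:

* **k-q sampling patterns** — rotating PROPELLER blades (one blade per
  diffusion direction), variable-density Poisson-disc subsampling with a
  fully sampled low-frequency core, Hermitian ("halved") partial-Fourier
  masks, and radial masks;
* **sparse reconstruction** — exact NUFFT forward/adjoint, zero filling,
  conjugate-symmetry completion of half k-space, POCS partial-Fourier
  iteration, a data-consistency cascade with a pluggable refiner, and the
  neighbor-direction composite that borrows unsampled k-space from
  angularly nearby q-space directions (weights `cos²θ` in the angular
  distance);
* **motion estimation** — deformable registration by discrete displacement
  labeling, solved *exactly* by dynamic programming on the minimum spanning
  tree of a block graph, minimizing
  `E(w) = Σᵢ S(wᵢ) + κ Σ₍l,m₎ R(w_l, w_m)`, coarse-to-fine with subpixel
  labels; accuracy is reported as target registration error (TRE) at
  landmarks;
* **learned stages** — Wasserstein-GAN super-resolution (residual trunk +
  two sub-pixel stages, 8-layer critic, weight clipping `c = 0.01`),
  encoder–decoder deblurring (adversarial + `λ·`perceptual content loss,
  `λ = 100`), and 3D Rician denoising (channel ladder
  32-64-128-256-128-64-32-1, gradient-penalty critic, composite
  `δ₁L_MSE + δ₂L_perc + δ₃L_WGAN`), all on a self-contained deterministic
  neural-network core with exact gradients;
* **evaluation and phantoms** — PSNR/SSIM/MSE reports, the analytic
  Shepp–Logan phantom, a diffusion-tensor phantom whose contrast is smooth
  across q-space (the redundancy the composite reconstruction exploits),
  and the full degradation model (motion, blur, decimation,
  Gaussian/Rician noise).

Everything runs at desk scale on generated phantoms: no external data, no
GPU, deterministic under a seed.

## Worked example

Reconstruct an 8-direction diffusion phantom from one sparse blade per
direction, with and without neighbor-direction sharing, then register a
deformed frame:

```r
library(dwisr)

# 8-direction tensor phantom, 64x64, b = 1000 s/mm^2
st  <- make_dwi_phantom(phantom_spec("dwi_tensor", 64, 8, seed = 1))

# one rotating blade per direction (12 phase-encode lines of 64)
bl  <- propeller_blades(8, 12, 64, 64)
kd  <- lapply(1:8, function(d)
  kspace_from_image(st$images[, , d], rasterize_trajectory(bl[[d]])))

# composite reconstruction: share k-space with the 2 nearest q-neighbors
rec2 <- rosa_composite(st, kd, kq_schedule(8, 8, 2))
rec0 <- suppressWarnings(rosa_composite(st, kd, kq_schedule(8, 8, 0)))
mean_psnr <- function(r) mean(sapply(1:8, function(d)
  compute_metrics(r$images[, , d], st$images[, , d])$psnr))
cat(sprintf("blade-only %.2f dB -> shared %.2f dB\n",
            mean_psnr(rec0), mean_psnr(rec2)))

# deformable registration of a nonrigidly warped phantom
img <- make_shepp_logan(phantom_spec("shepp_logan", 64))
wr  <- apply_deformation(img, deformation_spec("rbf_nonrigid",
                                               max_displacement = 3, seed = 31))
est <- mrf_register(wr$image, img, label_range = 3, kappa = 0.1, levels = 2)
lm  <- with_seed(32, cbind(runif(20, 8, 56), runif(20, 8, 56)))
zero <- displacement_field(matrix(0, 64, 64), matrix(0, 64, 64))
cat(sprintf("TRE without correction %.2f -> registered %.2f voxels\n",
            tre(wr$field, zero, lm), tre(wr$field, est$field, lm)))
```

```
blade-only 22.69 dB -> shared 24.46 dB
TRE without correction 1.79 -> registered 0.43 voxels
```

Sharing each direction's unsampled k-space with its two angular neighbors
buys ~1.8 dB at no acquisition cost — the premise of single-blade-per-
direction imaging — and tree-exact registration removes about three
quarters of the forced deformation at the landmarks.

The end-to-end pipeline (`run_pipeline()`) chains phantom → degradation →
sampling → sparse reconstruction → denoise → deblur → register →
super-resolve → evaluate from one `pipeline_config()`, and
`make_fixtures()` writes the canonical small test inputs (NIfTI images,
b-vector/b-value sidecars, landmark tables, mask archives). A thin
command-line front-end over these functions is installed at
`inst/cli/dwisr.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "dwisr.R", package = "dwisr"))')" \
    pipeline --size 64 --directions 4 --rate 60 --out out/
```

## Scope

The package implements and tests the method's structure and qualitative
behavior on synthetic phantoms. Clinical-scale claims (absolute PSNR/TRE on
in vivo scanner data, publication-scale GAN training) are out of scope; the
methods vignette (`vignettes/dwisr-methods.Rmd`) documents the models,
parameter choices, and limitations in detail.
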