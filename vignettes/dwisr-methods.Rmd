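---
title: "Sparse k-q space DWI super-resolution: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse k-q space DWI super-resolution: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwisr)
```

## The problem

Diffusion-weighted MRI trades spatial resolution against scan time: each
q-space direction requires its own acquisition, and each acquisition samples
k-space under hard time limits. `dwisr` implements an accelerated
reconstruction strategy built on three redundancies:

1. **Conjugate symmetry.** A (nearly) real-valued object has Hermitian
   k-space, so only slightly more than half of the phase encodes carry
   independent information (partial Fourier).
2. **Incoherent sparsity.** Poisson-disc subsampling below the Nyquist rate
   produces noise-like (rather than coherent) aliasing that compressed-sensing
   style reconstruction can remove.
3. **q-space smoothness.** Diffusion contrast varies smoothly with the
   encoding direction, so blades of k-space acquired for *neighboring*
   directions are nearly interchangeable. Acquiring a single rotating
   PROPELLER blade per direction and borrowing the unsampled k-space
   positions from angular neighbors (the rotating single-shot idea, a
   HYPR-style composite) recovers per-direction images from a fraction of
   the data.

On top of the sparse low-resolution reconstruction sit four learned or
model-based enhancement stages: Rician denoising, blind deblurring,
deformable motion estimation, and adversarially trained super-resolution.

## Sampling model

`propeller_blades()` generates rectangular strips of parallel phase-encoded
lines through the k-space center; blade $b$ of $B$ is rotated by
$b\cdot180^\circ/B$ (Cartesian lines are undirected, so $180^\circ$ covers
all orientations). `kq_schedule()` assigns direction $d$ the blade angle
$(d-1)\cdot180^\circ/n$ and the `neighbor_window` angularly nearest
directions under the antipodally symmetric distance
$\arccos|g_d^\top g_n|$.

`poisson_subsample()` implements variable-density Poisson-disc selection by
dart throwing in a seeded random order. A density profile $\rho(|k|)$ maps
normalized k-space radius to a relative rate: candidates are prioritized by
weighted sampling without replacement ($u^{1/\rho}$) and accepted when no
previously kept sample lies within the local exclusion radius
$r_{\min}/\rho$. The fully sampled low-frequency core (default radius 8% of
$k_\max$; the paper-style scheme boosts a high-frequency band) has infinite
rate, hence no exclusion. Two properties matter for testing and for the
sparsity sweep:

* with the uniform profile the kept set provably satisfies the pairwise
  distance bound $r_{\min}$ (verified exhaustively in the tests);
* acceptance decisions never depend on the target fraction, so masks at
  increasing fractions under one seed are **nested**, which makes PSNR
  comparisons across sparsity rates paired rather than confounded by mask
  redraws.

`partial_fourier_mask()` keeps $\lceil fN \rceil$ phase-encode rows
($f \in (0.5, 1]$): one half-plane plus the full symmetric center band.
Every removed point's conjugate mirror ($(-i) \bmod N$ per axis, identical
in centered and uncentered storage) lies in the kept set. We flag such masks
`hermitian_half`, meaning *the removed region is recoverable by conjugate
symmetry* — note the complementary band where both mirrors are present is
what makes phase estimation possible, so a literal "no sampled point has a
sampled mirror" reading would contradict the construction itself.

## Reconstruction

All transforms use the centered FFT convention (DC at index
$\lfloor N/2\rfloor$); magnitude is taken only at the final output of each
reconstruction.

* `nufft()` evaluates the non-uniform Fourier sum directly, split along the
  two axes so memory stays at $O(MN)$ for $M$ samples on an $N^2$ grid. At
  desk scale this exact evaluation is preferable to gridding approximations:
  the forward/adjoint pair satisfies the adjoint identity to machine
  precision, which the tests verify — density compensation is a separate,
  optional weighting of the adjoint.
* `zero_fill()` embeds k-space in a factor-2 larger matrix (sinc
  interpolation; pixel count doubles without adding information).
* `hermitian_fill()` fills every unsampled position with the conjugate of
  its mirror; exact for real-valued objects (the tests require > 100 dB).
* `pocs_pf_recon()` handles slowly varying phase: a reference phase is
  estimated from the windowed symmetric center band (raised-cosine window of
  radius `phase_ref_radius`, default 0.12 of $k_\max$), and the iteration
  alternates phase projection with restoration of the measured data. It is
  initialized from the conjugate-symmetry completion, so the zero-phase case
  is exact from the first iterate and the iteration only has to correct
  phase errors.
* `dc_cascade_recon()` is the unrolled iterative reconstruction
  $x \leftarrow \mathrm{DC}(\mathrm{refine}(x))$ with a pluggable refiner
  and $\lambda$-weighted k-space data replacement ($\lambda = 1$: hard
  consistency, making the identity refiner an immediate fixed point). The
  refiner can be a trained network or an analytic smoother. A practical
  note, measured on the phantoms here: an isotropic Gaussian refiner is
  neutral to slightly harmful relative to zero filling (it attenuates true
  edges as much as incoherent aliasing), whereas the edge-preserving
  `median_filter3()` refiner gives a small consistent gain on
  piecewise-smooth objects. The package therefore ships the median refiner
  as its default analytic choice, and the cascade's contract (data
  consistency, fixed points, divergence abort) is independent of the hook.
* `rosa_composite()` builds, for each direction, a composite k-space: own
  blade data kept exactly; positions the blade missed are filled from the
  q-space neighbors' blades with weights $\cos^2\theta$ in the angular
  distance, normalized over contributors. With identical per-direction
  images (a $b=0$ stack) this equals reconstruction from the union of all
  blades; with zero neighbor window it degrades to per-direction zero
  filling (with a warning when coverage is incomplete).

## Registration

Motion is estimated as a discrete labeling problem. The image is divided
into square blocks (default 8 px); a 4-neighbor block graph with edge cost
equal to the mean absolute intensity difference is reduced to its minimum
spanning tree (ties broken lexicographically, so deterministic). Each block
chooses a 2D displacement from $\{-R,\dots,R\}^2$ at `label_step`
resolution, minimizing

$$E(w) = \sum_{i} S(w_i) + \kappa \sum_{(l,m)} R(w_l, w_m),$$

with $S$ the block sum of squared differences under the candidate
displacement and $R$ the squared Euclidean distance between neighboring
labels. The functional forms are our choice (the underlying formulation
names the terms but not their forms): SSD and squared label distance keep
the pairwise term convex in the label difference and make exactness
testable. On a tree the energy is minimized *exactly* by two-pass dynamic
programming (min-sum belief propagation); the package ships an independent
exhaustive-enumeration oracle (`mrf_bruteforce_min`, C++) against which the
solver is tested on random 6-node, 27-label problems. The regularizer is
accumulated over tree edges — the same support the optimizer uses — rather
than all grid neighbors, keeping the reported energy the quantity actually
minimized.

Registration is coarse-to-fine: each pyramid level registers the residual
after warping by the upsampled field, and the finest level halves the label
quantum (default $1 \to 0.5$ voxels) because subpixel shifts are part of
the degradation model. Warping is backward with Catmull-Rom cubic
interpolation and reflected boundaries. Accuracy is summarized by the
target registration error,
$\mathrm{TRE} = \frac1N\sum_i \lVert T_L(x_i) - T_D(x_i)\rVert$, at
landmark positions (the through-plane term is zero in 2D).

## Networks and losses

No deep-learning framework ships with this package's dependency set, so
`dwisr` includes a compact, fully deterministic neural-network core (2D/3D
convolution evaluated tap-by-tap on BLAS matrix products, transposed
convolution, sub-pixel shuffling, batch normalization with per-sample
statistics, leaky ReLU, dense and global-pool layers) with exact
reverse-mode gradients — every architecture is finite-difference verified in
development to $\sim 10^{-10}$ relative error.

* **SR generator**: 9-px head convolution, `n_resblocks` (default 8)
  residual blocks, a long skip, two $\times 2$ sub-pixel stages, and a 9-px
  tail; a fixed nearest-neighbor upsample of the input is added to the
  learned output so a fresh network starts at plain interpolation quality
  (global residual learning — our choice, standard in SR practice, and the
  reason short toy runs improve monotonically rather than spending their
  budget rediscovering the identity). Input $H\times W\times2$ (the target
  LR frame stacked with a neighbor), output $rH\times rW\times1$, $r=4$.
* **SR critic**: eight 3-px convolutions, channels doubling
  $c\to8c$ with alternating stride-2 shrinking, global average pool, one
  linear output. No terminal sigmoid and *no normalization layers*: a
  Wasserstein critic must represent an unconstrained scalar potential, and
  keeping the stack piecewise-linear is also what makes the gradient
  penalty's parameter gradient computable exactly by double backprop.
* **Deblur generator**: five-conv encoder (stride 2 at layers 2 and 4),
  mirrored transposed-convolution decoder, optional identity skip (zeroing
  the final layer then yields the exact identity — tested). Input sizes
  must be divisible by the total stride 4.
* **Denoising GAN (3D)**: generator stages with the printed channel ladder
  32-64-128-256-128-64-32-1 at multiplier 1, uniform $3^3$ kernels,
  conv → leaky-ReLU → batch-norm on all but the last stage (conv +
  leaky-ReLU only), short skips joining conv/deconv pairs symmetrically,
  plus a global input skip (noise-residual learning). Critic: three 3D
  convolutions (32, 64, 128) and a single dense output.
* **Feature extractor**: perceptual distances are computed in the feature
  space of a *fixed-seed random* convolution stack by default — a
  documented surrogate for pretrained feature networks, which are external
  data this package does not bundle; `net_set_params()` accepts externally
  supplied weights of the same structure, and the degenerate identity
  extractor reduces every perceptual loss to pixel MSE (used as an
  algebraic test).

Losses follow the method's published structure: the Wasserstein critic gap
$\mathbb{E}[D(\text{fake})] - \mathbb{E}[D(\text{real})]$ (its negation
estimates the Wasserstein distance; invariant to critic offset), weight
clipping at $c = 0.01$, the gradient penalty
$\psi\,(\lVert\nabla_{\hat x}D(\hat x)\rVert_2 - 1)^2$ on uniform
interpolates ($\psi = 10$), the SR composite
$l_{\mathrm{MSE}} + 10^{-6} l_{\mathrm{Gen}} + \varrho\,\mathrm{RLT}$ with
$\varrho = 0.001$ and the registration-consistency term
$\mathrm{RLT} = \sum_{i=\pm1}\lVert I'_{t+i} - I_t\rVert^2$, the deblurring
composite $L_{\mathrm{GAN}} + \lambda L_X$ with $\lambda = 100$, and the
denoising composite
$\delta_1 L_{\mathrm{MSE}} + \delta_2 L_{\mathrm{perc}} + \delta_3 L_{\mathrm{WGAN}}$.
The $\delta$ weights are not fixed by the method's description; the package
defaults to $(1, 0.1, 10^{-3})$ — fidelity-dominated, with the adversarial
term as a texture prior — and records all weights in every run's
manifest. Where the printed generator objectives are internally
inconsistent (a self-referential composite; expectations duplicated over one
distribution), we use the standard Wasserstein forms that the surrounding
definitions imply; every composite is returned with its components, and the
exact weighted-sum identity is asserted in the tests.

## Training at desk scale

`train_adversarial()` alternates `critic_updates_per_gen` critic steps
(default 5 in clipping mode, 1 in gradient-penalty mode) with one generator
step, single-sample batches, Adam throughout. The full-scale reference
learning rate is $10^{-5}$; the package's toy runs (width multiplier 1/4,
$16^3$ Rician volumes or $16^2\to64^2$ SR pairs, 60–120 steps) use
$10^{-3}$–$2\times10^{-3}$, chosen once as the standard Adam range in which
a quarter-width network moves appreciably within a hundred steps — at
$10^{-5}$ such a run cannot leave its initialization, which would test
nothing. Toy runs demonstrate the mechanics (determinism, loss descent,
held-out PSNR gain over the inputs), not publication-scale quality.

## Synthetic data: what it does and does not emulate

`make_shepp_logan()` is the standard modified 10-ellipse analytic phantom on
$[-1,1)^2$ with the pixel at index $N/2$ exactly at the origin (matching the
centered-FFT convention). `make_dwi_phantom()` is a mono-exponential tensor
phantom $S = S_0\exp(-b\,g^\top D g)$ with three tissue classes: an
isotropic high-diffusivity ring (CSF-like, $2.5\times10^{-3}$ mm²/s), an
annulus of circumferential fibers, and a central band of straight fibers
(eigenvalues $1.7/0.3\times10^{-3}$ mm²/s, $b = 1000$ s/mm² by default) —
values in the normal range for white matter and CSF at 3 T. Because the
signal is smooth in $g$, adjacent-direction images correlate, decreasing
with angular distance: the redundancy the composite reconstruction needs,
present by construction and verified against the closed form.

Degradation follows blur → block-average decimation → noise. "Noise level
25" is interpreted as an additive standard deviation of 25 on a 0–255
intensity scale; the package works on the unit scale, so the default is
$25/255 \approx 0.098$ (this scale is a configuration default, not a claim —
the original description leaves the intensity scale unstated). Rician noise
is generated exactly as $\sqrt{(x+n_1)^2 + n_2^2}$; its Rayleigh mean in
the zero-signal limit and Gaussian limit at high SNR are both tested.
Nonrigid motion is a normalized linear combination of Gaussian radial basis
functions with the exact ground-truth field returned alongside the warped
image.

What the phantoms deliberately do **not** model: anatomical realism,
off-resonance/EPI distortion, multi-coil sensitivity encoding, through-plane
motion, spatially varying noise. Passing tests therefore demonstrate the
correctness and qualitative behavior of the algorithms (exact recovery
limits, optimality, monotone trends, training mechanics) on data with the
*assumed statistical structure* — not clinical performance.

## Numerical choices and degenerate inputs

* Interpolation: Catmull-Rom cubic with reflected boundaries (smooth fields,
  bounded error; exact at integer offsets). Fields upsample bilinearly.
* Conjugate mirror: $(-i) \bmod N$ per axis; self-conjugate points (DC and
  Nyquist rows on even grids) are handled by the same map.
* Poisson-disc infeasibility: rejection with a message when fewer than 90%
  of the requested samples can be placed.
* Tie-breaks: MST edges lexicographically by index; DP label argmins take
  the first minimum; neighbor lists break ties by lowest direction index.
* Divergence guard: the DC cascade aborts when the update norm exceeds
  10 times its initial value; training aborts on non-finite losses and
  returns the last good parameters.
* All stochastic operations draw through `with_seed()`, restoring the
  caller's RNG state, so a `(config, seed)` pair reproduces any run
  bit-for-bit.

## Problem sizes used by the test suite

Phantoms are $64^2$ (Shepp-Logan, DWI stacks) and $16^3$ (denoising
volumes); tree-solver optimality is checked on 100 random 6-node problems
with 27 labels against exhaustive enumeration; the sparsity sweep runs the
full pipeline at retained-sample rates 20–100% on an 8-direction $64^2$
phantom at decimation factor 2. These sizes were chosen so the entire
behavior of each algorithm — including its exact-recovery and optimality
properties — is exercised in seconds per test.

Parameter counts at reference widths (reproducible from the seeds alone):

| network | multiplier 1 | multiplier 1/4 |
|---|---|---|
| SR generator | 940,993 | 62,449 |
| SR critic | 4,684,737 | 293,361 |
| deblur generator | 2,217,217 | 139,585 |
| denoise generator | 2,326,273 | 146,113 |
| denoise critic | 277,697 | 17,585 |

## Known limitations

* The pipeline operates per 2D slice; the denoiser is the only 3D stage.
* Density compensation for non-Cartesian gridding uses analytic/uniform
  weights; Voronoi weighting is out of scope.
* The registration layer estimates in-plane motion only.
* GAN training at publication scale (and hence absolute PSNR/TRE values on
  clinical data) is explicitly out of scope; all learned-stage claims are
  about toy-scale mechanics.
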