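---
title: "Reference-guided superresolution of MR volumes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided superresolution of MR volumes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsr)
```

## The problem

Clinical MR studies routinely mix voxel resolutions: a high-resolution (HR)
volume in one contrast (say a 1 mm³ T1-weighted scan) alongside a
low-resolution (LR) volume in another (a T2-weighted or FLAIR acquisition
with thick slices). Interpolating the LR volume up to the HR grid cannot
recover the high-frequency content lost at acquisition — interpolated
images are blurred versions of the underlying anatomy. But when a
coplanar, rigidly registered HR volume of the *same subject* exists, its
voxel-similarity structure carries anatomical information that can be
transferred to the LR data. `mrsr` implements that transfer as an
iterative, physically constrained reconstruction.

## Acquisition model

Each LR voxel is modeled as the average of its underlying HR voxels plus
Rician noise:

$$ y = DHx + n $$

where `D` decimates (every L-th voxel per axis, starting at index zero)
and `H` is a 3D boxcar blur matched to the decimation factors. Because the
boxcar support equals the block size and is aligned to block origins, the
composition `DH` acts as plain non-overlapping block averaging, and that
is how `boxcar_downsample()` implements it — one concrete operator instead
of two matrices. The block-average reading is supported by the
partial-volume interpretation of MR voxels: a thick-slice voxel's
intensity is a mixture of the thin-slice intensities it spans.

The adjoint-like upsampling `block_replicate_upsample()` replicates each
LR value over its HR block (nearest-neighbour on blocks); downsampling a
replicated volume returns the input exactly, an identity the tests assert
to machine precision.

Rician noise is simulated as the modulus of the complex signal after
adding independent Gaussian noise of standard deviation sigma to the real
and imaginary channels (the clean volume being real). Sample moments match
the closed forms `E[M] = sigma * sqrt(pi/2)` at zero signal and
`E[M^2] = A^2 + 2 sigma^2` in general; the test suite checks both by
Monte-Carlo at one million voxels.

## Denoising prerequisite

The reconstruction imposes *subsampling consistency* — the downsampled
reconstruction must equal the LR input exactly. With noise present this
constraint would reproduce the noise, so both inputs are denoised first.
`nlm_denoise()` is a voxelwise 3D nonlocal-means filter with Rician bias
correction: weights `exp(-SSD(p,q)/h^2)` from the raw sum of squared
differences between 3×3×3 patches, applied to the *squared* intensities,
followed by `sqrt(max(m2 - 2 sigma^2, 0))`. The automatic bandwidth is
`h^2 = 2 * beta * sigma^2 * |patch|` with `beta = 1` by default. This is a
standard voxelwise Rician NLM; blockwise aggregation speedups found in
some denoiser implementations are intentionally not reproduced — they
change nothing the reconstruction relies on.

When sigma is unknown, `estimate_sigma()` recovers it from the median
absolute deviation of discrete-Laplacian pseudo-residuals (each interior
voxel minus the mean of its six neighbours, whose standard deviation under
i.i.d. noise is `sigma * sqrt(7/6)`). The estimator treats noise as
additive Gaussian, accurate away from low-SNR background.

## The reconstruction iteration

Starting from an interpolated initialization, two steps alternate.

**Reconstruction step.** Every voxel is replaced by a weighted average of
the current reconstruction over a 7×7×7 search window:

$$ \hat x_p^{t+1} = \frac{1}{C_p} \sum_{q \in \Omega}
   \hat x_q^t \; e^{-(z_p - z_q)^2/h^2} \;
   e^{-\lVert N(\hat x_p^t) - N(\hat x_q^t)\rVert^2 / (k h^2)} $$

The first factor is a sigma filter on the HR reference `z`: voxels with
similar reference intensity are trusted to be similar in the
reconstruction. The second is a nonlocal-means term on the reconstruction
itself: 3×3×3 patch similarity captures LR self-similarity, which keeps
the method robust to small misregistration and lets it reconstruct
structures (such as lesions) visible only in the LR contrast. A single
normalisation constant `C_p` covers the product weight. Both distances are
symmetric under exchange of p and q, so the combined weight is symmetric
— the property that makes the halved "symmetric weight" evaluation of the
filtering step valid.

**Mean correction.** The block means of the reconstruction are snapped
back onto the LR data:

$$ \hat x^{t+1} \leftarrow \hat x^{t+1} - \mathrm{NN}(DH\hat x^{t+1} - y) $$

After this step `DH x̂ = y` holds to floating-point accuracy (the tests
bound the sup-norm by 1e-10), so the final reconstruction is always
consistent with the acquisition model regardless of what the averaging
step did.

### Interpretation choices

Several details of the weighting are open to interpretation; the package
fixes them as follows, and the naive-loop oracles in the test suite pin
them down:

* the patch norm is the raw SSD over all 27 patch voxels, with no
  normalisation by patch size — `k` absorbs the scale;
* the search window includes the centre voxel (its weight is exactly 1);
* one normalisation constant over the product weights, not one per kernel;
* search windows are clipped at the volume border while patches are
  mirror-padded (half-sample reflection), the same conventions in the
  denoiser and the reconstruction so the two code paths coincide exactly
  when the reference is constant;
* the step is Jacobi-style: all outputs are computed from the frozen
  current volume, making the result traversal-order independent and the
  oracle well defined. Any parallel implementation must be bitwise
  equivalent to this sequential reference.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `search_radius` | 3 | 7×7×7 search volume; larger windows give only marginal gains at steep cost |
| `patch_radius` | 1 | 3×3×3 self-similarity patches |
| `h_schedule` | 32, 16, 8, 4, 2 | filtering strength per pass, 8-bit scale |
| `k` | 256 | balance of reference vs self-similarity terms |
| `tol` | 0.01 | MAD stopping tolerance, 8-bit scale |
| `max_iters` | 50 | safety cap |
| `init_method` | nearest | initial interpolation |

The decremental `h` schedule drives a coarse-to-fine reconstruction: at
`h = 32` (about 12.5% of an 8-bit range) dissimilar regions are still
averaged together; by `h = 2` only close matches are copied. Each listed
value is used for exactly one reconstruction + correction pass; the
iteration then continues at the final value until the mean absolute
difference (MAD) between consecutive volumes, over all voxels, drops below
`tol`. Convergence is checked only from the end of the schedule onward, so
the schedule always executes in full. With `k` small the method leans on
LR self-similarity (robust but modest gains); with `k` large the HR
reference dominates (best reconstruction when registration is perfect,
fragile otherwise). `k = 256` is a good middle ground.

Volumes are processed at native intensity scale: `h` and `tol` are
multiplied by `range_peak / 255` (`scale_h_schedule()`), where
`range_peak` is the HR reference's nominal peak. This is equivalent to
requantising the data to 8 bits but lossless. The fractional schedule
(12.5%, 6.3%, 3.1%, 1.6%, 0.8% of the range) is what actually matters; the
integer values are its 8-bit quantisation.

The initialization barely matters — the acceptance suite shows nearest-
and B-spline-initialized runs agreeing beyond 40 dB mutual PSNR — so the
cheapest option is the default.

## Baselines, metrics and protocols

`interpolate_upsample()` provides nearest, trilinear, Keys cubic
(a = −1/2), and interpolating natural-cubic-spline ("B-spline") baselines.
All share one geometric convention, chosen to match the block-mean model:
the LR voxel centre sits at the centre of its HR block, i.e. HR voxel `i`
(0-based) samples the LR signal at `(i - (L-1)/2)/L`. Comparing methods on
any other alignment convention silently biases PSNR, so the proposed
method's initialization uses the same operators.

`psnr()` is `10 log10(peak² / MSE)`; the peak defaults to the reference
volume's `range_peak` (identical volumes are flagged infinite). `ipsnr()`
is the PSNR difference against a named baseline. `shift_volume()`
translates a volume by whole voxels (or sub-voxel, trilinear) with edge
replication, used to probe sensitivity to residual misregistration of the
reference — at 1 mm isotropic reference spacing a 1 mm shift is one voxel.

## The synthetic phantom

`generate_multimodal_phantom()` builds paired-contrast test data with no
external downloads: a shared anatomy of nested/overlapping ellipsoids
(later structures overwrite earlier ones, so labels partition the grid),
mapped through two intensity tables with inverted orderings to emulate
T1/T2-like contrast inversion, plus optional lesions inserted into only
one modality — the situation where hyperintense lesions are visible in T2
but not T1. Boundaries are softened with a Gaussian of 0.8 voxels to
emulate partial-volume mixing. Geometry, lesions and noise are all seeded.

What the phantom preserves from real paired-contrast brain data are
exactly the two properties the method exploits: cross-modal structural
correspondence (shared boundaries under different intensity mappings) and
intra-modal self-similarity. What it does not emulate: MR physics (bias
fields, relaxometry), gyral/cortical geometry, scanner-correlated noise,
and texture within tissues. Passing tests therefore demonstrate the
mechanism and its orderings (guided reconstruction ≫ spline ≫ nearest;
graceful degradation with noise and misregistration), not absolute dB
values on real brains — absolute numbers also depend on a PSNR peak
convention that differs between datasets.

Default study sizes are 64³ for the noiseless comparisons and 48³ for the
noise and misregistration protocols, chosen so a full simulated experiment
runs in minutes on a single core while leaving the anatomy several tissue
shells deep; `shape` scales up freely.

## Numerical details and edge cases

* **Borders.** Strict mode requires divisible dimensions and errors with
  the offending axis otherwise; `pad_edge` mode edge-replicates up to the
  next multiple before averaging, and upsampling crops back to the
  recorded HR shape, preserving the round-trip identity.
* **Degenerate inputs.** Constant volumes are fixed points of every
  operator (all weights equal); `sigma = 0` short-circuits the denoiser
  and the noise generator; identical volumes make PSNR infinite rather
  than erroring.
* **Convexity.** Each reconstruction pass is a convex combination, so the
  intensity range never expands during averaging; only the mean
  correction can move values outside the input range (as it must, to
  restore block means).
* **Determinism.** The reconstruction contains no randomness; phantom and
  noise generation consume an isolated RNG stream restored afterwards, so
  package calls do not perturb a caller's random state.
* **Stopping.** MAD is computed over all voxels on the native scale
  against `tol * range_peak / 255`. The `max_iters = 50` cap exists for
  badly misregistered references where convergence can stall; typical
  runs converge in 10–40 iterations.

## Limitations

Registration is a precondition, not a feature: the package assumes the
inputs share a rigid geometric frame and only quantifies (via the shift
protocol) how much residual misalignment the self-similarity term can
absorb — about one voxel before the advantage over spline interpolation
halves, two to three before it disappears. The degradation model is a pure
boxcar; Gaussian slice profiles, slice gaps and k-space apodisation are
out of scope, as are non-integer resolution ratios. NIfTI-1 is the only
supported container, and reconstruction operates on voxel grids — header
affines beyond the voxel spacing are not propagated.
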