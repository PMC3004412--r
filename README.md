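# mrsr — multimodal superresolution reconstruction of MR volumes

`mrsr` reconstructs a high-resolution (HR) version of a low-resolution
(LR) 3D magnetic-resonance volume using a coplanar HR volume of another
contrast from the same subject as a structural guide. Typical use case: a
thick-slice T2-weighted or FLAIR acquisition upsampled to the grid of a
1 mm³ T1-weighted scan for registration, segmentation, or multimodal
feature extraction — with sharper anatomy than any interpolation can
provide, and with outputs that remain exactly consistent with the MR
acquisition physics.

## The method

Acquisition is modeled as block averaging plus Rician noise,
`y = DHx + n`, where the boxcar blur `H` matched to the decimation `D`
makes each LR voxel the mean of its HR block. After denoising both inputs
(Rician-bias-corrected nonlocal means), the reconstruction `x̂` is built
by iterating two steps on the HR grid:

1. **Guided averaging** — every voxel becomes a weighted average over a
   7×7×7 search window, weights combining a sigma filter on the HR
   reference `z` with a patch-based nonlocal-means term on the current
   reconstruction:

   `x̂_p ← (1/C_p) Σ_q x̂_q · exp(−(z_p−z_q)²/h²) · exp(−‖N(x̂_p)−N(x̂_q)‖²/(k h²))`

2. **Mean correction** — block means are snapped back onto the LR data,
   `x̂ ← x̂ − NN(DH x̂ − y)`, so the subsampling-consistency constraint
   `DH x̂ = y` holds exactly after every iteration.

The filtering strength `h` follows a decremental coarse-to-fine schedule
(32, 16, 8, 4, 2 on the 8-bit scale, rescaled to the data range); after
one pass per value the iteration continues at the last one until the mean
absolute difference between consecutive volumes drops below tolerance.

The package also ships the acquisition/degradation model with seeded
Rician noise simulation, interpolation baselines (nearest, trilinear,
cubic, B-spline) on the same block-centre geometry, PSNR/IPSNR
evaluation, a paired-contrast synthetic brain phantom generator for fully
self-contained experiments, NIfTI-1 I/O, and a CLI
(`inst/cli/mrsr`) plus YAML-configurable pipeline driver.

## Worked example

```r
library(mrsr)

# a paired-contrast phantom study: modality B degraded to 3x slice
# thickness, modality A kept at high resolution as the reference
bundle <- simulate_study(phantom_spec(shape = c(48, 48, 48), seed = 42),
                         degradation_spec(c(1, 1, 3)),
                         rician_noise_spec(0))

res <- superresolve(bundle$lr_input, bundle$hr_reference, bundle$spec,
                    sr_params())
res$state$iteration
#> [1] 19

psnr(bundle$hr_truth, res$volume)
#> [1] 45.57617
psnr(bundle$hr_truth, interpolate_upsample(bundle$lr_input, bundle$spec, "bspline"))
#> [1] 30.26229
psnr(bundle$hr_truth, interpolate_upsample(bundle$lr_input, bundle$spec, "nearest"))
#> [1] 24.50020

max(abs(boxcar_downsample(res$volume, bundle$spec)$data - bundle$lr_input$data))
#> [1] 2.842171e-14
```

The guided reconstruction recovers the truth at 45.6 dB PSNR versus
30.3 dB for B-spline and 24.5 dB for nearest-neighbour interpolation — a
15 dB improvement — while reproducing the LR input exactly (sup-norm
error at machine precision) when downsampled through the acquisition
model. The same pipeline can be driven from a single config:

```r
run_pipeline(list(stages = list("simulate", "reconstruct", "evaluate"),
                  seed = 42,
                  simulate = list(shape = c(48, 48, 48), factors = c(1, 1, 3))))
```

See `vignettes/methods.Rmd` for the model, parameter meanings, and the
design decisions behind the implementation.

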