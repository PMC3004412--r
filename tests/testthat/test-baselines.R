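test_that("nearest upsampling is block replication and all methods fix constants", {
  y <- random_volume(c(4, 4, 3), seed = 41)
  sp <- degradation_spec(c(1, 1, 3))
  expect_identical(interpolate_upsample(y, sp, "nearest")$data,
                   block_replicate_upsample(y, sp)$data)
  const <- volume3d(array(9.5, c(4, 4, 4)))
  sp2 <- degradation_spec(c(2, 2, 2))
  for (m in c("nearest", "trilinear", "cubic", "bspline")) {
    out <- interpolate_upsample(const, sp2, m)
    expect_identical(dim(out$data), c(8L, 8L, 8L))
    expect_equal(out$data, array(9.5, c(8, 8, 8)), tolerance = 1e-12,
                 info = m)
  }
})

test_that("trilinear upsampling is exact on a linear ramp away from borders", {
  d <- c(4, 4, 8)
  ramp <- volume3d(array(rep(seq_len(d[3]), each = 16), d))
  sp <- degradation_spec(c(1, 1, 2))
  up <- interpolate_upsample(ramp, sp, "trilinear")
  # HR z-index i samples the LR ramp at (i - 0.5)/2 + 0.5 (block-centre
  # alignment); interior values must lie on that same affine ramp
  expected <- (seq_len(16) - 0.5) / 2 + 0.5
  interior <- 3:14
  expect_equal(up$data[2, 2, interior], expected[interior], tolerance = 1e-12)
  # cubic and spline interpolation are also exact on affine signals, but
  # their wider supports feel the clamped border further in
  deep <- 5:12
  for (m in c("cubic", "bspline")) {
    up2 <- interpolate_upsample(ramp, sp, m)
    expect_equal(up2$data[2, 2, deep], expected[deep],
                 tolerance = 1e-9, info = m)
  }
})

test_that("interpolation geometry is consistent with the block-mean model", {
  # downsample-then-upsample of a smooth field should roughly recover it,
  # with smoother kernels doing at least as well as replication
  ph <- generate_multimodal_phantom(phantom_spec(shape = c(24, 24, 24), seed = 6))
  hr <- ph$modality_b
  sp <- degradation_spec(c(1, 1, 2))
  lr <- boxcar_downsample(hr, sp)
  p_nn <- psnr(hr, interpolate_upsample(lr, sp, "nearest"))
  p_bs <- psnr(hr, interpolate_upsample(lr, sp, "bspline"))
  expect_gt(p_bs, p_nn)
})

test_that("PSNR follows its closed form and degrades with noise", {
  ref <- volume3d(array(0, c(4, 4, 4)), range_peak = 255)
  expect_identical(psnr(ref, ref), Inf)
  bad <- volume3d(array(255, c(4, 4, 4)))
  expect_equal(psnr(ref, bad, peak = 255), 0)
  # MSE = 1 at peak 255
  off <- volume3d(array(1, c(4, 4, 4)))
  expect_equal(psnr(ref, off, peak = 255), 48.1308, tolerance = 1e-4)
  expect_error(psnr(ref, volume3d(array(0, c(5, 5, 5)))), "grid")

  v <- random_volume(c(16, 16, 16), seed = 42)
  ps <- sapply(c(1, 4, 16), function(s) {
    noisy <- add_rician_noise(v, rician_noise_spec(sigma = s, seed = 43))
    psnr(v, noisy)
  })
  expect_true(all(diff(ps) < 0))
})

test_that("IPSNR is a PSNR difference and antisymmetric", {
  ref <- random_volume(c(8, 8, 8), seed = 44)
  a <- add_rician_noise(ref, rician_noise_spec(sigma = 1, seed = 45))
  b <- add_rician_noise(ref, rician_noise_spec(sigma = 3, seed = 46))
  expect_equal(ipsnr(ref, a, a), 0)
  expect_equal(ipsnr(ref, a, b), -ipsnr(ref, b, a))
  expect_equal(ipsnr(ref, a, b), psnr(ref, a) - psnr(ref, b))
  expect_identical(ipsnr(ref, ref, a), Inf)
  # a tenfold MSE ratio is exactly 10 dB
  e1 <- vol_like_test(ref, ref$data + 1)
  e10 <- vol_like_test(ref, ref$data + sqrt(10))
  expect_equal(ipsnr(ref, e1, e10), 10, tolerance = 1e-10)
})

test_that("volume shifting translates content with edge replication", {
  v <- random_volume(c(8, 8, 8), seed = 47)
  expect_identical(shift_volume(v, c(0, 0, 0))$data, v$data)
  const <- volume3d(array(3, c(6, 6, 6)))
  expect_equal(shift_volume(const, c(2, -1, 3))$data, const$data)

  s <- shift_volume(v, c(2, 0, 0))
  expect_equal(s$data[3:8, , ], v$data[1:6, , ])
  back <- shift_volume(s, c(-2, 0, 0))
  expect_equal(back$data[3:6, , ], v$data[3:6, , ])  # away from the margin

  half <- shift_volume(v, c(0.5, 0, 0), mode = "trilinear")
  expect_equal(half$data[4, 2, 2], (v$data[3, 2, 2] + v$data[4, 2, 2]) / 2)
  expect_error(shift_volume(v, c(0.5, 0, 0), mode = "integer"), "whole")
  expect_error(shift_volume(v, c(9, 0, 0)), "offset")
})
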