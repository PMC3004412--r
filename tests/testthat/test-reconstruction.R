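test_that("reconstruction step matches the naive seven-loop oracle", {
  x <- random_volume(c(8, 8, 8), seed = 31, lo = 0, hi = 1, peak = 1)
  z <- random_volume(c(8, 8, 8), seed = 32, lo = 0, hi = 1, peak = 1)
  pars <- sr_params(search_radius = 3, patch_radius = 1, k = 4)
  for (h in c(0.1, 0.4)) {
    got <- reconstruction_step(x, z, pars, h = h)
    want <- naive_recon_step(x$data, z$data, sr = 3, pr = 1,
                             h2 = h^2, kh2 = 4 * h^2)
    expect_equal(got$data, want, tolerance = 1e-10)
  }
  # smaller search radius exercises the window clipping differently
  pars1 <- sr_params(search_radius = 1, patch_radius = 1, k = 4)
  got <- reconstruction_step(x, z, pars1, h = 0.2)
  want <- naive_recon_step(x$data, z$data, sr = 1, pr = 1,
                           h2 = 0.2^2, kh2 = 4 * 0.2^2)
  expect_equal(got$data, want, tolerance = 1e-10)
})

test_that("reconstruction step is a convex combination and fixes constants", {
  x <- random_volume(c(10, 10, 10), seed = 33)
  z <- random_volume(c(10, 10, 10), seed = 34)
  out <- reconstruction_step(x, z, sr_params(), h = 8)
  expect_true(all(out$data >= min(x$data) - 1e-9))
  expect_true(all(out$data <= max(x$data) + 1e-9))

  const <- volume3d(array(42, c(8, 8, 8)), range_peak = 255)
  out2 <- reconstruction_step(const, const, sr_params(), h = 8)
  expect_equal(out2$data, const$data, tolerance = 1e-12)

  expect_error(reconstruction_step(x, random_volume(c(8, 8, 8), 1),
                                   sr_params(), h = 8), "grid")
  expect_error(reconstruction_step(x, z, sr_params(), h = 0), "h must be")
})

test_that("with a constant reference the step reduces to a pure patch NLM", {
  x <- random_volume(c(8, 8, 8), seed = 35, lo = 0, hi = 1, peak = 1)
  z <- volume3d(array(1, c(8, 8, 8)))
  k <- 16; h <- 0.1
  got <- reconstruction_step(x, z, sr_params(k = k), h = h)
  # sigma term is identically 1, so weights equal exp(-SSD/(k h^2)):
  # the denoiser's averaging stage at bandwidth sqrt(k)*h
  want <- nlm_average(x, h = sqrt(k) * h)
  expect_equal(got$data, want$data, tolerance = 1e-10)
})

test_that("combined weights are symmetric under p-q exchange", {
  # both the sigma term (z_p - z_q)^2 and the patch SSD are symmetric
  # distances, so w(p,q) = w(q,p); check on the raw kernel ingredients
  x <- random_volume(c(6, 6, 6), seed = 36, lo = 0, hi = 1, peak = 1)
  p <- c(2, 3, 4); q <- c(4, 3, 2)
  ssd_pq <- sum((get_patch(x$data, p[1], p[2], p[3], 1) -
                 get_patch(x$data, q[1], q[2], q[3], 1))^2)
  ssd_qp <- sum((get_patch(x$data, q[1], q[2], q[3], 1) -
                 get_patch(x$data, p[1], p[2], p[3], 1))^2)
  expect_identical(ssd_pq, ssd_qp)
})

test_that("mean correction enforces subsampling consistency", {
  sp <- degradation_spec(c(1, 1, 2))
  x <- random_volume(c(6, 6, 6), seed = 37)
  y <- random_volume(c(6, 6, 3), seed = 38)
  out <- mean_correction(x, y, sp)
  expect_lt(max(abs(boxcar_downsample(out, sp)$data - y$data)), 1e-10)

  # already-consistent input is a fixed point
  y2 <- boxcar_downsample(x, sp)
  expect_equal(mean_correction(x, y2, sp)$data, x$data, tolerance = 1e-12)
  up <- block_replicate_upsample(y, sp)
  expect_equal(mean_correction(up, y, sp)$data, up$data, tolerance = 1e-12)

  expect_error(mean_correction(x, random_volume(c(5, 5, 5), 1), sp), "grid")
})

test_that("h-schedule scaling is linear in the intensity range", {
  expect_equal(scale_h_schedule(c(32, 16, 8, 4, 2), 255), c(32, 16, 8, 4, 2))
  expect_equal(scale_h_schedule(c(32, 16, 8, 4, 2), 510), c(64, 32, 16, 8, 4))
  expect_error(scale_h_schedule(c(32), 0), "range_peak")
  # the default 8-bit schedule expressed as a fraction of the range starts
  # near 12.5% and halves each stage
  expect_equal(32 / 255, 0.1255, tolerance = 0.001)
})

test_that("superresolve keeps a constant fixed and records its schedule", {
  const <- volume3d(array(100, c(8, 8, 8)), range_peak = 255)
  sp <- degradation_spec(c(2, 2, 2))
  y <- boxcar_downsample(const, sp)
  z <- volume3d(array(50, c(8, 8, 8)), range_peak = 255)
  res <- superresolve(y, z, sp, sr_params())
  expect_equal(res$volume$data, const$data, tolerance = 1e-10)
  expect_equal(res$state$h_history, c(32, 16, 8, 4, 2))
  expect_true(res$state$converged)
  expect_equal(res$state$iteration, 5L)  # one pass per h, MAD already 0
})

test_that("superresolve converges, is consistent, and validates its inputs", {
  ph <- generate_multimodal_phantom(phantom_spec(shape = c(24, 24, 24), seed = 4))
  sp <- degradation_spec(c(1, 1, 2))
  y <- boxcar_downsample(ph$modality_b, sp)
  res <- superresolve(y, ph$modality_a, sp, sr_params())
  st <- res$state
  expect_true(st$converged)
  expect_lt(st$mad_history[st$iteration], st$tol_native)
  # exactly one pass per scheduled h, then the terminal-h loop
  expect_equal(st$h_history[1:5], scale_h_schedule(c(32, 16, 8, 4, 2), 255))
  if (st$iteration > 5) {
    expect_true(all(st$h_history[6:st$iteration] == st$h_history[5]))
  }
  expect_lt(max(abs(boxcar_downsample(res$volume, sp)$data - y$data)), 1e-10)

  expect_error(superresolve(y, ph$modality_a, degradation_spec(c(1, 1, 3)),
                            sr_params()), "incompatib")
  expect_error(sr_params(h_schedule = c(2, 4)), "decreasing")
  expect_error(sr_params(tol = 0), "tol")
})

test_that("reconstruction is deterministic given its inputs", {
  ph <- generate_multimodal_phantom(phantom_spec(shape = c(16, 16, 16), seed = 5))
  sp <- degradation_spec(c(1, 1, 2))
  y <- boxcar_downsample(ph$modality_b, sp)
  r1 <- superresolve(y, ph$modality_a, sp, sr_params())
  r2 <- superresolve(y, ph$modality_a, sp, sr_params())
  expect_identical(r1$volume$data, r2$volume$data)
  expect_identical(r1$state$mad_history, r2$state$mad_history)
})
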