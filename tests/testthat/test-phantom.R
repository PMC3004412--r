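test_that("phantom generation is deterministic and labels partition the grid", {
  spec <- phantom_spec(shape = c(32, 32, 32), seed = 9)
  p1 <- generate_multimodal_phantom(spec)
  p2 <- generate_multimodal_phantom(spec)
  expect_identical(p1$modality_a$data, p2$modality_a$data)
  expect_identical(p1$modality_b$data, p2$modality_b$data)
  expect_identical(p1$labels, p2$labels)

  expect_true(all(p1$labels %in% 0:5))
  expect_identical(dim(p1$labels), c(32L, 32L, 32L))
  # background plus several tissue classes are actually populated
  expect_gte(length(unique(as.vector(p1$labels))), 4L)
  expect_true(0L %in% p1$labels)
  # different seed moves the geometry
  p3 <- generate_multimodal_phantom(phantom_spec(shape = c(32, 32, 32), seed = 10))
  expect_false(identical(p1$labels, p3$labels))
})

test_that("a single unsmoothed structure yields two-valued volumes with one support", {
  spec <- phantom_spec(shape = c(16, 16, 16), n_structures = 1,
                       pv_smoothing_sigma = 0, seed = 11)
  p <- generate_multimodal_phantom(spec)
  expect_identical(sort(unique(as.vector(p$modality_a$data))),
                   sort(unique(spec$contrast_A)))
  expect_identical(sort(unique(as.vector(p$modality_b$data))),
                   sort(unique(spec$contrast_B)))
  support_a <- p$modality_a$data != spec$contrast_A[1]
  support_b <- p$modality_b$data != spec$contrast_B[1]
  expect_identical(support_a, support_b)
})

test_that("unsmoothed volumes attain only table values; smoothing stays in range", {
  spec0 <- phantom_spec(shape = c(24, 24, 24), pv_smoothing_sigma = 0, seed = 12)
  p0 <- generate_multimodal_phantom(spec0)
  expect_true(all(p0$modality_a$data %in% spec0$contrast_A))
  expect_true(all(p0$modality_b$data %in% spec0$contrast_B))

  spec1 <- phantom_spec(shape = c(24, 24, 24), pv_smoothing_sigma = 0.8, seed = 12)
  p1 <- generate_multimodal_phantom(spec1)
  expect_true(all(p1$modality_a$data >= min(spec1$contrast_A) - 1e-9))
  expect_true(all(p1$modality_a$data <= max(spec1$contrast_A) + 1e-9))
  expect_true(all(p1$modality_b$data >= min(spec1$contrast_B) - 1e-9))
  expect_true(all(p1$modality_b$data <= max(spec1$contrast_B) + 1e-9))
})

test_that("a lesion visible in one modality decorrelates the pair locally", {
  spec <- phantom_spec(shape = c(40, 40, 40), seed = 13,
                       lesion = list(count = 3, radius_range = c(2.5, 4),
                                     visible_in = "B", intensity_B = 255))
  p <- generate_multimodal_phantom(spec)
  expect_true(any(p$lesion_mask))
  host <- p$labels == spec$n_structures
  lesion <- p$lesion_mask
  healthy <- host & !lesion
  cor_lesion <- abs(cor(p$modality_a$data[lesion], p$modality_b$data[lesion]))
  cor_healthy <- abs(cor(p$modality_a$data[healthy], p$modality_b$data[healthy]))
  expect_lt(cor_lesion, cor_healthy)
  # the lesion leaves modality A untouched
  spec_nl <- spec; spec_nl$lesion <- NULL
  pn <- generate_multimodal_phantom(spec_nl)
  expect_identical(p$modality_a$data, pn$modality_a$data)
  expect_false(identical(p$modality_b$data, pn$modality_b$data))
})

test_that("simulated studies wire the degradation model correctly", {
  pspec <- phantom_spec(shape = c(16, 16, 16), seed = 14)
  b0 <- simulate_study(pspec, degradation_spec(c(1, 1, 1)),
                       rician_noise_spec(0))
  expect_identical(b0$lr_input$data, b0$hr_truth$data)

  b1 <- simulate_study(phantom_spec(shape = c(64, 64, 64), seed = 14),
                       degradation_spec(c(1, 1, 3), "pad_edge"),
                       rician_noise_spec(0))
  expect_identical(dim(b1$lr_input$data), c(64L, 64L, 22L))

  # noisy bundle: LR and reference get independent noise streams
  bn <- simulate_study(pspec, degradation_spec(c(1, 1, 2)),
                       rician_noise_spec(percent_of_max = 2, seed = 15))
  clean <- simulate_study(pspec, degradation_spec(c(1, 1, 2)),
                          rician_noise_spec(0))
  expect_false(identical(bn$lr_input$data, clean$lr_input$data))
  expect_false(identical(bn$hr_reference$data, clean$hr_reference$data))
  b_ref_clean <- simulate_study(pspec, degradation_spec(c(1, 1, 2)),
                                rician_noise_spec(percent_of_max = 2, seed = 15),
                                noise_reference = FALSE)
  expect_identical(b_ref_clean$hr_reference$data, clean$hr_reference$data)
})

test_that("contrast tables must cover every label", {
  expect_error(phantom_spec(n_structures = 3, contrast_A = c(0, 1, 2)),
               "every label")
  expect_error(phantom_spec(contrast_A = c(0, 10, 20, 30, 40, 300)),
               "\\[0, 255\\]")
  expect_error(phantom_spec(lesion = list(count = 1, radius_range = c(0.5, 1))),
               "radii")
})
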