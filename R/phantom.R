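#' Specification of a paired-contrast synthetic brain phantom
#'
#' Describes a BrainWeb-style pair of co-registered volumes: one shared
#' piecewise-constant anatomy (nested/overlapping ellipsoidal tissue
#' regions), two intensity mappings emulating two MR contrasts, optional
#' lesions visible in only one modality, and partial-volume softening of
#' tissue boundaries by a small Gaussian blur.
#'
#' @param shape HR grid dimensions (default `c(64, 64, 64)`).
#' @param n_structures number of ellipsoidal tissue regions layered from
#'   outside in (default 5: head, skull/CSF-like shells, and inner
#'   tissue blobs).
#' @param contrast_A,contrast_B numeric vectors of length
#'   `n_structures + 1` mapping labels `0..n_structures` to intensities on
#'   the 8-bit scale. Defaults are inverted between the modalities (bright
#'   inner tissue in A, dark in B) to emulate T1/T2-like contrast
#'   inversion.
#' @param pv_smoothing_sigma Gaussian sigma in voxels for partial-volume
#'   boundary softening (default 0.8; 0 disables it).
#' @param lesion optional list with elements `count`, `radius_range`
#'   (voxels, min/max), `visible_in` (subset of `c("A", "B")`),
#'   `intensity_A`, `intensity_B`.
#' @param seed integer seed controlling geometry and lesion placement.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), n_structures = 5L,
                         contrast_A = NULL, contrast_B = NULL,
                         pv_smoothing_sigma = 0.8, lesion = NULL,
                         seed = 42L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) {
    stop("shape must be 3 integers >= 8", call. = FALSE)
  }
  n_structures <- as.integer(n_structures)
  if (n_structures < 1L) stop("n_structures must be >= 1", call. = FALSE)
  if (is.null(contrast_A)) {
    contrast_A <- c(0, seq(70, 250, length.out = n_structures))
  }
  if (is.null(contrast_B)) {
    contrast_B <- c(0, seq(250, 45, length.out = n_structures))
  }
  n_labels <- n_structures + 1L
  if (length(contrast_A) != n_labels || length(contrast_B) != n_labels) {
    stop(sprintf("contrast tables must map every label 0..%d (length %d)",
                 n_structures, n_labels), call. = FALSE)
  }
  if (any(contrast_A < 0 | contrast_A > 255) ||
      any(contrast_B < 0 | contrast_B > 255)) {
    stop("contrast intensities must lie in [0, 255]", call. = FALSE)
  }
  if (!is.null(lesion)) {
    stopifnot(is.list(lesion))
    lesion$count <- as.integer(lesion$count %||% 1L)
    lesion$radius_range <- as.numeric(lesion$radius_range %||% c(2, 4))
    lesion$visible_in <- lesion$visible_in %||% "B"
    lesion$intensity_A <- as.numeric(lesion$intensity_A %||% 255)
    lesion$intensity_B <- as.numeric(lesion$intensity_B %||% 255)
    if (any(lesion$radius_range < 1)) {
      stop("lesion radii must be >= 1 voxel", call. = FALSE)
    }
    if (!all(lesion$visible_in %in% c("A", "B"))) {
      stop("lesion visible_in must be a subset of c('A', 'B')", call. = FALSE)
    }
  }
  if (pv_smoothing_sigma < 0) stop("pv_smoothing_sigma must be >= 0", call. = FALSE)
  structure(list(shape = shape, n_structures = n_structures,
                 contrast_A = as.numeric(contrast_A),
                 contrast_B = as.numeric(contrast_B),
                 pv_smoothing_sigma = pv_smoothing_sigma,
                 lesion = lesion, seed = as.integer(seed)),
            class = "phantom_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Inside-ellipsoid mask from per-axis grid coordinates cx, cy, cz.
ellipsoid_mask <- function(cx, cy, cz, centre, semi) {
  tx <- ((cx - centre[1]) / semi[1])^2
  ty <- ((cy - centre[2]) / semi[2])^2
  tz <- ((cz - centre[3]) / semi[3])^2
  outer(outer(tx, ty, `+`), tz, `+`) <= 1
}

# Separable Gaussian blur with edge replication (weights folded inwards so
# every row of the 1D operator sums to one — a convex combination).
gauss_smooth_3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-r):r)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  for (ax in 1:3) {
    m <- dim(a)[ax]
    W <- matrix(0, m, m)
    for (i in seq_len(m)) {
      idx <- pmin(pmax(i + (-r):r, 1L), m)
      for (q in seq_along(idx)) W[i, idx[q]] <- W[i, idx[q]] + kern[q]
    }
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    d <- dim(ap)
    dim(ap) <- c(d[1], d[2] * d[3])
    ap <- W %*% ap
    dim(ap) <- d
    a <- aperm(ap, order(perm))
  }
  a
}

#' Generate a paired-contrast synthetic phantom
#'
#' Builds one label geometry of nested/overlapping ellipsoids (later
#' structures overwrite earlier ones, so every voxel carries exactly one
#' label), maps it through the two contrast tables, optionally inserts
#' lesions into the modalities listed in `visible_in`, and softens the
#' boundaries with a Gaussian blur to emulate partial-volume mixing.
#' Deterministic given the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return a list with [volume3d()] fields `modality_a`, `modality_b`
#'   (both with `range_peak = 255`), an integer `labels` array, and a
#'   logical `lesion_mask` array (all `FALSE` when no lesion was
#'   requested).
#' @export
generate_multimodal_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  with_seed(spec$seed, {
    cx <- seq_len(d[1]) - (d[1] + 1) / 2
    cy <- seq_len(d[2]) - (d[2] + 1) / 2
    cz <- seq_len(d[3]) - (d[3] + 1) / 2
    labels <- array(0L, d)
    base_semi <- d / 2 * 0.88
    for (e in seq_len(spec$n_structures)) {
      shrink <- 0.88^(e - 1)
      jitter <- if (e == 1) c(0, 0, 0) else stats::runif(3, -0.08, 0.08) * d
      semi <- base_semi * shrink * stats::runif(3, 0.75, 1.05)
      mask <- ellipsoid_mask(cx, cy, cz, jitter, semi)
      labels[mask] <- e
    }
    lesion_mask <- array(FALSE, d)
    if (!is.null(spec$lesion)) {
      host <- which(labels == spec$n_structures)
      if (length(host) == 0L) {
        stop("no voxels of the innermost label to host lesions", call. = FALSE)
      }
      centres <- sample(host, spec$lesion$count)
      rr <- spec$lesion$radius_range
      for (cidx in centres) {
        pos <- arrayInd(cidx, d)
        radius <- stats::runif(1, rr[1], rr[2])
        mask <- ellipsoid_mask(seq_len(d[1]) - pos[1], seq_len(d[2]) - pos[2],
                               seq_len(d[3]) - pos[3], c(0, 0, 0),
                               rep(radius, 3))
        lesion_mask <- lesion_mask | mask
      }
    }
    A <- array(spec$contrast_A[labels + 1L], d)
    B <- array(spec$contrast_B[labels + 1L], d)
    if (any(lesion_mask)) {
      if ("A" %in% spec$lesion$visible_in) A[lesion_mask] <- spec$lesion$intensity_A
      if ("B" %in% spec$lesion$visible_in) B[lesion_mask] <- spec$lesion$intensity_B
    }
    A <- gauss_smooth_3d(A, spec$pv_smoothing_sigma)
    B <- gauss_smooth_3d(B, spec$pv_smoothing_sigma)
    list(modality_a = volume3d(A, range_peak = 255),
         modality_b = volume3d(B, range_peak = 255),
         labels = labels,
         lesion_mask = lesion_mask)
  })
}

#' Simulate one superresolution study from a phantom
#'
#' Generates the phantom, takes modality B as the ground-truth HR volume
#' and modality A as the HR reference, degrades B through the acquisition
#' model and adds Rician noise to the LR input. The same noise level is
#' applied to the HR reference (with an independent noise stream), matching
#' the situation where both acquisitions share the scanner noise floor;
#' `noise_reference = FALSE` keeps the reference clean.
#'
#' @param pspec a [phantom_spec()].
#' @param dspec a [degradation_spec()].
#' @param noise a [rician_noise_spec()] for the LR input.
#' @param noise_reference also corrupt the HR reference (default `TRUE`).
#' @return a `study_bundle` list: `hr_truth`, `hr_reference`, `lr_input`
#'   ([volume3d()]s), `spec`, `noise`, `labels`, `lesion_mask`.
#' @export
simulate_study <- function(pspec, dspec, noise = rician_noise_spec(0),
                           noise_reference = TRUE) {
  ph <- generate_multimodal_phantom(pspec)
  hr_truth <- ph$modality_b
  lr_clean <- boxcar_downsample(hr_truth, dspec)
  lr_input <- add_rician_noise(lr_clean, noise)
  hr_reference <- ph$modality_a
  sigma <- resolve_sigma(noise, hr_truth)
  if (noise_reference && sigma > 0) {
    ref_noise <- rician_noise_spec(sigma = sigma,
                                   seed = (noise$seed + 1L) %% .Machine$integer.max)
    hr_reference <- add_rician_noise(hr_reference, ref_noise)
  }
  structure(list(hr_truth = hr_truth, hr_reference = hr_reference,
                 lr_input = lr_input, spec = dspec, noise = noise,
                 labels = ph$labels, lesion_mask = ph$lesion_mask),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> HR %s -> LR %s, factors %s\n",
              paste(dim(x$hr_truth$data), collapse = "x"),
              paste(dim(x$lr_input$data), collapse = "x"),
              paste(x$spec$factors, collapse = "x")))
  invisible(x)
}
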