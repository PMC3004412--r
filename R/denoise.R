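#' Parameters of the Rician nonlocal-means denoiser
#'
#' @param search_radius search-window radius in voxels (default 3, i.e. a
#'   7x7x7 window).
#' @param patch_radius patch radius in voxels (default 1, i.e. 3x3x3
#'   patches).
#' @param sigma noise standard deviation in intensity units, or `NULL` to
#'   estimate it from the data with [estimate_sigma()].
#' @param beta filtering-strength multiplier (default 1); the automatic
#'   bandwidth is `h^2 = 2 * beta * sigma^2 * patch_size`.
#' @export
denoise_params <- function(search_radius = 3L, patch_radius = 1L,
                           sigma = NULL, beta = 1.0) {
  search_radius <- as.integer(search_radius)
  patch_radius <- as.integer(patch_radius)
  if (patch_radius < 0L || search_radius < patch_radius) {
    stop("need search_radius >= patch_radius >= 0", call. = FALSE)
  }
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  }
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  structure(list(search_radius = search_radius, patch_radius = patch_radius,
                 sigma = sigma, beta = beta),
            class = "denoise_params")
}

#' Nonlocal-means weighted average (the averaging stage)
#'
#' The plain NLM averaging stage, exposed on its own: every voxel is
#' replaced by a weighted average of the search-window voxels with weights
#' `exp(-SSD(p, q) / h^2)`, where SSD is the raw sum of squared differences
#' over mirror-padded patches. This is the common filtering primitive: the
#' denoiser applies it to squared intensities before bias correction, and
#' the reconstruction step reduces to it when the reference volume is
#' constant.
#'
#' @param v a [volume3d()] supplying the patch similarities.
#' @param h filtering bandwidth (the weights use `h^2`).
#' @param values optional 3D array averaged instead of `v$data` (same grid);
#'   the weights are always computed from `v$data`.
#' @inheritParams denoise_params
#' @return a [volume3d()] on the same grid.
#' @export
nlm_average <- function(v, h, search_radius = 3L, patch_radius = 1L,
                        values = NULL) {
  stop_if_not_volume(v, "v")
  if (!is.finite(h) || h <= 0) stop("h must be > 0", call. = FALSE)
  if (is.null(values)) values <- v$data
  stopifnot(identical(dim(values), dim(v$data)))
  out <- cpp_patch_nlm(as.vector(v$data), as.vector(values), dim(v$data),
                       as.integer(search_radius), as.integer(patch_radius),
                       h^2)
  dim(out) <- dim(v$data)
  vol_like(v, out)
}

#' Rician bias correction of a filtered second moment
#'
#' For a Rice-distributed magnitude M with underlying signal A and channel
#' noise sigma, `E[M^2] = A^2 + 2*sigma^2`. Given a (filtered) estimate of
#' the second moment this inverts the relation, clamping at zero:
#' `sqrt(max(m2 - 2*sigma^2, 0))`.
#'
#' @param filtered_second_moment non-negative value(s) of the filtered
#'   squared intensity.
#' @param sigma noise standard deviation, >= 0.
#' @return the bias-corrected amplitude(s).
#' @examples
#' rician_bias_correct(10^2 + 2 * 3^2, 3)  # recovers 10
#' @export
rician_bias_correct <- function(filtered_second_moment, sigma) {
  if (any(!is.finite(filtered_second_moment)) || !is.finite(sigma)) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (any(filtered_second_moment < 0) || sigma < 0) {
    stop("inputs must be >= 0", call. = FALSE)
  }
  sqrt(pmax(filtered_second_moment - 2 * sigma^2, 0))
}

#' Denoise a volume with a Rician-adapted nonlocal-means filter
#'
#' The mandatory preprocessing step before reconstruction: a voxelwise 3D
#' nonlocal-means filter whose weights come from patch similarity of the
#' intensities, applied to the squared intensities, followed by voxelwise
#' Rician bias correction (`sqrt(max(. - 2 sigma^2, 0))`). With
#' `sigma = 0` the input is returned unchanged.
#'
#' @param noisy a [volume3d()].
#' @param params a [denoise_params()]; if its `sigma` is `NULL` the noise
#'   level is estimated with [estimate_sigma()].
#' @return the denoised [volume3d()].
#' @export
nlm_denoise <- function(noisy, params = denoise_params()) {
  stop_if_not_volume(noisy, "noisy")
  sigma <- params$sigma
  if (is.null(sigma)) sigma <- estimate_sigma(noisy)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(noisy)
  npatch <- (2L * params$patch_radius + 1L)^3
  h2 <- 2 * params$beta * sigma^2 * npatch
  m2 <- cpp_patch_nlm(as.vector(noisy$data), as.vector(noisy$data)^2,
                      dim(noisy$data), params$search_radius,
                      params$patch_radius, h2)
  out <- rician_bias_correct(m2, sigma)
  dim(out) <- dim(noisy$data)
  vol_like(noisy, out)
}

#' Estimate the noise standard deviation of a volume
#'
#' A robust estimate from high-frequency pseudo-residuals: at each interior
#' voxel the residual against the mean of its six face neighbours is
#' computed (a discrete Laplacian, whose standard deviation under i.i.d.
#' noise of level sigma is `sigma * sqrt(7/6)`), and sigma is recovered
#' from the median absolute deviation of those residuals. The estimate is
#' approximate — it treats the noise as additive Gaussian, which for
#' magnitude MR data is accurate away from the low-SNR background.
#'
#' @param noisy a [volume3d()] with at least 1000 voxels.
#' @return the estimated sigma (0 for a constant volume).
#' @export
estimate_sigma <- function(noisy) {
  stop_if_not_volume(noisy, "noisy")
  a <- noisy$data
  d <- dim(a)
  if (prod(d) < 1000) {
    stop("estimate_sigma needs at least 10^3 voxels", call. = FALSE)
  }
  ii <- 2:(d[1] - 1); jj <- 2:(d[2] - 1); kk <- 2:(d[3] - 1)
  nb <- a[ii - 1, jj, kk] + a[ii + 1, jj, kk] +
        a[ii, jj - 1, kk] + a[ii, jj + 1, kk] +
        a[ii, jj, kk - 1] + a[ii, jj, kk + 1]
  r <- a[ii, jj, kk] - nb / 6
  stats::mad(as.vector(r), center = 0) / sqrt(7 / 6)
}
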