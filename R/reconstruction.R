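#' Parameters of the iterative superresolution reconstruction
#'
#' Defaults follow the values that work well on 8-bit brain data: a 7x7x7
#' search volume, 3x3x3 patches, a decremental filtering-strength schedule
#' `h = 32, 16, 8, 4, 2`, balance factor `k = 256` between the reference
#' (sigma-filter) and self-similarity (patch) terms, and a stopping
#' tolerance of 0.01 on the mean absolute difference between consecutive
#' reconstructions. `h` and `tol` are quoted on the 8-bit (0–255) scale and
#' rescaled linearly to the data's native range at run time (see
#' [scale_h_schedule()]).
#'
#' @param search_radius search-window radius in voxels (default 3).
#' @param patch_radius patch radius in voxels (default 1).
#' @param h_schedule strictly decreasing positive filtering strengths on
#'   the 8-bit scale; each value drives one reconstruction + correction
#'   pass, after which iteration continues at the last value.
#' @param k balance factor: the patch (self-similarity) term uses bandwidth
#'   `k * h^2`, so larger `k` weakens the LR self-similarity constraint and
#'   lets the HR reference dominate.
#' @param tol convergence tolerance for the mean absolute difference
#'   between consecutive reconstructions, on the 8-bit scale.
#' @param max_iters safety cap on the total number of iterations.
#' @param init_method initial interpolation of the LR data onto the HR
#'   grid; the iteration converges to nearly the same solution from any of
#'   them, so the cheapest (`"nearest"`) is the default.
#' @export
sr_params <- function(search_radius = 3L, patch_radius = 1L,
                      h_schedule = c(32, 16, 8, 4, 2), k = 256,
                      tol = 0.01, max_iters = 50L,
                      init_method = c("nearest", "trilinear", "cubic", "bspline")) {
  init_method <- match.arg(init_method)
  search_radius <- as.integer(search_radius)
  patch_radius <- as.integer(patch_radius)
  if (patch_radius < 0L || search_radius < patch_radius) {
    stop("need search_radius >= patch_radius >= 0", call. = FALSE)
  }
  h_schedule <- as.numeric(h_schedule)
  if (length(h_schedule) < 1L || any(h_schedule <= 0) ||
      any(diff(h_schedule) >= 0)) {
    stop("h_schedule must be strictly decreasing and positive", call. = FALSE)
  }
  if (!is.finite(k) || k <= 0) stop("k must be > 0", call. = FALSE)
  if (!is.finite(tol) || tol <= 0) stop("tol must be > 0", call. = FALSE)
  max_iters <- as.integer(max_iters)
  if (max_iters < length(h_schedule)) {
    stop("max_iters must cover at least one pass per h value", call. = FALSE)
  }
  structure(list(search_radius = search_radius, patch_radius = patch_radius,
                 h_schedule = h_schedule, k = k, tol = tol,
                 max_iters = max_iters, init_method = init_method),
            class = "sr_params")
}

#' Rescale an 8-bit filtering-strength schedule to a native intensity range
#'
#' Filtering strengths are quoted for 8-bit (0–255) data; for other
#' quantisation levels they scale linearly with the intensity range:
#' `schedule * range_peak / 255`. At `range_peak = 255` the schedule is
#' returned unchanged; the default `32, 16, 8, 4, 2` corresponds to roughly
#' 12%, 6%, 3%, 1.5% and 0.7% of the range.
#'
#' @param schedule_8bit numeric schedule on the 8-bit scale.
#' @param range_peak positive intensity peak of the data.
#' @export
scale_h_schedule <- function(schedule_8bit, range_peak) {
  if (!is.finite(range_peak) || range_peak <= 0) {
    stop("range_peak must be > 0", call. = FALSE)
  }
  as.numeric(schedule_8bit) * (range_peak / 255)
}

#' One reference-guided reconstruction pass
#'
#' For every voxel p the output is a normalised weighted average of the
#' current reconstruction over the search window, with the weight of voxel
#' q combining a sigma filter on the HR reference z and a nonlocal-means
#' patch term on the reconstruction itself:
#' `w(p,q) = exp(-(z_p - z_q)^2 / h^2) * exp(-SSD(x;p,q) / (k h^2))`.
#' Voxels that look alike in the reference and share local context in the
#' LR data are averaged together; when one of the two images is
#' uninformative at p (constant reference, or a structure visible in only
#' one modality) its term is non-discriminating and the other drives the
#' reconstruction. All outputs are computed from the frozen input
#' (Jacobi-style), so the result is independent of traversal order, and
#' every output lies within the range of `x_t` over its search window.
#'
#' @param x_t current reconstruction, a [volume3d()] on the HR grid.
#' @param z HR reference volume on the same grid (denoised).
#' @param params an [sr_params()].
#' @param h filtering strength for this pass, in native intensity units.
#' @return the updated reconstruction.
#' @export
reconstruction_step <- function(x_t, z, params = sr_params(), h) {
  stop_if_not_volume(x_t, "x_t")
  stop_if_not_volume(z, "z")
  check_same_grid(x_t, z, "x_t and z")
  if (!is.finite(h) || h <= 0) stop("h must be > 0", call. = FALSE)
  out <- cpp_recon_step(as.vector(x_t$data), as.vector(z$data), dim(x_t$data),
                        params$search_radius, params$patch_radius,
                        h^2, params$k * h^2)
  dim(out) <- dim(x_t$data)
  vol_like(x_t, out)
}

#' Subsampling-consistency (mean) correction
#'
#' Enforces the acquisition constraint that downsampling the reconstruction
#' must reproduce the observed LR data exactly: the per-block offset
#' between the block means of `x` and the LR values `y` is replicated back
#' to the HR grid and subtracted,
#' `x - NN(DH x - y)`. After correction `boxcar_downsample(output)` equals
#' `y` to floating-point accuracy.
#'
#' @param x reconstruction on the HR grid, a [volume3d()].
#' @param y observed LR volume.
#' @param spec the [degradation_spec()] relating the two grids.
#' @return the corrected [volume3d()].
#' @export
mean_correction <- function(x, y, spec) {
  stop_if_not_volume(x, "x")
  stop_if_not_volume(y, "y")
  dhx <- boxcar_downsample(x, spec)
  check_same_grid(dhx, y, "downsampled x and y")
  resid <- vol_like(y, dhx$data - y$data)
  offset <- block_replicate_upsample(resid, spec, out_dim = dim(x$data))
  vol_like(x, x$data - offset$data)
}

#' Superresolve an LR volume guided by a coplanar HR reference
#'
#' The full iterative procedure. The LR input is first interpolated onto
#' the HR grid (`init_method`); then, for each filtering strength in the
#' decremental schedule, one [reconstruction_step()] followed by one
#' [mean_correction()] is applied — a coarse-to-fine progression in which
#' large `h` averages broadly and small `h` copies only closely similar
#' voxels. After the schedule is exhausted the two steps are repeated at
#' the final `h` until the mean absolute difference between consecutive
#' reconstructions falls below `tol`, or `max_iters` is reached. Both
#' inputs are assumed denoised and rigidly registered. The returned volume
#' satisfies the subsampling-consistency constraint by construction.
#'
#' `h_schedule` and `tol` are interpreted on the 8-bit scale and rescaled
#' by `z_hr$range_peak / 255` to the data's native intensity range.
#'
#' @param y_lr denoised LR [volume3d()].
#' @param z_hr denoised HR reference [volume3d()]; its grid must equal the
#'   LR grid multiplied by the decimation factors (up to `pad_edge`
#'   cropping).
#' @param spec the [degradation_spec()] relating the grids.
#' @param params an [sr_params()].
#' @param verbose log the MAD of every iteration via [message()].
#' @return a list with `volume` (the reconstruction) and `state`, a list
#'   recording `iteration`, `current_h`, `mad_history` and `h_history`
#'   (the `h` used at each iteration), plus `converged`.
#' @export
superresolve <- function(y_lr, z_hr, spec, params = sr_params(),
                         verbose = FALSE) {
  stop_if_not_volume(y_lr, "y_lr")
  stop_if_not_volume(z_hr, "z_hr")
  hr_dim <- dim(z_hr$data)
  expected_lr <- as.integer(ceiling(hr_dim / spec$factors))
  if (!identical(expected_lr, dim(y_lr$data))) {
    stop(sprintf("grid incompatibility: LR %s does not match HR %s at factors %s",
                 paste(dim(y_lr$data), collapse = "x"),
                 paste(hr_dim, collapse = "x"),
                 paste(spec$factors, collapse = "x")), call. = FALSE)
  }

  scale <- z_hr$range_peak / 255
  h_native <- params$h_schedule * scale
  tol_native <- params$tol * scale

  x <- interpolate_upsample(y_lr, spec, method = params$init_method,
                            out_dim = hr_dim)
  x <- vol_like(z_hr, x$data, spacing = x$spacing)

  n_sched <- length(h_native)
  h_last <- h_native[n_sched]
  mad_history <- numeric(0)
  h_history <- numeric(0)
  converged <- FALSE
  t <- 0L
  while (t < params$max_iters) {
    t <- t + 1L
    h <- if (t <= n_sched) h_native[t] else h_last
    x_new <- reconstruction_step(x, z_hr, params, h)
    x_new <- mean_correction(x_new, y_lr, spec)
    mad <- mean(abs(x_new$data - x$data))
    mad_history <- c(mad_history, mad)
    h_history <- c(h_history, h)
    if (verbose) {
      message(sprintf("iteration %d: h = %.4g, MAD = %.6g", t, h, mad))
    }
    x <- x_new
    # every scheduled h runs exactly once; convergence only ends the
    # terminal loop at the last h
    if (t >= n_sched && mad < tol_native) {
      converged <- TRUE
      break
    }
  }
  state <- list(iteration = t, current_h = h_history[t],
                mad_history = mad_history, h_history = h_history,
                tol_native = tol_native, converged = converged)
  list(volume = x, state = state)
}
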