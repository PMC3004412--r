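#' Interpolation baselines for upsampling an LR volume
#'
#' Upsamples onto the HR grid implied by the degradation factors using
#' standard separable interpolation. All methods share one geometric
#' convention, matched to the block-mean acquisition model: the centre of
#' LR voxel j coincides with the centre of its HR block, so HR voxel i
#' (0-based) samples the LR signal at position `(i - (L-1)/2) / L`.
#' `nearest` is therefore exactly block replication; `trilinear` is
#' separable linear interpolation; `cubic` uses the Keys cubic-convolution
#' kernel (a = -1/2); `bspline` is an interpolating natural cubic spline
#' per axis. Coordinates are clamped at the borders (edge replication).
#'
#' @param y LR [volume3d()].
#' @param spec a [degradation_spec()].
#' @param method one of `"nearest"`, `"trilinear"`, `"cubic"`, `"bspline"`.
#' @param out_dim optional HR shape to crop to (`pad_edge` bookkeeping).
#' @return a [volume3d()] on the HR grid.
#' @export
interpolate_upsample <- function(y, spec,
                                 method = c("nearest", "trilinear", "cubic", "bspline"),
                                 out_dim = NULL) {
  method <- match.arg(method)
  stop_if_not_volume(y, "y")
  f <- spec$factors
  if (method == "nearest") {
    return(block_replicate_upsample(y, spec, out_dim = out_dim))
  }
  a <- y$data
  full_dim <- dim(a) * f
  target <- if (is.null(out_dim)) full_dim else as.integer(out_dim)
  for (ax in 1:3) {
    a <- interp_axis(a, ax, f[ax], target[ax], method)
  }
  vol_like(y, a, spacing = y$spacing / f)
}

# Separable 1D interpolation along `axis` from m LR samples to n HR
# samples, as a precomputed n x m weight matrix applied to every line.
interp_axis <- function(a, axis, L, n, method) {
  m <- dim(a)[axis]
  if (L == 1L && n == m) return(a)
  # HR sample positions in 1-based LR index coordinates, block-centre
  # aligned, clamped to the sample range (edge replication)
  s <- ((seq_len(n) - 1) - (L - 1) / 2) / L + 1
  s <- pmin(pmax(s, 1), m)
  W <- interp_weights(s, m, method)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  d <- dim(ap)
  dim(ap) <- c(d[1], d[2] * d[3])
  out <- W %*% ap
  dim(out) <- c(n, d[2], d[3])
  aperm(out, order(perm))
}

interp_weights <- function(s, m, method) {
  n <- length(s)
  W <- matrix(0, n, m)
  if (method == "trilinear") {
    i0 <- pmin(floor(s), m - 1); if (m == 1) i0 <- rep(1, n)
    tfrac <- s - i0
    for (r in seq_len(n)) {
      if (m == 1) { W[r, 1] <- 1; next }
      W[r, i0[r]] <- W[r, i0[r]] + (1 - tfrac[r])
      W[r, i0[r] + 1] <- W[r, i0[r] + 1] + tfrac[r]
    }
  } else if (method == "cubic") {
    for (r in seq_len(n)) {
      i0 <- floor(s[r]); t <- s[r] - i0
      idx <- (i0 - 1):(i0 + 2)
      w <- keys_kernel(t - (-1:2))
      idx <- pmin(pmax(idx, 1), m)  # edge replication: fold weight inwards
      for (q in 1:4) W[r, idx[q]] <- W[r, idx[q]] + w[q]
    }
  } else if (method == "bspline") {
    # natural interpolating cubic spline is linear in the samples: build
    # the weight matrix column-by-column from unit impulses
    xs <- seq_len(m)
    for (j in seq_len(m)) {
      e <- numeric(m); e[j] <- 1
      W[, j] <- if (m < 4) stats::approx(xs, e, xout = s, rule = 2)$y
                else stats::splinefun(xs, e, method = "natural")(s)
    }
  } else {
    stop("unknown interpolation method: ", method, call. = FALSE)
  }
  W
}

# Keys cubic-convolution kernel, a = -1/2 (exact for quadratics)
keys_kernel <- function(x) {
  ax <- abs(x)
  w <- numeric(length(x))
  i1 <- ax <= 1
  w[i1] <- 1.5 * ax[i1]^3 - 2.5 * ax[i1]^2 + 1
  i2 <- ax > 1 & ax < 2
  w[i2] <- -0.5 * ax[i2]^3 + 2.5 * ax[i2]^2 - 4 * ax[i2] + 2
  w
}

#' Peak signal-to-noise ratio between two volumes
#'
#' `10 * log10(peak^2 / MSE)` in dB; an RMSE-derived measure normalised by
#' the intensity range so values are comparable across quantisation
#' levels. Identical volumes give `Inf`.
#'
#' @param reference ground-truth [volume3d()].
#' @param test volume under evaluation, same grid.
#' @param peak intensity peak; defaults to `reference$range_peak`.
#' @return PSNR in dB.
#' @examples
#' a <- volume3d(array(0, c(4, 4, 4)), range_peak = 255)
#' b <- volume3d(array(255, c(4, 4, 4)))
#' psnr(a, b)  # 0 dB: the error equals the peak everywhere
#' @export
psnr <- function(reference, test, peak = NULL) {
  stop_if_not_volume(reference, "reference")
  stop_if_not_volume(test, "test")
  check_same_grid(reference, test)
  if (is.null(peak)) peak <- reference$range_peak
  if (!is.finite(peak) || peak <= 0) stop("peak must be > 0", call. = FALSE)
  mse <- mean((reference$data - test$data)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' PSNR improvement of a method over a baseline
#'
#' `psnr(reference, proposed) - psnr(reference, baseline)` in dB; positive
#' values mean the proposed reconstruction is closer to the reference than
#' the baseline is.
#'
#' @inheritParams psnr
#' @param proposed,baseline volumes under comparison, same grid as
#'   `reference`.
#' @export
ipsnr <- function(reference, proposed, baseline, peak = NULL) {
  psnr(reference, proposed, peak) - psnr(reference, baseline, peak)
}

#' Translate a volume by per-axis offsets
#'
#' Used to emulate residual misregistration of the HR reference: the
#' volume content is shifted by `offsets` voxels along each axis, with
#' edge replication at exposed borders. `integer` mode shifts by whole
#' voxels; `trilinear` mode resamples and supports sub-voxel offsets.
#'
#' @param z a [volume3d()].
#' @param offsets numeric length-3, displacement in voxels (positive moves
#'   content towards higher indices).
#' @param mode `"integer"` or `"trilinear"`.
#' @return the shifted [volume3d()].
#' @export
shift_volume <- function(z, offsets, mode = c("integer", "trilinear")) {
  mode <- match.arg(mode)
  stop_if_not_volume(z, "z")
  offsets <- as.numeric(offsets)
  if (length(offsets) != 3L) stop("offsets must have length 3", call. = FALSE)
  d <- dim(z$data)
  if (any(abs(offsets) >= d)) {
    stop("offset magnitude must be smaller than the volume extent",
         call. = FALSE)
  }
  if (mode == "integer") {
    if (any(offsets != round(offsets))) {
      stop("integer mode requires whole-voxel offsets", call. = FALSE)
    }
    ix <- lapply(1:3, function(ax) {
      pmin(pmax(seq_len(d[ax]) - as.integer(offsets[ax]), 1L), d[ax])
    })
    out <- z$data[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  } else {
    out <- z$data
    for (ax in 1:3) {
      if (offsets[ax] == 0) next
      s <- pmin(pmax(seq_len(d[ax]) - offsets[ax], 1), d[ax])
      W <- interp_weights(s, d[ax], "trilinear")
      perm <- c(ax, setdiff(1:3, ax))
      ap <- aperm(out, perm)
      dd <- dim(ap)
      dim(ap) <- c(dd[1], dd[2] * dd[3])
      ap <- W %*% ap
      dim(ap) <- dd
      out <- aperm(ap, order(perm))
    }
  }
  vol_like(z, out)
}
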