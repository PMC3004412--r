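#' Degradation specification: decimation factors and boundary handling
#'
#' Describes the acquisition model `y = DHx + n` in its concrete form used
#' throughout the package: `H` is a 3D boxcar matched to the per-axis
#' decimation factors, so `DH` acts as non-overlapping block averaging —
#' each LR voxel is the arithmetic mean of its `Lx x Ly x Lz` HR block.
#'
#' @param factors integer length-3, per-axis decimation factors
#'   `(Lx, Ly, Lz)`, each >= 1.
#' @param boundary_mode `"strict"` (HR dimensions must be divisible by the
#'   factors, the default) or `"pad_edge"` (edge-replicate to the next
#'   multiple before averaging; upsampling then crops back).
#' @return an object of class `degradation_spec`.
#' @seealso [boxcar_downsample()], [block_replicate_upsample()]
#' @export
degradation_spec <- function(factors, boundary_mode = c("strict", "pad_edge")) {
  boundary_mode <- match.arg(boundary_mode)
  factors <- as.integer(factors)
  if (length(factors) == 1L) factors <- rep(factors, 3L)
  if (length(factors) != 3L || any(is.na(factors)) || any(factors < 1L)) {
    stop("degradation factors must be 3 integers >= 1", call. = FALSE)
  }
  structure(list(factors = factors, boundary_mode = boundary_mode),
            class = "degradation_spec")
}

#' @export
print.degradation_spec <- function(x, ...) {
  cat(sprintf("<degradation_spec> factors %s, boundary %s\n",
              paste(x$factors, collapse = "x"), x$boundary_mode))
  invisible(x)
}

check_divisible <- function(dims, factors) {
  rem <- dims %% factors
  if (any(rem != 0L)) {
    ax <- which(rem != 0L)[1]
    stop(sprintf(
      "dimension %d (axis %d) is not divisible by factor %d in strict mode",
      dims[ax], ax, factors[ax]), call. = FALSE)
  }
}

pad_edge_to_multiple <- function(a, factors) {
  d <- dim(a)
  target <- as.integer(ceiling(d / factors) * factors)
  if (all(target == d)) return(a)
  ix <- lapply(1:3, function(k) pmin(seq_len(target[k]), d[k]))
  a[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

# Mean over non-overlapping blocks of length L along one axis, for every
# line of the volume at once: fold the axis into (L, n/L) and average the
# first sub-axis.
block_mean_axis <- function(a, L, axis) {
  if (L == 1L) return(a)
  a <- aperm(a, c(axis, setdiff(1:3, axis)))
  d <- dim(a)
  dim(a) <- c(L, d[1] %/% L, d[2], d[3])
  a <- colMeans(a)                       # drops the first (length-L) axis
  aperm(a, order(c(axis, setdiff(1:3, axis))))
}

#' Downsample a volume through the boxcar acquisition model
#'
#' Applies the composed operator `DH`: each output voxel is the arithmetic
#' mean of its non-overlapping HR block, and output spacing is the input
#' spacing multiplied by the factors. This is the forward model a
#' superresolution reconstruction must remain consistent with.
#'
#' @param x a [volume3d()].
#' @param spec a [degradation_spec()].
#' @return a [volume3d()] on the LR grid (dimension `ceiling(dim/factor)`
#'   per axis).
#' @examples
#' x <- volume3d(array(0:7, c(2, 2, 2)))
#' boxcar_downsample(x, degradation_spec(c(2, 2, 2)))$data  # 3.5
#' @export
boxcar_downsample <- function(x, spec) {
  stop_if_not_volume(x, "x")
  a <- x$data
  f <- spec$factors
  if (spec$boundary_mode == "strict") {
    check_divisible(dim(a), f)
  } else {
    a <- pad_edge_to_multiple(a, f)
  }
  for (ax in 1:3) a <- block_mean_axis(a, f[ax], ax)
  vol_like(x, a, spacing = x$spacing * f)
}

#' Upsample a volume by block replication (nearest-neighbour on blocks)
#'
#' Each LR voxel value is replicated over its HR block; this is the `NN`
#' operator of the mean-correction step and also the `nearest` interpolation
#' baseline. It is an exact right inverse of [boxcar_downsample()]:
#' downsampling the result recovers the input.
#'
#' @param y a [volume3d()] on the LR grid.
#' @param spec a [degradation_spec()].
#' @param out_dim optional integer length-3: crop the replicated volume to
#'   this HR shape (used in `pad_edge` mode to undo edge padding).
#' @return a [volume3d()] on the HR grid.
#' @export
block_replicate_upsample <- function(y, spec, out_dim = NULL) {
  stop_if_not_volume(y, "y")
  f <- spec$factors
  a <- y$data
  d <- dim(a)
  a <- a[rep(seq_len(d[1]), each = f[1]),
         rep(seq_len(d[2]), each = f[2]),
         rep(seq_len(d[3]), each = f[3]), drop = FALSE]
  if (!is.null(out_dim)) {
    out_dim <- as.integer(out_dim)
    if (any(out_dim > dim(a))) {
      stop("out_dim exceeds the replicated volume's dimensions", call. = FALSE)
    }
    a <- a[seq_len(out_dim[1]), seq_len(out_dim[2]), seq_len(out_dim[3]),
           drop = FALSE]
  }
  vol_like(y, a, spacing = y$spacing / f)
}

#' Rician noise specification
#'
#' Magnitude-MR noise: independent Gaussian noise of standard deviation
#' `sigma` is added to the real and imaginary channels of a real-valued
#' signal and the complex modulus taken. `percent_of_max` expresses sigma
#' as a percentage of a volume's `range_peak` and is resolved against the
#' target volume when the noise is applied.
#'
#' @param sigma Gaussian channel standard deviation (intensity units);
#'   ignored when `percent_of_max` is given.
#' @param percent_of_max optional noise level as percent of the target
#'   volume's `range_peak`.
#' @param seed integer seed making the noise reproducible.
#' @export
rician_noise_spec <- function(sigma = 0, percent_of_max = NULL, seed = 1L) {
  if (!is.null(percent_of_max)) {
    if (percent_of_max < 0) stop("percent_of_max must be >= 0", call. = FALSE)
    sigma <- NA_real_  # resolved against range_peak at application time
  } else {
    sigma <- as.numeric(sigma)
    if (!is.finite(sigma) || sigma < 0) {
      stop("sigma must be a finite value >= 0", call. = FALSE)
    }
  }
  structure(list(sigma = sigma, percent_of_max = percent_of_max,
                 seed = as.integer(seed)),
            class = "rician_noise_spec")
}

resolve_sigma <- function(noise, v) {
  if (!is.null(noise$percent_of_max)) {
    noise$percent_of_max / 100 * v$range_peak
  } else {
    noise$sigma
  }
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so simulation code does not perturb it.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Add Rician noise to a volume
#'
#' Simulates magnitude-MR noise: the input is treated as a complex signal
#' with zero imaginary part, Gaussian noise of standard deviation `sigma`
#' is added to both channels (real channel drawn first), and the modulus is
#' returned. With `sigma = 0` the output is `|x|`.
#'
#' @param x a [volume3d()] (assumed non-negative real).
#' @param noise a [rician_noise_spec()].
#' @return a noisy [volume3d()] on the same grid.
#' @examples
#' v <- volume3d(array(100, c(4, 4, 4)))
#' n <- add_rician_noise(v, rician_noise_spec(sigma = 2, seed = 7))
#' @export
add_rician_noise <- function(x, noise) {
  stop_if_not_volume(x, "x")
  sigma <- resolve_sigma(noise, x)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(vol_like(x, abs(x$data)))
  n <- length(x$data)
  a <- with_seed(noise$seed, {
    g1 <- stats::rnorm(n, 0, sigma)
    g2 <- stats::rnorm(n, 0, sigma)
    sqrt((as.vector(x$data) + g1)^2 + g2^2)
  })
  dim(a) <- dim(x$data)
  vol_like(x, a)
}
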