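#' 3D scalar volume with voxel-spacing metadata
#'
#' `volume3d` is the universal currency of the package: a 3D array of
#' finite real intensities together with per-axis voxel size in mm and a
#' nominal intensity peak. The peak (`range_peak`) is the value used to
#' rescale filtering strengths quoted on the 8-bit scale and as the default
#' `peak` of [psnr()]; by convention it defaults to the maximum intensity of
#' the data.
#'
#' @param data numeric 3D array (a plain vector or matrix is promoted to a
#'   3D array with trailing singleton dimensions).
#' @param spacing numeric length-3, voxel size in mm along each axis.
#' @param range_peak positive scalar; defaults to `max(data)` (or 1 when the
#'   maximum is not positive, so a degenerate all-zero volume still carries
#'   a usable peak).
#' @return an object of class `volume3d` with fields `data`, `spacing`,
#'   `range_peak`.
#' @examples
#' v <- volume3d(array(runif(8), c(2, 2, 2)), spacing = c(1, 1, 3))
#' dim(v)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), range_peak = NULL) {
  data <- as_array3d(data)
  if (!all(is.finite(data))) {
    stop("volume3d: intensities must be finite (no NaN/Inf)", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("volume3d: spacing must be 3 positive finite values", call. = FALSE)
  }
  if (is.null(range_peak)) {
    mx <- max(data)
    range_peak <- if (mx > 0) mx else 1
  }
  range_peak <- as.numeric(range_peak)
  if (length(range_peak) != 1L || !is.finite(range_peak) || range_peak <= 0) {
    stop("volume3d: range_peak must be a positive finite scalar", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, range_peak = range_peak),
    class = "volume3d"
  )
}

as_array3d <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) {
    stop("expected a 3D array, got ", length(dim(x)), " dimensions",
         call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %s mm, range [%g, %g], peak %g\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$data), max(x$data), x$range_peak))
  invisible(x)
}

is_volume3d <- function(x) inherits(x, "volume3d")

#' Replace the data of a volume, keeping its metadata
#'
#' Internal convenience: returns a copy of `v` with new intensities and
#' (optionally) new spacing; `range_peak` is carried over unchanged so that
#' derived volumes keep the scale of their source.
#' @noRd
vol_like <- function(v, data, spacing = v$spacing) {
  volume3d(data, spacing = spacing, range_peak = v$range_peak)
}

stop_if_not_volume <- function(x, arg) {
  if (!is_volume3d(x)) {
    stop(sprintf("`%s` must be a volume3d object", arg), call. = FALSE)
  }
  invisible(x)
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data))) {
    stop(sprintf("%s must share one grid: %s vs %s", what,
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}
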