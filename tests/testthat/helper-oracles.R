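# Naive reference implementations of the patch filters, written as direct
# transcriptions of their definitions (explicit loops, per-voxel mirror
# indexing). They exist to cross-check the optimized compiled kernels and
# are deliberately kept independent of the package internals.

mirror_idx <- function(i, n) {
  ifelse(i < 1L, 1L - i, ifelse(i > n, 2L * n + 1L - i, i))
}

get_patch <- function(arr, i, j, k, pr) {
  d <- dim(arr)
  arr[mirror_idx(i + (-pr:pr), d[1]),
      mirror_idx(j + (-pr:pr), d[2]),
      mirror_idx(k + (-pr:pr), d[3])]
}

# Plain patch-weighted NLM average of `values` with similarities on `arr`.
naive_patch_nlm <- function(arr, values, sr, pr, h2) {
  d <- dim(arr)
  out <- array(0, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    pp <- get_patch(arr, i, j, k, pr)
    num <- 0; den <- 0
    for (qk in max(1, k - sr):min(d[3], k + sr))
      for (qj in max(1, j - sr):min(d[2], j + sr))
        for (qi in max(1, i - sr):min(d[1], i + sr)) {
          ssd <- sum((pp - get_patch(arr, qi, qj, qk, pr))^2)
          w <- exp(-ssd / h2)
          num <- num + w * values[qi, qj, qk]
          den <- den + w
        }
    out[i, j, k] <- num / den
  }
  out
}

# Reference-guided reconstruction pass: sigma-filter term on z times
# patch-NLM term on x, single normalisation over the product weights.
naive_recon_step <- function(x, z, sr, pr, h2, kh2) {
  d <- dim(x)
  out <- array(0, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    pp <- get_patch(x, i, j, k, pr)
    zp <- z[i, j, k]
    num <- 0; den <- 0
    for (qk in max(1, k - sr):min(d[3], k + sr))
      for (qj in max(1, j - sr):min(d[2], j + sr))
        for (qi in max(1, i - sr):min(d[1], i + sr)) {
          ssd <- sum((pp - get_patch(x, qi, qj, qk, pr))^2)
          w <- exp(-(zp - z[qi, qj, qk])^2 / h2) * exp(-ssd / kh2)
          num <- num + w * x[qi, qj, qk]
          den <- den + w
        }
    out[i, j, k] <- num / den
  }
  out
}

random_volume <- function(dims, seed, lo = 0, hi = 255, peak = 255) {
  set.seed(seed)
  volume3d(array(runif(prod(dims), lo, hi), dims), range_peak = peak)
}

vol_like_test <- function(v, data) {
  volume3d(data, spacing = v$spacing, range_peak = v$range_peak)
}
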