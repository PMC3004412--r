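// Patch-similarity neighbourhood filters shared by the denoiser and the
// reference-guided reconstruction step.
//
// Conventions (shared with the R-level naive oracles in the test suite):
//   - search window: (2*sr+1)^3 cube clipped at the volume borders, the
//     centre voxel included;
//   - patches: (2*pr+1)^3 cubes read from a mirror-padded copy of the
//     volume (half-sample reflection: index -1 maps to 0, n to n-1);
//   - patch distance: raw sum of squared differences over all patch
//     voxels, no normalisation by patch size;
//   - sequential Jacobi-style update: every output voxel is computed from
//     the frozen input volume.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

inline int mirror_index(int i, int n) {
  // half-sample symmetric reflection; valid for |overhang| < n
  if (i < 0) return -i - 1;
  if (i >= n) return 2 * n - i - 1;
  return i;
}

// Copy vol (dims nx,ny,nz) into a buffer padded by pr on every side using
// mirror reflection.
std::vector<double> mirror_pad(const NumericVector &vol,
                               int nx, int ny, int nz, int pr) {
  const int px = nx + 2 * pr, py = ny + 2 * pr, pz = nz + 2 * pr;
  std::vector<double> out((size_t)px * py * pz);
  for (int k = 0; k < pz; ++k) {
    const int sk = mirror_index(k - pr, nz);
    for (int j = 0; j < py; ++j) {
      const int sj = mirror_index(j - pr, ny);
      const double *src = &vol[(size_t)nx * (sj + (size_t)ny * sk)];
      double *dst = &out[(size_t)px * (j + (size_t)py * k)];
      for (int i = 0; i < px; ++i) dst[i] = src[mirror_index(i - pr, nx)];
    }
  }
  return out;
}

// Linear offsets (in the padded layout) of the (2*pr+1)^3 patch voxels.
std::vector<long long> patch_offsets(int px, int py, int pr) {
  std::vector<long long> off;
  off.reserve((2 * pr + 1) * (2 * pr + 1) * (2 * pr + 1));
  for (int dk = -pr; dk <= pr; ++dk)
    for (int dj = -pr; dj <= pr; ++dj)
      for (int di = -pr; di <= pr; ++di)
        off.push_back((long long)di + (long long)px * (dj + (long long)py * dk));
  return off;
}

} // namespace

// Weighted neighbourhood average with nonlocal-means patch weights.
// Similarities are computed on `sim`; the quantity averaged is `values`
// (so the Rician denoiser can average squared intensities while weighting
// on the intensities themselves). w(p,q) = exp(-SSD_patch(sim;p,q)/h2).
// [[Rcpp::export]]
NumericVector cpp_patch_nlm(NumericVector sim, NumericVector values,
                            IntegerVector dims, int search_radius,
                            int patch_radius, double h2) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int sr = search_radius, pr = patch_radius;
  const int px = nx + 2 * pr, py = ny + 2 * pr;
  std::vector<double> pad = mirror_pad(sim, nx, ny, nz, pr);
  std::vector<long long> off = patch_offsets(px, py, pr);
  const int npatch = (int)off.size();
  NumericVector out(sim.size());

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const long long pp =
            (long long)(i + pr) + (long long)px * ((j + pr) + (long long)py * (k + pr));
        double num = 0.0, den = 0.0;
        const int k0 = std::max(0, k - sr), k1 = std::min(nz - 1, k + sr);
        const int j0 = std::max(0, j - sr), j1 = std::min(ny - 1, j + sr);
        const int i0 = std::max(0, i - sr), i1 = std::min(nx - 1, i + sr);
        for (int qk = k0; qk <= k1; ++qk) {
          for (int qj = j0; qj <= j1; ++qj) {
            for (int qi = i0; qi <= i1; ++qi) {
              const long long qq =
                  (long long)(qi + pr) + (long long)px * ((qj + pr) + (long long)py * (qk + pr));
              double ssd = 0.0;
              for (int m = 0; m < npatch; ++m) {
                const double d = pad[pp + off[m]] - pad[qq + off[m]];
                ssd += d * d;
              }
              const double w = std::exp(-ssd / h2);
              num += w * values[qi + (size_t)nx * (qj + (size_t)ny * qk)];
              den += w;
            }
          }
        }
        out[i + (size_t)nx * (j + (size_t)ny * k)] = num / den;
      }
    }
  }
  return out;
}

// One reconstruction pass: output(p) = sum_q x(q) * w(p,q) / C_p with
//   w(p,q) = exp(-((z_p - z_q)^2 / h2 + SSD_patch(x;p,q) / kh2)).
// The two exponentials are fused into one exp call; the intensity term
// uses the HR reference z, the patch term the current reconstruction x.
// [[Rcpp::export]]
NumericVector cpp_recon_step(NumericVector x, NumericVector z,
                             IntegerVector dims, int search_radius,
                             int patch_radius, double h2, double kh2) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int sr = search_radius, pr = patch_radius;
  const int px = nx + 2 * pr, py = ny + 2 * pr;
  std::vector<double> pad = mirror_pad(x, nx, ny, nz, pr);
  std::vector<long long> off = patch_offsets(px, py, pr);
  const int npatch = (int)off.size();
  NumericVector out(x.size());

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const size_t pidx = i + (size_t)nx * (j + (size_t)ny * k);
        const long long pp =
            (long long)(i + pr) + (long long)px * ((j + pr) + (long long)py * (k + pr));
        const double zp = z[pidx];
        double num = 0.0, den = 0.0;
        const int k0 = std::max(0, k - sr), k1 = std::min(nz - 1, k + sr);
        const int j0 = std::max(0, j - sr), j1 = std::min(ny - 1, j + sr);
        const int i0 = std::max(0, i - sr), i1 = std::min(nx - 1, i + sr);
        for (int qk = k0; qk <= k1; ++qk) {
          for (int qj = j0; qj <= j1; ++qj) {
            for (int qi = i0; qi <= i1; ++qi) {
              const size_t qidx = qi + (size_t)nx * (qj + (size_t)ny * qk);
              const long long qq =
                  (long long)(qi + pr) + (long long)px * ((qj + pr) + (long long)py * (qk + pr));
              double ssd = 0.0;
              for (int m = 0; m < npatch; ++m) {
                const double d = pad[pp + off[m]] - pad[qq + off[m]];
                ssd += d * d;
              }
              const double dz = zp - z[qidx];
              const double w = std::exp(-(dz * dz / h2 + ssd / kh2));
              num += w * x[qidx];
              den += w;
            }
          }
        }
        out[pidx] = num / den;
      }
    }
  }
  return out;
}
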