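#include <Rcpp.h>
using namespace Rcpp;

// One self-similarity weighting pass over a 3D volume.
//
// For every in-mask voxel (i,j,k) the update is the weight-normalised average
// of its kernel neighbourhood, with
//   -ln w = h^2 * ( SSD(patch_i, patch_x) / (n_patch * k_dwi)
//                 + (ref[x] - ref[i])^2 / k_ref )
// Patches are truncated at the volume boundary; the SSD is normalised by the
// number of voxel pairs actually compared so edge voxels are not penalised.
// Out-of-mask voxels pass through untouched.  If every weight underflows the
// centre value is kept (the centre weight is 1 by construction, so this only
// guards pathological inputs).
// [[Rcpp::export(name = ".sr_iteration_cpp")]]
NumericVector sr_iteration_cpp(NumericVector dwi, NumericVector ref,
                               LogicalVector mask, IntegerVector dim,
                               double h, int kernel, int patch,
                               double k_dwi, double k_ref) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kr = kernel / 2, pr = patch / 2;
  const double h2 = h * h;
  NumericVector out = clone(dwi);

  auto idx = [&](int x, int y, int z) { return x + nx * (y + ny * z); };

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int c = idx(i, j, k);
        if (!mask[c]) continue;
        double wsum = 0.0, vsum = 0.0;
        const double refc = ref[c];
        for (int dz = -kr; dz <= kr; ++dz) {
          const int z = k + dz; if (z < 0 || z >= nz) continue;
          for (int dy = -kr; dy <= kr; ++dy) {
            const int y = j + dy; if (y < 0 || y >= ny) continue;
            for (int dx = -kr; dx <= kr; ++dx) {
              const int x = i + dx; if (x < 0 || x >= nx) continue;
              // patch SSD with identical offsets around both centres
              double ssd = 0.0; int npair = 0;
              for (int pz = -pr; pz <= pr; ++pz) {
                const int zc = k + pz, zn = z + pz;
                if (zc < 0 || zc >= nz || zn < 0 || zn >= nz) continue;
                for (int py = -pr; py <= pr; ++py) {
                  const int yc = j + py, yn = y + py;
                  if (yc < 0 || yc >= ny || yn < 0 || yn >= ny) continue;
                  for (int px = -pr; px <= pr; ++px) {
                    const int xc = i + px, xn = x + px;
                    if (xc < 0 || xc >= nx || xn < 0 || xn >= nx) continue;
                    const double d = dwi[idx(xc, yc, zc)] - dwi[idx(xn, yn, zn)];
                    ssd += d * d;
                    ++npair;
                  }
                }
              }
              const double dref = ref[idx(x, y, z)] - refc;
              const double mlnw = h2 * (ssd / (npair * k_dwi) +
                                        dref * dref / k_ref);
              const double w = std::exp(-mlnw);
              wsum += w;
              vsum += w * dwi[idx(x, y, z)];
            }
          }
        }
        out[c] = (wsum > 0.0) ? vsum / wsum : dwi[c];
      }
  out.attr("dim") = dim;
  return out;
}
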