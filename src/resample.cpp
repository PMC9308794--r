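#include <Rcpp.h>
using namespace Rcpp;

// Rigid resampling of a 3D volume by inverse mapping.
//
// The forward transform moves the object: x' = R (x - c) + c + t, with x in
// world mm (voxel centres at (i - 0.5) * spacing, i 1-based), c the grid
// centre and t a translation in mm. Each output voxel centre is pulled back
// through the inverse transform and the input is interpolated there.
//
// rot: 3x3 rotation matrix (row-major irrelevant: passed as R matrix,
//      column-major). order: 0 = nearest neighbour, 1 = trilinear.
// fill: value used outside the input grid.
// [[Rcpp::export]]
NumericVector resample_rigid_cpp(NumericVector vol, IntegerVector dim,
                                 NumericVector spacing, NumericMatrix rot,
                                 NumericVector trans, int order, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double cx = nx * sx / 2.0, cy = ny * sy / 2.0, cz = nz * sz / 2.0;
  // inverse rotation = transpose
  const double r11 = rot(0, 0), r12 = rot(1, 0), r13 = rot(2, 0);
  const double r21 = rot(0, 1), r22 = rot(1, 1), r23 = rot(2, 1);
  const double r31 = rot(0, 2), r32 = rot(1, 2), r33 = rot(2, 2);
  const double tx = trans[0], ty = trans[1], tz = trans[2];

  NumericVector out(vol.size());
  const double *v = vol.begin();
  double *o = out.begin();
  const R_xlen_t sxy = (R_xlen_t)nx * ny;

  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double wz = (k + 0.5) * sz;
    for (int j = 0; j < ny; ++j) {
      const double wy = (j + 0.5) * sy;
      for (int i = 0; i < nx; ++i, ++idx) {
        const double wx = (i + 0.5) * sx;
        // pull back: x_src = R^T (x_dst - c - t) + c
        const double dx = wx - cx - tx, dy = wy - cy - ty, dz = wz - cz - tz;
        const double xs = r11 * dx + r12 * dy + r13 * dz + cx;
        const double ys = r21 * dx + r22 * dy + r23 * dz + cy;
        const double zs = r31 * dx + r32 * dy + r33 * dz + cz;
        // continuous voxel coordinates (0-based voxel centre frame)
        const double fi = xs / sx - 0.5, fj = ys / sy - 0.5, fk = zs / sz - 0.5;
        if (order == 0) {
          const int ii = (int)std::lround(fi), jj = (int)std::lround(fj),
                    kk = (int)std::lround(fk);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            o[idx] = fill;
          else
            o[idx] = v[ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * sxy];
        } else {
          const int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj),
                    k0 = (int)std::floor(fk);
          const double ai = fi - i0, aj = fj - j0, ak = fk - k0;
          double acc = 0.0;
          bool inside = true;
          for (int dk = 0; dk <= 1 && inside; ++dk)
            for (int dj = 0; dj <= 1 && inside; ++dj)
              for (int di = 0; di <= 1 && inside; ++di) {
                const int ii = i0 + di, jj = j0 + dj, kk = k0 + dk;
                const double w = (di ? ai : 1 - ai) * (dj ? aj : 1 - aj) *
                                 (dk ? ak : 1 - ak);
                if (w == 0.0) continue;
                if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                    kk >= nz) {
                  inside = false;
                } else {
                  acc += w * v[ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * sxy];
                }
              }
          o[idx] = inside ? acc : fill;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
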