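#include <Rcpp.h>
using namespace Rcpp;

// Radiological depth by upstream ray marching through a homogeneous
// (unit-density) body mask. Rays are parallel to `dir` (no divergence).
// `vox` holds 1-based linear indices (column-major, dims order x,y,z) of
// the voxels to evaluate; depth is the path length (mm) inside the body
// from the body entry point to the voxel center, sampled every `step` mm.
// [[Rcpp::export]]
NumericVector ray_depth_cpp(LogicalVector body, IntegerVector dims,
                            NumericVector spacing, NumericVector origin,
                            NumericVector dir, IntegerVector vox,
                            double step) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ex = ox + nx * sx, ey = oy + ny * sy, ez = oz + nz * sz;
  // max path length: grid diagonal
  const double dmax = std::sqrt((ex - ox) * (ex - ox) + (ey - oy) * (ey - oy) +
                                (ez - oz) * (ez - oz));
  const int n = vox.size();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    int lin = vox[q] - 1;
    int ix = lin % nx;
    int iy = (lin / nx) % ny;
    int iz = lin / (nx * ny);
    double px = ox + (ix + 0.5) * sx;
    double py = oy + (iy + 0.5) * sy;
    double pz = oz + (iz + 0.5) * sz;
    double depth = 0.0;
    // sample phase 1/pi: keeps samples off voxel faces even when the
    // direction cosines are rational (e.g. gantry multiples of 60 deg)
    for (double s = 0.3183098861837907 * step; s < dmax; s += step) {
      double qx = px - dir[0] * s;
      double qy = py - dir[1] * s;
      double qz = pz - dir[2] * s;
      if (qx < ox || qx >= ex || qy < oy || qy >= ey || qz < oz || qz >= ez)
        break;
      int jx = (int)((qx - ox) / sx);
      int jy = (int)((qy - oy) / sy);
      int jz = (int)((qz - oz) / sz);
      if (body[jx + nx * (jy + (long long)ny * jz)]) depth += step;
    }
    out[q] = depth;
  }
  return out;
}

// dose <- dose + sum_k D[, cols[k]] * vals[k] for a CSC matrix given by
// slots (p, i 0-based, x). cols are 1-based column indices. Returns a new
// vector; the input is not modified.
// [[Rcpp::export]]
NumericVector csc_axpy_cpp(IntegerVector p, IntegerVector i, NumericVector x,
                           IntegerVector cols, NumericVector vals,
                           NumericVector dose) {
  NumericVector out = clone(dose);
  const int k = cols.size();
  for (int c = 0; c < k; ++c) {
    double v = vals[c];
    if (v == 0.0) continue;
    int col = cols[c] - 1;
    for (int j = p[col]; j < p[col + 1]; ++j) out[i[j]] += x[j] * v;
  }
  return out;
}
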