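#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Resample `vals` (moving grid) onto the reference grid under a rigid
// transform mapping moving-space world points to reference-space world
// points: p_ref = R (q - c) + c + t. Each reference voxel center is pulled
// back through the inverse (R^T) and interpolated in the moving grid.
// `rot` is the 3x3 rotation in column-major order, `cen` the rotation center
// in world mm, `tra` the translation in mm.
// [[Rcpp::export]]
NumericVector cpp_resample_rigid(NumericVector vals, IntegerVector dimM,
                                 NumericVector spacingM, NumericVector originM,
                                 IntegerVector dimR, NumericVector spacingR,
                                 NumericVector originR, NumericVector rot,
                                 NumericVector tra, NumericVector cen,
                                 bool nearest, double fill) {
  const int m1 = dimM[0], m2 = dimM[1], m3 = dimM[2];
  const int r1 = dimR[0], r2 = dimR[1], r3 = dimR[2];
  NumericVector out((size_t)r1 * r2 * r3);
  // columns of R
  const double R11 = rot[0], R21 = rot[1], R31 = rot[2];
  const double R12 = rot[3], R22 = rot[4], R32 = rot[5];
  const double R13 = rot[6], R23 = rot[7], R33 = rot[8];
  size_t o = 0;
  for (int k = 0; k < r3; ++k) {
    const double pz = originR[2] + k * spacingR[2];
    for (int j = 0; j < r2; ++j) {
      const double py = originR[1] + j * spacingR[1];
      for (int i = 0; i < r1; ++i, ++o) {
        const double px = originR[0] + i * spacingR[0];
        // q = R^T (p - c - t) + c
        const double dx = px - cen[0] - tra[0];
        const double dy = py - cen[1] - tra[1];
        const double dz = pz - cen[2] - tra[2];
        const double qx = R11 * dx + R21 * dy + R31 * dz + cen[0];
        const double qy = R12 * dx + R22 * dy + R32 * dz + cen[1];
        const double qz = R13 * dx + R23 * dy + R33 * dz + cen[2];
        // continuous voxel index in moving grid
        const double fx = (qx - originM[0]) / spacingM[0];
        const double fy = (qy - originM[1]) / spacingM[1];
        const double fz = (qz - originM[2]) / spacingM[2];
        if (nearest) {
          const int ix = (int)std::lround(fx);
          const int iy = (int)std::lround(fy);
          const int iz = (int)std::lround(fz);
          if (ix < 0 || iy < 0 || iz < 0 || ix >= m1 || iy >= m2 || iz >= m3) {
            out[o] = fill;
          } else {
            out[o] = vals[(size_t)iz * m1 * m2 + (size_t)iy * m1 + ix];
          }
        } else {
          const int x0 = (int)std::floor(fx);
          const int y0 = (int)std::floor(fy);
          const int z0 = (int)std::floor(fz);
          if (x0 < 0 || y0 < 0 || z0 < 0 || x0 >= m1 - 1 || y0 >= m2 - 1 ||
              z0 >= m3 - 1) {
            // allow exact upper boundary
            if (fx >= 0 && fy >= 0 && fz >= 0 && fx <= m1 - 1 && fy <= m2 - 1 &&
                fz <= m3 - 1) {
              const int ix = (int)std::lround(fx);
              const int iy = (int)std::lround(fy);
              const int iz = (int)std::lround(fz);
              out[o] = vals[(size_t)iz * m1 * m2 + (size_t)iy * m1 + ix];
            } else {
              out[o] = fill;
            }
            continue;
          }
          const double ax = fx - x0, ay = fy - y0, az = fz - z0;
          const size_t b000 = (size_t)z0 * m1 * m2 + (size_t)y0 * m1 + x0;
          const size_t b100 = b000 + 1;
          const size_t b010 = b000 + m1;
          const size_t b110 = b010 + 1;
          const size_t b001 = b000 + (size_t)m1 * m2;
          const size_t b101 = b001 + 1;
          const size_t b011 = b001 + m1;
          const size_t b111 = b011 + 1;
          const double c00 = vals[b000] * (1 - ax) + vals[b100] * ax;
          const double c10 = vals[b010] * (1 - ax) + vals[b110] * ax;
          const double c01 = vals[b001] * (1 - ax) + vals[b101] * ax;
          const double c11 = vals[b011] * (1 - ax) + vals[b111] * ax;
          const double c0 = c00 * (1 - ay) + c10 * ay;
          const double c1 = c01 * (1 - ay) + c11 * ay;
          out[o] = c0 * (1 - az) + c1 * az;
        }
      }
    }
  }
  return out;
}

// Separable Gaussian blur with per-axis sigma in voxel units; kernel
// truncated at 4 sigma, replicate boundary handling. sigma <= 0 skips the
// axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector vals, IntegerVector dim,
                             NumericVector sigma) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const size_t n = (size_t)n1 * n2 * n3;
  std::vector<double> cur(vals.begin(), vals.end()), tmp(n);
  const int dims[3] = {n1, n2, n3};
  const size_t strides[3] = {1, (size_t)n1, (size_t)n1 * n2};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int rad = std::max(1, (int)std::ceil(4.0 * s));
    std::vector<double> ker(2 * rad + 1);
    double sum = 0;
    for (int t = -rad; t <= rad; ++t) {
      ker[t + rad] = std::exp(-0.5 * (double)t * t / (s * s));
      sum += ker[t + rad];
    }
    for (double &w : ker) w /= sum;
    const int na = dims[ax];
    const size_t sa = strides[ax];
    // iterate over all lines along axis ax
    const int nb = dims[(ax + 1) % 3], nc = dims[(ax + 2) % 3];
    const size_t sb = strides[(ax + 1) % 3], sc = strides[(ax + 2) % 3];
    for (int c = 0; c < nc; ++c)
      for (int b = 0; b < nb; ++b) {
        const size_t base = (size_t)c * sc + (size_t)b * sb;
        for (int a = 0; a < na; ++a) {
          double acc = 0;
          for (int t = -rad; t <= rad; ++t) {
            int u = a + t;
            if (u < 0) u = 0;
            if (u >= na) u = na - 1;
            acc += ker[t + rad] * cur[base + (size_t)u * sa];
          }
          tmp[base + (size_t)a * sa] = acc;
        }
      }
    std::swap(cur, tmp);
  }
  return NumericVector(cur.begin(), cur.end());
}

// Fused resample + mean-squared-difference: avoids materializing the
// resampled volume during registration, where this is the inner loop.
// The mean is taken over reference voxels that map inside the moving
// volume's field of view: anatomy crossing the field boundary otherwise
// contributes a large fill-vs-tissue mismatch that anchors the optimum
// at zero motion. Below 50% overlap a large smooth penalty takes over,
// growing with the overlap deficit, so shrinking the overlap never looks
// like an improvement and the optimizer is pushed back toward overlap.
// [[Rcpp::export]]
double cpp_msd_rigid(NumericVector valsM, IntegerVector dimM,
                     NumericVector spacingM, NumericVector originM,
                     NumericVector valsF, IntegerVector dimF,
                     NumericVector spacingF, NumericVector originF,
                     NumericVector rot, NumericVector tra, NumericVector cen,
                     double fill) {
  const int m1 = dimM[0], m2 = dimM[1], m3 = dimM[2];
  const int r1 = dimF[0], r2 = dimF[1], r3 = dimF[2];
  const double R11 = rot[0], R21 = rot[1], R31 = rot[2];
  const double R12 = rot[3], R22 = rot[4], R32 = rot[5];
  const double R13 = rot[6], R23 = rot[7], R33 = rot[8];
  double acc = 0;
  size_t nvalid = 0;
  size_t o = 0;
  for (int k = 0; k < r3; ++k) {
    const double pz = originF[2] + k * spacingF[2];
    for (int j = 0; j < r2; ++j) {
      const double py = originF[1] + j * spacingF[1];
      for (int i = 0; i < r1; ++i, ++o) {
        const double px = originF[0] + i * spacingF[0];
        const double dx = px - cen[0] - tra[0];
        const double dy = py - cen[1] - tra[1];
        const double dz = pz - cen[2] - tra[2];
        const double qx = R11 * dx + R21 * dy + R31 * dz + cen[0];
        const double qy = R12 * dx + R22 * dy + R32 * dz + cen[1];
        const double qz = R13 * dx + R23 * dy + R33 * dz + cen[2];
        const double fx = (qx - originM[0]) / spacingM[0];
        const double fy = (qy - originM[1]) / spacingM[1];
        const double fz = (qz - originM[2]) / spacingM[2];
        const int x0 = (int)std::floor(fx);
        const int y0 = (int)std::floor(fy);
        const int z0 = (int)std::floor(fz);
        if (x0 < 0 || y0 < 0 || z0 < 0 || x0 >= m1 - 1 || y0 >= m2 - 1 ||
            z0 >= m3 - 1)
          continue; // out of the moving field: no data, no contribution
        const double ax = fx - x0, ay = fy - y0, az = fz - z0;
        const size_t b000 = (size_t)z0 * m1 * m2 + (size_t)y0 * m1 + x0;
        const double c00 = valsM[b000] * (1 - ax) + valsM[b000 + 1] * ax;
        const double c10 =
            valsM[b000 + m1] * (1 - ax) + valsM[b000 + m1 + 1] * ax;
        const size_t b001 = b000 + (size_t)m1 * m2;
        const double c01 = valsM[b001] * (1 - ax) + valsM[b001 + 1] * ax;
        const double c11 =
            valsM[b001 + m1] * (1 - ax) + valsM[b001 + m1 + 1] * ax;
        const double c0 = c00 * (1 - ay) + c10 * ay;
        const double c1 = c01 * (1 - ay) + c11 * ay;
        const double v = c0 * (1 - az) + c1 * az;
        const double dlt = v - valsF[o];
        acc += dlt * dlt;
        ++nvalid;
      }
    }
  }
  (void)fill;
  const size_t ntot = (size_t)r1 * r2 * r3;
  const double frac = (double)nvalid / (double)ntot;
  if (frac < 0.5) return 1e9 * (1.0 + (0.5 - frac));
  return acc / (double)nvalid;
}
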