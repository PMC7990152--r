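#ifndef GRAFTQUANT_EDT_CORE_H
#define GRAFTQUANT_EDT_CORE_H

#include <cmath>
#include <limits>
#include <vector>

// 1D squared-distance transform (lower envelope of parabolas), Felzenszwalb
// & Huttenlocher; `w` is the sample spacing along the axis.
inline void gq_dt1d(const std::vector<double> &f, std::vector<double> &d,
                    int n, double w) {
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) {
      v[0] = q;
      continue;
    }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (q - v[k]) * w;
    d[q] = dq * dq + f[v[k]];
  }
}

// In-place 3-pass squared EDT over a column-major n1 x n2 x n3 grid.
inline void gq_edt_pass(std::vector<double> &g, int n1, int n2, int n3,
                        const double sp[3]) {
  std::vector<double> line, out;
  line.resize(n1);
  out.resize(n1);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      size_t base = (size_t)k * n1 * n2 + (size_t)j * n1;
      for (int i = 0; i < n1; ++i) line[i] = g[base + i];
      gq_dt1d(line, out, n1, sp[0]);
      for (int i = 0; i < n1; ++i) g[base + i] = out[i];
    }
  line.resize(n2);
  out.resize(n2);
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      size_t base = (size_t)k * n1 * n2 + i;
      for (int j = 0; j < n2; ++j) line[j] = g[base + (size_t)j * n1];
      gq_dt1d(line, out, n2, sp[1]);
      for (int j = 0; j < n2; ++j) g[base + (size_t)j * n1] = out[j];
    }
  line.resize(n3);
  out.resize(n3);
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      size_t base = (size_t)j * n1 + i;
      for (int k = 0; k < n3; ++k) line[k] = g[base + (size_t)k * n1 * n2];
      gq_dt1d(line, out, n3, sp[2]);
      for (int k = 0; k < n3; ++k) g[base + (size_t)k * n1 * n2] = out[k];
    }
}

// Signed distance in voxel units to the boundary of `inside`, negative
// inside, half-voxel offset so the zero level lies between voxels.
inline void gq_signed_distance(const std::vector<char> &inside,
                               std::vector<double> &phi, int n1, int n2,
                               int n3) {
  const double INF = std::numeric_limits<double>::infinity();
  size_t n = (size_t)n1 * n2 * n3;
  std::vector<double> din(n), dout(n);
  for (size_t i = 0; i < n; ++i) {
    dout[i] = inside[i] ? 0.0 : INF;
    din[i] = inside[i] ? INF : 0.0;
  }
  const double sp[3] = {1.0, 1.0, 1.0};
  gq_edt_pass(dout, n1, n2, n3, sp);
  gq_edt_pass(din, n1, n2, n3, sp);
  phi.resize(n);
  for (size_t i = 0; i < n; ++i) {
    if (inside[i])
      phi[i] = -(std::sqrt(din[i]) - 0.5);
    else
      phi[i] = std::sqrt(dout[i]) - 0.5;
  }
}

#endif
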