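#include <Rcpp.h>
#include "edt_core.h"
using namespace Rcpp;

// Exact squared Euclidean distance from every voxel to the nearest feature
// voxel, with anisotropic spacing. Feature voxels get 0; if no feature
// exists, Inf everywhere.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dim,
                         NumericVector spacing) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  size_t n = (size_t)n1 * n2 * n3;
  if ((size_t)feature.size() != n) stop("feature/dim mismatch");
  std::vector<double> g(n);
  const double INF = std::numeric_limits<double>::infinity();
  for (size_t i = 0; i < n; ++i) g[i] = feature[i] ? 0.0 : INF;
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  gq_edt_pass(g, n1, n2, n3, sp);
  return NumericVector(g.begin(), g.end());
}

// Signed distance in voxel units: negative inside the mask, positive
// outside, half-voxel offset so the zero level sits on the voxel-face
// boundary and |grad phi| is ~1 across the interface.
// [[Rcpp::export]]
NumericVector cpp_signed_distance(LogicalVector mask, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  size_t n = (size_t)n1 * n2 * n3;
  if ((size_t)mask.size() != n) stop("mask/dim mismatch");
  bool any_in = false, any_out = false;
  std::vector<char> inside(n);
  for (size_t i = 0; i < n; ++i) {
    inside[i] = mask[i] ? 1 : 0;
    if (mask[i])
      any_in = true;
    else
      any_out = true;
  }
  NumericVector out(n);
  const double INF = std::numeric_limits<double>::infinity();
  if (!any_in) {
    std::fill(out.begin(), out.end(), INF);
    return out;
  }
  if (!any_out) {
    std::fill(out.begin(), out.end(), -INF);
    return out;
  }
  std::vector<double> phi;
  gq_signed_distance(inside, phi, n1, n2, n3);
  std::copy(phi.begin(), phi.end(), out.begin());
  return out;
}
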