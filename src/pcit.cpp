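#include <Rcpp.h>
using namespace Rcpp;

// PCIT edge filter. For every trio (x, y, z) the three first-order partial
// correlations are computed, a trio tolerance eps is formed as the mean of
// the partial/direct ratios, and each pair of the trio is eliminated when its
// direct correlation is smaller in magnitude than eps times both correlations
// to the remaining (control) feature. An edge survives only if no trio
// eliminates it. Trios where any |r| is numerically 0 (ratio undefined) or
// >= 1 - 1e-12 (partial-correlation denominator underflow) are skipped; the
// number of skipped trios is returned in the "skipped" attribute.
//
// The R-level reference implementation (pcitReference) must stay in exact
// step with this loop: same skip rules, same expressions, same order.
// [[Rcpp::export(name = ".pcit_mask_cpp")]]
LogicalMatrix pcit_mask_cpp(NumericMatrix r) {
  const int n = r.nrow();
  LogicalMatrix keep(n, n);
  if (n != r.ncol()) stop("correlation matrix must be square");
  long long skipped = 0;
  if (n < 3) {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) keep(i, j) = (i != j);
    keep.attr("skipped") = 0.0;
    return keep;
  }
  std::vector<char> elim((size_t)n * n, 0);
  const double lo = 1e-12, hi = 1.0 - 1e-12;
  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      const double rxy = r(x, y);
      const double axy = std::fabs(rxy);
      for (int z = y + 1; z < n; ++z) {
        const double rxz = r(x, z), ryz = r(y, z);
        const double axz = std::fabs(rxz), ayz = std::fabs(ryz);
        if (axy < lo || axz < lo || ayz < lo ||
            axy > hi || axz > hi || ayz > hi) {
          ++skipped;
          continue;
        }
        const double rxy_z =
            (rxy - rxz * ryz) / std::sqrt((1.0 - rxz * rxz) * (1.0 - ryz * ryz));
        const double rxz_y =
            (rxz - rxy * ryz) / std::sqrt((1.0 - rxy * rxy) * (1.0 - ryz * ryz));
        const double ryz_x =
            (ryz - rxy * rxz) / std::sqrt((1.0 - rxy * rxy) * (1.0 - rxz * rxz));
        const double eps = (rxy_z / rxy + rxz_y / rxz + ryz_x / ryz) / 3.0;
        const double aeps = std::fabs(eps);
        if (axy < aeps * axz && axy < aeps * ayz) elim[(size_t)x * n + y] = 1;
        if (axz < aeps * axy && axz < aeps * ayz) elim[(size_t)x * n + z] = 1;
        if (ayz < aeps * axy && ayz < aeps * axz) elim[(size_t)y * n + z] = 1;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const bool k = !elim[(size_t)i * n + j];
      keep(i, j) = k;
      keep(j, i) = k;
    }
  }
  keep.attr("skipped") = (double)skipped;
  return keep;
}
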