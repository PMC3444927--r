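#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exhaustive trio scan for PCIT edge significance.
//
// For every trio {x, y, z} the three first-order partial correlations are
// computed; the trio tolerance eps is the mean of the |partial/direct|
// ratios (direct correlations below `tiny` in magnitude are skipped).  The
// pair (a, b) is discarded when, for at least one third gene c,
// |r_ab| <= eps * |r_ac| and |r_ab| <= eps * |r_bc|.  A pair whose partial
// is undefined (degenerate denominator) is not tested in that trio.
//
// Returns the keep-adjacency plus, for each discarded pair, the first
// explaining third gene (1-based, 0 = kept) and the tolerance that
// dismissed it.
// [[Rcpp::export]]
List pcit_scan_cpp(NumericMatrix r) {
  const int n = r.nrow();
  const double tiny = 1e-12;
  LogicalMatrix keep(n, n);
  IntegerMatrix witness(n, n);
  NumericMatrix tol(n, n);

  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      keep(i, j) = (i != j) && (r(i, j) != 0.0);

  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      const double rxy = r(x, y);
      for (int z = y + 1; z < n; ++z) {
        const double rxz = r(x, z);
        const double ryz = r(y, z);

        const double dxy = (1.0 - rxz * rxz) * (1.0 - ryz * ryz);
        const double dxz = (1.0 - rxy * rxy) * (1.0 - ryz * ryz);
        const double dyz = (1.0 - rxy * rxy) * (1.0 - rxz * rxz);
        const bool okxy = dxy > tiny, okxz = dxz > tiny, okyz = dyz > tiny;

        double s = 0.0;
        int m = 0;
        if (okxy && std::abs(rxy) >= tiny) {
          s += std::abs((rxy - rxz * ryz) / std::sqrt(dxy) / rxy); ++m;
        }
        if (okxz && std::abs(rxz) >= tiny) {
          s += std::abs((rxz - rxy * ryz) / std::sqrt(dxz) / rxz); ++m;
        }
        if (okyz && std::abs(ryz) >= tiny) {
          s += std::abs((ryz - rxy * rxz) / std::sqrt(dyz) / ryz); ++m;
        }
        if (m == 0) continue;
        const double eps = s / m;

        if (okxy && keep(x, y) &&
            std::abs(rxy) <= eps * std::abs(rxz) &&
            std::abs(rxy) <= eps * std::abs(ryz)) {
          keep(x, y) = keep(y, x) = false;
          witness(x, y) = witness(y, x) = z + 1;
          tol(x, y) = tol(y, x) = eps;
        }
        if (okxz && keep(x, z) &&
            std::abs(rxz) <= eps * std::abs(rxy) &&
            std::abs(rxz) <= eps * std::abs(ryz)) {
          keep(x, z) = keep(z, x) = false;
          witness(x, z) = witness(z, x) = y + 1;
          tol(x, z) = tol(z, x) = eps;
        }
        if (okyz && keep(y, z) &&
            std::abs(ryz) <= eps * std::abs(rxy) &&
            std::abs(ryz) <= eps * std::abs(rxz)) {
          keep(y, z) = keep(z, y) = false;
          witness(y, z) = witness(z, y) = x + 1;
          tol(y, z) = tol(z, y) = eps;
        }
      }
    }
  }
  return List::create(_["keep"] = keep,
                      _["witness"] = witness,
                      _["tolerance"] = tol);
}
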