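#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// PCIT edge elimination over all unordered trios.
//
// For a trio (x, y, z) the three first-order partial correlations are
// computed; the trio tolerance is the mean of the ratios partial/direct,
// with a ratio contributing 0 when |direct| < guard. An edge (x, y) is
// eliminated when, for at least one third variable z,
//   |r_xy| < |eps * r_xz|  AND  |r_xy| < |eps * r_yz|.
// A trio whose partial-correlation denominator falls below the guard is
// degenerate and provides no elimination evidence. Pairs flagged invalid
// (insufficient overlap) never participate in trios and are never kept.
//
// [[Rcpp::export]]
LogicalMatrix pcit_keep_cpp(NumericMatrix r, LogicalMatrix valid, double guard) {
    const int n = r.nrow();
    LogicalMatrix elim(n, n);

    for (int x = 0; x < n - 2; ++x) {
        for (int y = x + 1; y < n - 1; ++y) {
            for (int z = y + 1; z < n; ++z) {
                if (!valid(x, y) || !valid(x, z) || !valid(y, z)) continue;
                const double rxy = r(x, y), rxz = r(x, z), ryz = r(y, z);
                const double dxy = std::sqrt((1.0 - rxz * rxz) * (1.0 - ryz * ryz));
                const double dxz = std::sqrt((1.0 - rxy * rxy) * (1.0 - ryz * ryz));
                const double dyz = std::sqrt((1.0 - rxy * rxy) * (1.0 - rxz * rxz));
                if (dxy < guard || dxz < guard || dyz < guard) continue;
                const double pxy = (rxy - rxz * ryz) / dxy;
                const double pxz = (rxz - rxy * ryz) / dxz;
                const double pyz = (ryz - rxy * rxz) / dyz;
                const double t1 = (std::fabs(rxy) < guard) ? 0.0 : pxy / rxy;
                const double t2 = (std::fabs(rxz) < guard) ? 0.0 : pxz / rxz;
                const double t3 = (std::fabs(ryz) < guard) ? 0.0 : pyz / ryz;
                const double aeps = std::fabs((t1 + t2 + t3) / 3.0);
                const double axy = std::fabs(rxy), axz = std::fabs(rxz), ayz = std::fabs(ryz);
                if (axy < aeps * axz && axy < aeps * ayz) { elim(x, y) = true; elim(y, x) = true; }
                if (axz < aeps * axy && axz < aeps * ayz) { elim(x, z) = true; elim(z, x) = true; }
                if (ayz < aeps * axy && ayz < aeps * axz) { elim(y, z) = true; elim(z, y) = true; }
            }
        }
    }

    LogicalMatrix keep(n, n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            keep(i, j) = (i != j) && valid(i, j) && !elim(i, j);
    return keep;
}
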