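// Compiled kernels for the inner loops: Shrake-Rupley point exclusion and
// grouped minimum-distance matrices (optionally under orthorhombic PBC).
#include <Rcpp.h>
using namespace Rcpp;

static inline double wrap1(double d, double box) {
  if (box > 0.0) d -= box * std::round(d / box);
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector inflated,
                       int npoints) {
  const int n = coords.nrow();
  // deterministic golden-spiral lattice on the unit sphere
  std::vector<double> px(npoints), py(npoints), pz(npoints);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < npoints; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / npoints;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    px[k] = r * std::cos(phi);
    py[k] = r * std::sin(phi);
    pz[k] = z;
  }
  NumericVector area(n);
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    const double ri = inflated[i];
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
             dz = coords(j, 2) - zi;
      double lim = ri + inflated[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nbr.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < npoints; ++k) {
      const double sx = xi + ri * px[k], sy = yi + ri * py[k],
                   sz = zi + ri * pz[k];
      bool out = true;
      for (size_t m = 0; m < nbr.size(); ++m) {
        const int j = nbr[m];
        double dx = sx - coords(j, 0), dy = sy - coords(j, 1),
               dz = sz - coords(j, 2);
        double rj = inflated[j];
        if (dx * dx + dy * dy + dz * dz < rj * rj) { out = false; break; }
      }
      if (out) ++exposed;
    }
    area[i] = 4.0 * M_PI * ri * ri * exposed / npoints;
  }
  return area;
}

// Minimum distance between every group in X and every group in Y.
// gx/gy are 1-based group ids per row; returns an ngx x ngy matrix.
// [[Rcpp::export]]
NumericMatrix cpp_group_min_dist(NumericMatrix X, IntegerVector gx, int ngx,
                                 NumericMatrix Y, IntegerVector gy, int ngy,
                                 NumericVector box) {
  const bool pbc = box.size() == 3;
  NumericMatrix out(ngx, ngy);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int i = 0; i < X.nrow(); ++i) {
    const int gi = gx[i] - 1;
    for (int j = 0; j < Y.nrow(); ++j) {
      const int gj = gy[j] - 1;
      double dx = Y(j, 0) - X(i, 0), dy = Y(j, 1) - X(i, 1),
             dz = Y(j, 2) - X(i, 2);
      if (pbc) {
        dx = wrap1(dx, box[0]);
        dy = wrap1(dy, box[1]);
        dz = wrap1(dz, box[2]);
      }
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < out(gi, gj)) out(gi, gj) = d2;
    }
  }
  for (int i = 0; i < ngx; ++i)
    for (int j = 0; j < ngy; ++j)
      out(i, j) = std::sqrt(out(i, j));
  return out;
}
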