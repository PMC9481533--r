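#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley solvent accessible surface area.
//
// coords: n x 3 atom centers (Angstrom); radii: vdW radii; probe: probe
// radius; points: m x 3 quasi-uniform unit-sphere directions (deterministic,
// supplied from R); subset: 1-based indices of atoms whose area is computed
// (all atoms always act as occluders).
//
// For each computed atom, the fraction of sphere points on its
// solvent-expanded sphere (radius r_i + probe) lying outside every
// neighbour's expanded sphere is scaled by 4*pi*(r_i + probe)^2.
// [[Rcpp::export(name = ".sasaCpp")]]
NumericVector sasaCpp(NumericMatrix coords, NumericVector radii,
                      double probe, NumericMatrix points,
                      IntegerVector subset) {
  const int n = coords.nrow();
  const int m = points.nrow();
  const int ns = subset.size();
  NumericVector out(ns);
  std::vector<double> ex(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    ex[i] = radii[i] + probe;
    if (ex[i] > rmax) rmax = ex[i];
  }
  std::vector<int> nbr;
  nbr.reserve(256);
  for (int s = 0; s < ns; ++s) {
    const int i = subset[s] - 1;
    const double ri = ex[i];
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    nbr.clear();
    const double reach = ri + rmax;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = coords(j, 0) - xi;
      const double dy = coords(j, 1) - yi;
      const double dz = coords(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < reach * reach) {
        const double lim = ri + ex[j];
        if (d2 < lim * lim) nbr.push_back(j);
      }
    }
    int acc = 0;
    for (int k = 0; k < m; ++k) {
      const double px = xi + ri * points(k, 0);
      const double py = yi + ri * points(k, 1);
      const double pz = zi + ri * points(k, 2);
      bool free = true;
      for (size_t q = 0; q < nbr.size(); ++q) {
        const int j = nbr[q];
        const double dx = px - coords(j, 0);
        const double dy = py - coords(j, 1);
        const double dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < ex[j] * ex[j]) {
          free = false;
          break;
        }
      }
      if (free) ++acc;
    }
    out[s] = 4.0 * M_PI * ri * ri * (double)acc / (double)m;
  }
  return out;
}
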