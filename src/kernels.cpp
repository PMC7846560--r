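#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Semi-global dynamic-programming alignment (free end gaps) over a
// precomputed per-pair score matrix. Linear gap penalty. Returns the aligned
// index pairs (1-based), strictly increasing in both sequences.
// [[Rcpp::export]]
IntegerMatrix nw_align(NumericMatrix S, double gap) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix F(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1); // 1 diag, 2 up (gap in b), 3 left (gap in a)
  for (int i = 0; i <= n; ++i) { F(i, 0) = 0.0; P(i, 0) = 2; }
  for (int j = 0; j <= m; ++j) { F(0, j) = 0.0; P(0, j) = 3; }
  P(0, 0) = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = F(i - 1, j - 1) + S(i - 1, j - 1);
      double u = F(i - 1, j) + (j == m ? 0.0 : gap);
      double l = F(i, j - 1) + (i == n ? 0.0 : gap);
      if (d >= u && d >= l)      { F(i, j) = d; P(i, j) = 1; }
      else if (u >= l)           { F(i, j) = u; P(i, j) = 2; }
      else                       { F(i, j) = l; P(i, j) = 3; }
    }
  }
  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int p = P(i, j);
    if (p == 1)      { ai.push_back(i); bi.push_back(j); --i; --j; }
    else if (p == 2) { --i; }
    else             { --j; }
  }
  const int k = (int)ai.size();
  IntegerMatrix out(k, 2);
  for (int r = 0; r < k; ++r) { // reverse into increasing order
    out(r, 0) = ai[k - 1 - r];
    out(r, 1) = bi[k - 1 - r];
  }
  return out;
}

// Shrake-Rupley solvent accessible surface area. `sph` holds unit sphere
// sample points (n_points x 3); radii must already include the probe.
// Returns per-atom accessible area in A^2.
// [[Rcpp::export]]
NumericVector sasa_atoms(NumericMatrix xyz, NumericVector radii,
                         NumericMatrix sph) {
  const int n = xyz.nrow(), np = sph.nrow();
  NumericVector area(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i];
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xyz(i, 0);
      double dy = xyz(j, 1) - xyz(i, 1);
      double dz = xyz(j, 2) - xyz(i, 2);
      double lim = ri + radii[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < np; ++p) {
      const double px = xyz(i, 0) + ri * sph(p, 0);
      const double py = xyz(i, 1) + ri * sph(p, 1);
      const double pz = xyz(i, 2) + ri * sph(p, 2);
      bool free_pt = true;
      for (size_t q = 0; q < nb.size(); ++q) {
        const int j = nb[q];
        const double dx = px - xyz(j, 0);
        const double dy = py - xyz(j, 1);
        const double dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < radii[j] * radii[j]) {
          free_pt = false; break;
        }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)acc / (double)np;
  }
  return area;
}
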