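#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fixed-radius neighbor pairs via a uniform grid (cell list).
// Returns a 2-column integer matrix of pairs (i < j), 1-based,
// with Euclidean distance <= radius. Identical result to all-pairs.
// [[Rcpp::export(name = ".radius_pairs_cpp")]]
IntegerMatrix radius_pairs_cpp(NumericMatrix pos, double radius) {
  const int n = pos.nrow();
  std::vector<std::pair<int, int> > pairs;
  if (n < 2 || radius < 0) return IntegerMatrix(0, 2);
  const double r2 = radius * radius;

  double mn[3], mx[3];
  for (int k = 0; k < 3; ++k) { mn[k] = R_PosInf; mx[k] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      double v = pos(i, k);
      if (v < mn[k]) mn[k] = v;
      if (v > mx[k]) mx[k] = v;
    }
  // grid cell edge >= radius so neighbors are within adjacent cells
  double edge = radius > 0 ? radius : 1.0;
  int dims[3];
  for (int k = 0; k < 3; ++k) {
    double span = mx[k] - mn[k];
    dims[k] = span > 0 ? (int)std::floor(span / edge) + 1 : 1;
    if (dims[k] < 1) dims[k] = 1;
  }
  // guard against pathological memory use for tiny radii: cap bins at ~4M
  double nbins = (double)dims[0] * dims[1] * dims[2];
  while (nbins > 4e6) {
    for (int k = 0; k < 3; ++k) dims[k] = (dims[k] + 1) / 2;
    edge *= 2.0;
    nbins = (double)dims[0] * dims[1] * dims[2];
  }
  const int nb = dims[0] * dims[1] * dims[2];
  std::vector<int> cell(n);
  std::vector<int> count(nb + 1, 0);
  for (int i = 0; i < n; ++i) {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      int b = (int)std::floor((pos(i, k) - mn[k]) / edge);
      if (b < 0) b = 0;
      if (b >= dims[k]) b = dims[k] - 1;
      c[k] = b;
    }
    cell[i] = c[0] + dims[0] * (c[1] + dims[1] * c[2]);
    ++count[cell[i] + 1];
  }
  for (int b = 0; b < nb; ++b) count[b + 1] += count[b];
  std::vector<int> order(n);
  {
    std::vector<int> cursor(count.begin(), count.end() - 1);
    for (int i = 0; i < n; ++i) order[cursor[cell[i]]++] = i;
  }

  for (int bz = 0; bz < dims[2]; ++bz)
    for (int by = 0; by < dims[1]; ++by)
      for (int bx = 0; bx < dims[0]; ++bx) {
        int b = bx + dims[0] * (by + dims[1] * bz);
        int from = count[b], to = count[b + 1];
        if (from == to) continue;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int nx = bx + dx, ny = by + dy, nz = bz + dz;
              if (nx < 0 || ny < 0 || nz < 0 ||
                  nx >= dims[0] || ny >= dims[1] || nz >= dims[2]) continue;
              int b2 = nx + dims[0] * (ny + dims[1] * nz);
              if (b2 < b) continue; // visit each bin pair once
              int from2 = count[b2], to2 = count[b2 + 1];
              for (int ii = from; ii < to; ++ii) {
                int i = order[ii];
                int jj0 = (b2 == b) ? ii + 1 : from2;
                for (int jj = jj0; jj < to2; ++jj) {
                  int j = order[jj];
                  double dxy = pos(i, 0) - pos(j, 0);
                  double d2 = dxy * dxy;
                  dxy = pos(i, 1) - pos(j, 1); d2 += dxy * dxy;
                  dxy = pos(i, 2) - pos(j, 2); d2 += dxy * dxy;
                  if (d2 <= r2) {
                    if (i < j) pairs.push_back(std::make_pair(i + 1, j + 1));
                    else pairs.push_back(std::make_pair(j + 1, i + 1));
                  }
                }
              }
            }
      }

  IntegerMatrix out(pairs.size(), 2);
  for (size_t p = 0; p < pairs.size(); ++p) {
    out(p, 0) = pairs[p].first;
    out(p, 1) = pairs[p].second;
  }
  return out;
}
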