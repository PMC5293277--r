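#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Statistical region merging (sorted-edge, predicate-based union-find over
// 4-neighbour pixel pairs). Intensities are expected on a 0..g scale
// (g = 256 for 8-bit data). Q controls granularity: higher Q merges less.

static int uf_find(std::vector<int> &par, int x) {
  while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; }
  return x;
}

// [[Rcpp::export]]
List srm_regions(NumericMatrix img, double Q, double g) {
  int nr = img.nrow(), nc = img.ncol();
  int n = nr * nc;
  std::vector<int> par(n);
  std::vector<double> sum(n);
  std::vector<int> sz(n, 1);
  for (int i = 0; i < n; ++i) { par[i] = i; sum[i] = img[i]; }

  // 4-neighbour edges, bucket-sorted by |dI| quantized to 256 levels
  int m = nr * (nc - 1) + (nr - 1) * nc;
  std::vector<int> ea(m), eb(m);
  std::vector<double> ew(m);
  int k = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int p = c * nr + r;
      if (r + 1 < nr) { ea[k] = p; eb[k] = p + 1; ew[k] = std::fabs(img[p] - img[p + 1]); ++k; }
      if (c + 1 < nc) { ea[k] = p; eb[k] = p + nr; ew[k] = std::fabs(img[p] - img[p + nr]); ++k; }
    }
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return ew[a] < ew[b]; });

  double delta = 1.0 / (6.0 * double(n) * double(n));
  double lg = std::log(2.0 / delta);
  for (int i = 0; i < m; ++i) {
    int e = ord[i];
    int ra = uf_find(par, ea[e]), rb = uf_find(par, eb[e]);
    if (ra == rb) continue;
    double ma = sum[ra] / sz[ra], mb = sum[rb] / sz[rb];
    double b2a = g * g * lg / (2.0 * Q * sz[ra]);
    double b2b = g * g * lg / (2.0 * Q * sz[rb]);
    double d = ma - mb;
    if (d * d <= b2a + b2b) {
      if (sz[ra] < sz[rb]) std::swap(ra, rb);
      par[rb] = ra;
      sum[ra] += sum[rb];
      sz[ra] += sz[rb];
    }
  }

  // compact labels in scan order, emit per-pixel region mean
  IntegerMatrix lab(nr, nc);
  NumericMatrix mean(nr, nc);
  std::vector<int> newlab(n, 0);
  int nlab = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf_find(par, i);
    if (newlab[r] == 0) newlab[r] = ++nlab;
    lab[i] = newlab[r];
    mean[i] = sum[r] / sz[r];
  }
  return List::create(_["labels"] = lab, _["mean"] = mean,
                      _["n_regions"] = nlab);
}
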