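#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // reflect about the array edges until inside [0, n)
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian blur with reflecting boundary. Kernel truncated at
// 3 sigma. Both passes run as contiguous column updates so the inner loops
// vectorize.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(const NumericMatrix& img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (int i = 0; i <= 2 * r; ++i) k[i] /= s;

  // pad vertically by r (reflection), blur rows of the padded block
  int nrp = nr + 2 * r;
  std::vector<double> pad(nrp * nc), tmp((size_t)nr * (nc + 2 * r), 0.0);
  const double* src = &img(0, 0);
  for (int j = 0; j < nc; ++j) {
    double* pj = &pad[(size_t)j * nrp];
    const double* sj = src + (size_t)j * nr;
    for (int i = -r; i < nr + r; ++i)
      pj[i + r] = sj[reflect_idx(i, nr)];
  }
  // vertical pass into tmp, with horizontal reflection padding of columns
  for (int jp = 0; jp < nc + 2 * r; ++jp) {
    int j = reflect_idx(jp - r, nc);
    const double* pj = &pad[(size_t)j * nrp];
    double* tj = &tmp[(size_t)jp * nr];
    for (int d = 0; d <= 2 * r; ++d) {
      double kd = k[d];
      const double* q = pj + d;
      for (int i = 0; i < nr; ++i) tj[i] += kd * q[i];
    }
  }
  // horizontal pass: out column j = sum_d k[d] * tmp column (j + d)
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    double* oj = &out(0, j);
    for (int d = 0; d <= 2 * r; ++d) {
      double kd = k[d];
      const double* tj = &tmp[(size_t)(j + d) * nr];
      for (int i = 0; i < nr; ++i) oj[i] += kd * tj[i];
    }
  }
  return out;
}

// Local maxima above `threshold`, separated by >= min_sep (Euclidean).
// Equal-intensity ties within min_sep: keep the candidate with smaller
// (row, col) lexicographic order. Returns 0-based (row, col) pairs.
// [[Rcpp::export]]
IntegerMatrix cpp_local_maxima(const NumericMatrix& img, double threshold,
                               double min_sep) {
  int nr = img.nrow(), nc = img.ncol();
  int r = std::max(1, (int)std::ceil(min_sep));
  double r2 = min_sep * min_sep;
  std::vector<int> rows, cols;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double v = img(i, j);
      if (!(v > threshold)) continue;
      bool keep = true;
      for (int di = -r; di <= r && keep; ++di) {
        int ii = i + di;
        if (ii < 0 || ii >= nr) continue;
        for (int dj = -r; dj <= r; ++dj) {
          if (di == 0 && dj == 0) continue;
          int jj = j + dj;
          if (jj < 0 || jj >= nc) continue;
          if ((double)(di * di + dj * dj) > r2) continue;
          double w = img(ii, jj);
          if (w > v || (w == v && (ii < i || (ii == i && jj < j)))) {
            keep = false;
            break;
          }
        }
      }
      if (keep) { rows.push_back(i); cols.push_back(j); }
    }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t q = 0; q < rows.size(); ++q) {
    out(q, 0) = rows[q];
    out(q, 1) = cols[q];
  }
  return out;
}

// Minimum-cost perfect assignment on a square cost matrix (Jonker-Volgonant
// style shortest augmenting paths with potentials, O(n^3)). Returns for each
// row the 0-based column assigned to it.
// [[Rcpp::export]]
IntegerVector cpp_solve_lsap(const NumericMatrix& cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j) ans[p[j] - 1] = j - 1;
  return ans;
}
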