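#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger (KSG-1) pairwise mutual information.
// x: p x n matrix (rows = genes, columns = samples), k: neighbour count.
// For each pair (i, j): per sample s, eps_s = max-norm distance to the
// k-th nearest neighbour in the joint space (self excluded); nx_s / ny_s
// count samples strictly inside eps_s in each marginal;
// MI = digamma(k) + digamma(n) - mean(digamma(nx+1) + digamma(ny+1)).
// [[Rcpp::export]]
NumericMatrix knn_mi_cpp(NumericMatrix x, int k) {
  const int p = x.nrow(), n = x.ncol();
  NumericMatrix mi(p, p);
  const double base_term = R::digamma((double)k) + R::digamma((double)n);

  // per-gene absolute distance matrices (n*n, contiguous)
  std::vector<std::vector<double> > D(p, std::vector<double>(n * n));
  for (int g = 0; g < p; ++g) {
    for (int a = 0; a < n; ++a)
      for (int b = 0; b < n; ++b)
        D[g][a * n + b] = std::fabs(x(g, a) - x(g, b));
  }

  std::vector<double> dz(n);
  for (int i = 0; i < p - 1; ++i) {
    const std::vector<double>& Di = D[i];
    for (int j = i + 1; j < p; ++j) {
      const std::vector<double>& Dj = D[j];
      double acc = 0.0;
      for (int a = 0; a < n; ++a) {
        const double* dia = &Di[a * n];
        const double* dja = &Dj[a * n];
        int m = 0;
        for (int b = 0; b < n; ++b) {
          if (b == a) continue;
          dz[m++] = std::max(dia[b], dja[b]);
        }
        std::nth_element(dz.begin(), dz.begin() + (k - 1), dz.begin() + m);
        const double eps = dz[k - 1];
        int nx = 0, ny = 0;
        for (int b = 0; b < n; ++b) {
          if (b == a) continue;
          if (dia[b] < eps) ++nx;
          if (dja[b] < eps) ++ny;
        }
        acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
      }
      double est = base_term - acc / n;
      if (est < 0.0) est = 0.0;
      mi(i, j) = est;
      mi(j, i) = est;
    }
  }
  return mi;
}
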