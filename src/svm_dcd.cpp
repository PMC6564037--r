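#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear support vector
// machine:
//   min_w 0.5 ||w||^2 + C * sum_i max(0, 1 - y_i w.x_i)
// solved in the dual (box-constrained QP) by coordinate descent over the
// alpha_i, following the standard large-scale linear-SVM scheme.  A bias
// term is handled by the caller through an augmented constant feature.
//
// Xt is the d x n matrix of training samples stored sample-per-column so
// the inner loop touches contiguous memory.  The per-epoch visiting order
// is a Fisher-Yates permutation driven by a small deterministic LCG, so the
// solver is bit-reproducible for a given seed and independent of R's RNG.
//
// [[Rcpp::export]]
NumericVector svm_dcd_train(const NumericMatrix& Xt, const NumericVector& y,
                            double C, int max_epochs, double tol,
                            unsigned int seed) {
  const int d = Xt.nrow();
  const int n = Xt.ncol();
  if (y.size() != n) stop("label/sample size mismatch");

  std::vector<double> w(d, 0.0), alpha(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &Xt(0, i);
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
    qii[i] = s;
  }

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  unsigned long long state = seed ? seed : 1u;
  auto next_rand = [&state]() {
    state = state * 6364136223846793005ULL + 1442695040888963407ULL;
    return (unsigned int)(state >> 33);
  };

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    for (int i = n - 1; i > 0; --i) {
      int j = next_rand() % (i + 1);
      std::swap(order[i], order[j]);
    }
    double max_viol = 0.0;
    for (int k = 0; k < n; ++k) {
      const int i = order[k];
      if (qii[i] <= 0.0) continue;
      const double* xi = &Xt(0, i);
      double wx = 0.0;
      for (int j = 0; j < d; ++j) wx += w[j] * xi[j];
      const double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0) PG = std::min(G, 0.0);
      else if (alpha[i] >= C) PG = std::max(G, 0.0);
      if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
      if (std::fabs(PG) > 1e-12) {
        const double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        alpha[i] = a_new;
        const double step = (a_new - a_old) * y[i];
        if (step != 0.0)
          for (int j = 0; j < d; ++j) w[j] += step * xi[j];
      }
    }
    if (max_viol < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}
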