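#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Sequential minimal optimisation for the soft-margin C-SVC dual with a
// precomputed kernel matrix. Deterministic: the second working variable is
// the one maximising |E_i - E_j|, with a sequential fallback scan.
// Returns alpha and the intercept b so that f(x) = sum alpha_i y_i K(x_i, x) + b.
// [[Rcpp::export]]
List cpp_svm_smo(arma::mat K, arma::vec y, double C, double tol = 1e-3,
                 int max_passes = 5, int max_updates = 200000) {
  const arma::uword n = K.n_rows;
  arma::vec alpha(n, arma::fill::zeros);
  double b = 0.0;
  arma::vec f(n, arma::fill::zeros); // f_i = sum_l alpha_l y_l K(l, i)
  int passes = 0, updates = 0;
  const double eps = 1e-12;

  auto try_pair = [&](arma::uword i, arma::uword j) -> bool {
    if (i == j) return false;
    const double Ei = f(i) + b - y(i), Ej = f(j) + b - y(j);
    const double ai_old = alpha(i), aj_old = alpha(j);
    double L, H;
    if (y(i) != y(j)) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    if (H - L < eps) return false;
    const double eta = 2.0 * K(i, j) - K(i, i) - K(j, j);
    if (eta >= -eps) return false;
    double aj = aj_old - y(j) * (Ei - Ej) / eta;
    aj = std::min(H, std::max(L, aj));
    if (std::fabs(aj - aj_old) < 1e-7) return false;
    const double ai = ai_old + y(i) * y(j) * (aj_old - aj);
    alpha(i) = ai;
    alpha(j) = aj;
    f += (ai - ai_old) * y(i) * K.col(i) + (aj - aj_old) * y(j) * K.col(j);
    const double b1 = b - Ei - y(i) * (ai - ai_old) * K(i, i) -
                      y(j) * (aj - aj_old) * K(i, j);
    const double b2 = b - Ej - y(i) * (ai - ai_old) * K(i, j) -
                      y(j) * (aj - aj_old) * K(j, j);
    if (ai > eps && ai < C - eps)
      b = b1;
    else if (aj > eps && aj < C - eps)
      b = b2;
    else
      b = 0.5 * (b1 + b2);
    ++updates;
    return true;
  };

  while (passes < max_passes && updates < max_updates) {
    int changed = 0;
    for (arma::uword i = 0; i < n; ++i) {
      const double Ei = f(i) + b - y(i);
      const double r = y(i) * Ei;
      if ((r < -tol && alpha(i) < C - eps) || (r > tol && alpha(i) > eps)) {
        // second-choice heuristic: maximise |Ei - Ej|
        arma::vec E = f + b - y;
        arma::uword j = i;
        double best = -1.0;
        for (arma::uword l = 0; l < n; ++l) {
          if (l == i) continue;
          const double gap = std::fabs(Ei - E(l));
          if (gap > best) {
            best = gap;
            j = l;
          }
        }
        bool ok = try_pair(i, j);
        if (!ok) { // deterministic fallback scan
          for (arma::uword l = 0; l < n && !ok; ++l) ok = try_pair(i, l);
        }
        if (ok) ++changed;
      }
    }
    passes = (changed == 0) ? passes + 1 : 0;
  }
  return List::create(_["alpha"] = alpha, _["b"] = b, _["updates"] = updates);
}
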