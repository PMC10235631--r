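#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Neighborhood-component feature selection:
//   d_w(i,l) = sum_j w_j^2 |x_ij - x_lj|
//   p_il = exp(-d_w(i,l)) / sum_{m != i} exp(-d_w(i,m))
//   p_i  = sum_{l: y_l = y_i} p_il
//   F(w) = sum_i p_i - lambda * sum_j w_j^2
// All pair quantities are stored once per unordered pair (i < l); the
// kernel exp(-d) is symmetric even though p_il is not.
struct NcaWork {
  arma::mat Dpair;      // npair x d, |x_ij - x_lj|
  arma::uvec ia, la;    // pair endpoints
  arma::vec same;       // 1 if same class
  arma::uword n;
  // buffers
  arma::vec distp, ep, Z, numer, pi, Mp;
};

static double nca_objective(NcaWork &wk, const arma::vec &w, double lambda) {
  // per-column accumulation (not BLAS gemv) so that identical feature
  // columns produce bitwise-identical results and ties stay exact
  wk.distp.zeros();
  for (arma::uword j = 0; j < wk.Dpair.n_cols; ++j)
    wk.distp += (w(j) * w(j)) * wk.Dpair.col(j);
  wk.ep = arma::exp(-wk.distp);
  wk.Z.zeros();
  wk.numer.zeros();
  const arma::uword np = wk.ia.n_elem;
  for (arma::uword k = 0; k < np; ++k) {
    const double e = wk.ep(k);
    const arma::uword i = wk.ia(k), l = wk.la(k);
    wk.Z(i) += e;
    wk.Z(l) += e;
    if (wk.same(k) > 0.5) {
      wk.numer(i) += e;
      wk.numer(l) += e;
    }
  }
  for (arma::uword i = 0; i < wk.n; ++i) {
    wk.pi(i) = (wk.Z(i) > 0.0) ? wk.numer(i) / wk.Z(i) : 0.0;
  }
  return arma::accu(wk.pi) - lambda * arma::dot(w, w);
}

// gradient at the state left in the buffers by nca_objective(w)
static arma::vec nca_gradient(NcaWork &wk, const arma::vec &w, double lambda) {
  const arma::uword np = wk.ia.n_elem;
  for (arma::uword k = 0; k < np; ++k) {
    const arma::uword i = wk.ia(k), l = wk.la(k);
    const double s = wk.same(k);
    double m = 0.0;
    if (wk.Z(i) > 0.0) m += (wk.pi(i) - s) * wk.ep(k) / wk.Z(i);
    if (wk.Z(l) > 0.0) m += (wk.pi(l) - s) * wk.ep(k) / wk.Z(l);
    wk.Mp(k) = m;
  }
  arma::vec g(w.n_elem);
  for (arma::uword j = 0; j < w.n_elem; ++j)
    g(j) = 2.0 * w(j) * arma::dot(wk.Dpair.col(j), wk.Mp) -
      2.0 * lambda * w(j);
  return g;
}

// Gradient ascent from w = 1 with Barzilai-Borwein step initialisation and
// monotone backtracking line search; stops at |dF| < tol or maxit accepted
// iterations.
// [[Rcpp::export]]
List cpp_ncfs_fit(arma::mat X, arma::ivec y, double lambda,
                  int maxit = 200, double tol = 1e-6) {
  const arma::uword n = X.n_rows, d = X.n_cols;
  const arma::uword np = n * (n - 1) / 2;
  NcaWork wk;
  wk.n = n;
  wk.Dpair.set_size(np, d);
  wk.ia.set_size(np);
  wk.la.set_size(np);
  wk.same.set_size(np);
  arma::uword k = 0;
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword l = i + 1; l < n; ++l, ++k) {
      wk.ia(k) = i;
      wk.la(k) = l;
      wk.same(k) = (y(i) == y(l)) ? 1.0 : 0.0;
      for (arma::uword j = 0; j < d; ++j)
        wk.Dpair(k, j) = std::fabs(X(i, j) - X(l, j));
    }
  }
  wk.distp.set_size(np);
  wk.ep.set_size(np);
  wk.Z.set_size(n);
  wk.numer.set_size(n);
  wk.pi.set_size(n);
  wk.Mp.set_size(np);

  arma::vec w(d, arma::fill::ones);
  double F = nca_objective(wk, w, lambda);
  arma::vec g = nca_gradient(wk, w, lambda);
  arma::vec w_old = w, g_old = g;
  std::vector<double> trace;
  trace.push_back(F);
  double step = 1.0;
  bool have_prev = false;

  for (int it = 0; it < maxit; ++it) {
    if (have_prev) { // Barzilai-Borwein initial step (clamped)
      const arma::vec sv = w - w_old;
      const arma::vec yv = g - g_old;
      const double sy = std::fabs(arma::dot(sv, yv));
      if (sy > 1e-300) step = arma::dot(sv, sv) / sy;
      step = std::min(std::max(step, 1e-10), 1e6);
    }
    bool accepted = false;
    double s = step, F1 = F;
    arma::vec w1;
    for (int ls = 0; ls < 30; ++ls) {
      w1 = arma::clamp(w + s * g, 0.0, arma::datum::inf);
      F1 = nca_objective(wk, w1, lambda);
      if (F1 > F) {
        accepted = true;
        break;
      }
      s *= 0.5;
      if (s < 1e-14) break;
    }
    if (!accepted) break;
    const double dF = F1 - F;
    w_old = w;
    g_old = g;
    w = w1;
    F = F1;
    g = nca_gradient(wk, w, lambda); // buffers hold the accepted state
    have_prev = true;
    trace.push_back(F);
    if (dF < tol) break;
  }
  // leave buffers at the final w (gradient call above did not change them)
  const double loss = 1.0 - arma::mean(wk.pi);
  return List::create(_["w"] = w, _["objective"] = F, _["loss"] = loss,
                      _["trace"] = trace, _["p_i"] = wk.pi);
}

// Weighted-distance 1-NN prediction used as the held-out CV loss:
// each test row gets the label of the training row minimising
// d_w(x, x_train) = sum_j w_j^2 |x_j - x_train_j|.
// [[Rcpp::export]]
IntegerVector cpp_wnn_predict(arma::mat Xtrain, arma::ivec ytrain,
                              arma::mat Xtest, arma::vec w) {
  const arma::uword nte = Xtest.n_rows, ntr = Xtrain.n_rows, d = Xtrain.n_cols;
  const arma::vec w2 = arma::square(w);
  IntegerVector out(nte);
  for (arma::uword i = 0; i < nte; ++i) {
    double best = arma::datum::inf;
    arma::uword bidx = 0;
    for (arma::uword l = 0; l < ntr; ++l) {
      double dist = 0.0;
      for (arma::uword j = 0; j < d; ++j)
        dist += w2(j) * std::fabs(Xtest(i, j) - Xtrain(l, j));
      if (dist < best) {
        best = dist;
        bidx = l;
      }
    }
    out[i] = ytrain(bidx);
  }
  return out;
}
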