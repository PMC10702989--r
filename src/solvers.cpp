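// Compiled numerical kernels: nonnegative-lasso coordinate descent (the
// per-subject self-expressive coding problem) and the FISTA loop of the
// L2,1 multi-modality association solver. Semantics mirror the documented
// R-level interfaces in R/self_expressive.R and R/association.R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// min_{w >= 0} 0.5 ||x - D w||^2 + lambda sum(w), parameterized by the donor
// Gram matrix G = D D' and c0 = D x. Cyclic coordinate descent in fixed
// donor order; coordinates with zero diagonal (zero donors) stay zero.
// [[Rcpp::export]]
arma::vec nn_lasso_cd_cpp(const arma::mat& G, const arma::vec& c0,
                          double lambda, double tol = 1e-8,
                          int max_sweeps = 10000) {
  const arma::uword n = c0.n_elem;
  arma::vec w(n, arma::fill::zeros);
  arma::vec gd = G.diag();
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double delta = 0.0;
    for (arma::uword j = 0; j < n; ++j) {
      if (gd(j) <= 0.0) continue;
      double rho = c0(j) - arma::dot(G.row(j), w) + gd(j) * w(j);
      double wj = (rho - lambda) / gd(j);
      if (wj < 0.0) wj = 0.0;
      double d = std::fabs(wj - w(j));
      if (d > delta) delta = d;
      w(j) = wj;
    }
    if (delta < tol) break;
  }
  return w;
}

static double l21_norm_cpp(const arma::mat& W) {
  return arma::accu(arma::sqrt(arma::sum(arma::square(W), 1)));
}

static arma::mat row_prox_cpp(const arma::mat& V, double thr) {
  arma::vec nrm = arma::sqrt(arma::sum(arma::square(V), 1));
  arma::mat out = V;
  for (arma::uword j = 0; j < V.n_rows; ++j) {
    double s = nrm(j) > thr ? 1.0 - thr / nrm(j) : 0.0;
    out.row(j) *= s;
  }
  return out;
}

// FISTA with backtracking and monotone restart for
// min_W 0.5 sum_m ||yc - X^m w_m||^2 + lambda ||W||_{2,1}. The loss and
// gradient are evaluated through the residuals (not the Gram quadratic
// form) so the objective carries relative -- not absolute -- rounding
// error near the optimum. Returns the weight matrix, objective trace and
// iteration count.
// [[Rcpp::export]]
List l21_fista_cpp(const List& Xlist, const arma::vec& yc,
                   double lambda, double step0, double tol, int max_iter,
                   const arma::mat& Winit) {
  const int M = Xlist.size();
  std::vector<arma::mat> X(M);
  for (int m = 0; m < M; ++m) X[m] = as<arma::mat>(Xlist[m]);
  const arma::uword d = X[0].n_cols;

  auto fval = [&](const arma::mat& W) {
    double f = 0.0;
    for (int m = 0; m < M; ++m) {
      arma::vec r = yc - X[m] * W.col(m);
      f += 0.5 * arma::dot(r, r);
    }
    return f;
  };
  auto grad = [&](const arma::mat& W) {
    arma::mat G(d, M);
    for (int m = 0; m < M; ++m) {
      G.col(m) = X[m].t() * (X[m] * W.col(m) - yc);
    }
    return G;
  };

  arma::mat W = Winit, Z = Winit;
  double theta = 1.0, step = step0;
  double obj = fval(W) + lambda * l21_norm_cpp(W);
  std::vector<double> trace;
  trace.push_back(obj);
  int n_iter = 0;

  for (int it = 1; it <= max_iter; ++it) {
    n_iter = it;
    arma::mat G = grad(Z);
    double fZ = fval(Z);
    arma::mat V;
    double f_new = 0.0;
    while (true) {
      V = row_prox_cpp(Z - step * G, step * lambda);
      arma::mat D = V - Z;
      f_new = fval(V);
      double bound = fZ + arma::dot(G, D) + arma::dot(D, D) / (2.0 * step) + 1e-12;
      if (f_new <= bound || step < 1e-300) break;
      step /= 2.0;
    }
    double obj_new = f_new + lambda * l21_norm_cpp(V);
    if (obj_new > obj) {
      // momentum overshoot: restart at the monotone iterate
      Z = W;
      theta = 1.0;
      continue;
    }
    double theta_new = (1.0 + std::sqrt(1.0 + 4.0 * theta * theta)) / 2.0;
    Z = V + ((theta - 1.0) / theta_new) * (V - W);
    W = V;
    theta = theta_new;
    bool converged = (obj - obj_new) <= tol * std::max(1.0, std::fabs(obj));
    obj = obj_new;
    trace.push_back(obj);
    if (converged) break;
  }
  return List::create(_["W"] = W, _["obj_trace"] = trace,
                      _["n_iter"] = n_iter, _["objective"] = obj);
}
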