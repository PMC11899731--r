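// Core numerical solvers: graphical lasso (block coordinate descent on the
// covariance, Friedman-style) and the sum-to-zero constrained lasso (ADMM
// with the equality constraint absorbed into the quadratic KKT step).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// L1-penalised precision estimation.
// Solves max logdet(Theta) - tr(S Theta) - lambda ||Theta||_1 by cycling
// over columns of the working covariance W; each column update is a lasso
// problem solved by coordinate descent.
// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda,
                      double tol = 1e-7, int maxit = 200) {
  const int p = S.n_rows;
  mat W = S;
  W.diag() += lambda;
  mat B(p > 1 ? p - 1 : 1, p, fill::zeros);   // per-column lasso coefficients

  if (p == 1) {
    mat Theta(1, 1);
    Theta(0, 0) = 1.0 / W(0, 0);
    return Rcpp::List::create(Rcpp::Named("w") = W,
                              Rcpp::Named("theta") = Theta,
                              Rcpp::Named("iterations") = 0);
  }

  double offmean = (accu(abs(S)) - accu(abs(S.diag()))) / (p * (p - 1));
  double thr = tol * std::max(offmean, 1e-12);

  int it = 0;
  for (; it < maxit; ++it) {
    double dW = 0.0;
    for (int j = 0; j < p; ++j) {
      uvec idx(p - 1);
      for (int i = 0, t = 0; i < p; ++i) if (i != j) idx[t++] = i;
      mat W11 = W(idx, idx);
      vec s12(p - 1);
      for (int t = 0; t < p - 1; ++t) s12[t] = S(idx[t], j);

      vec beta = B.col(j);
      for (int inner = 0; inner < 200; ++inner) {
        double dmax = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double old = beta[k];
          double r = s12[k] - dot(W11.col(k), beta) + W11(k, k) * old;
          double bn = soft(r, lambda) / W11(k, k);
          beta[k] = bn;
          double d = std::fabs(bn - old);
          if (d > dmax) dmax = d;
        }
        if (dmax < 1e-9) break;
      }
      B.col(j) = beta;
      vec w12 = W11 * beta;
      for (int t = 0; t < p - 1; ++t) {
        double d = std::fabs(W(idx[t], j) - w12[t]);
        if (d > dW) dW = d;
        W(idx[t], j) = w12[t];
        W(j, idx[t]) = w12[t];
      }
    }
    if (dW < thr) break;
  }

  // recover Theta from the partitioned-inverse identities
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    uvec idx(p - 1);
    for (int i = 0, t = 0; i < p; ++i) if (i != j) idx[t++] = i;
    vec beta = B.col(j);
    vec w12(p - 1);
    for (int t = 0; t < p - 1; ++t) w12[t] = W(idx[t], j);
    double tjj = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = tjj;
    for (int t = 0; t < p - 1; ++t) Theta(idx[t], j) = -beta[t] * tjj;
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(Rcpp::Named("w") = W,
                            Rcpp::Named("theta") = Theta,
                            Rcpp::Named("iterations") = it + 1);
}

// Sum-to-zero constrained lasso:
//   min (1/2n)||y - Z b - W g||^2 + lambda ||b||_1  s.t.  1'b = 0
// ADMM split b/alpha; the (b, g) update solves a KKT system with the
// equality constraint, factored once per call.
// [[Rcpp::export]]
Rcpp::List admm_logcontrast(const arma::mat& Z, const arma::mat& W,
                            const arma::vec& y, double lambda,
                            double rho, double tol, int maxit,
                            arma::vec alpha, arma::vec u) {
  const int n = Z.n_rows, p = Z.n_cols, q = W.n_cols;
  const int d = p + q + 1;

  mat K(d, d, fill::zeros);
  K.submat(0, 0, p - 1, p - 1) = Z.t() * Z / n + rho * eye(p, p);
  if (q > 0) {
    K.submat(0, p, p - 1, p + q - 1) = Z.t() * W / n;
    K.submat(p, 0, p + q - 1, p - 1) = W.t() * Z / n;
    K.submat(p, p, p + q - 1, p + q - 1) = W.t() * W / n;
  }
  for (int k = 0; k < p; ++k) { K(d - 1, k) = 1.0; K(k, d - 1) = 1.0; }

  mat Kinv;
  if (!inv(Kinv, K))
    Rcpp::stop("KKT system is singular (rank-deficient covariate design?)");

  vec c1 = Z.t() * y / n;
  vec c2 = (q > 0) ? vec(W.t() * y / n) : vec();
  vec b(d, fill::zeros);
  vec beta(p, fill::zeros), gamma(q, fill::zeros);

  int it = 0;
  for (; it < maxit; ++it) {
    b.head(p) = c1 + rho * (alpha - u);
    if (q > 0) b.subvec(p, p + q - 1) = c2;
    b[d - 1] = 0.0;
    vec x = Kinv * b;
    beta = x.head(p);
    if (q > 0) gamma = x.subvec(p, p + q - 1);

    vec alphaOld = alpha;
    vec bu = beta + u;
    for (int k = 0; k < p; ++k) alpha[k] = soft(bu[k], lambda / rho);
    u += beta - alpha;

    double rp = norm(beta - alpha, 2);
    double rd = rho * norm(alpha - alphaOld, 2);
    double eps = tol * std::sqrt((double)p) * (1.0 + norm(alpha, 2));
    if (rp < eps && rd < eps) { ++it; break; }
  }

  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("gamma") = gamma,
                            Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("u") = u,
                            Rcpp::Named("iterations") = it);
}
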