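// Coordinate-descent elastic net on the objective
//   RSS(beta0, beta) + lambda * ( alpha*||beta||_1 + (1-alpha)/2*||beta||_2^2 )
// X is expected pre-centered (and usually standardized) and y pre-centered,
// so no intercept appears here; the R wrapper handles scaling and intercepts.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft_threshold(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// One full coordinate pass; returns max absolute coefficient change.
static double cd_pass(const arma::mat& X, arma::vec& r, arma::vec& beta,
                      const arma::vec& xnorm2, double lam_a, double lam_b,
                      const arma::uvec& idx) {
  double maxdel = 0.0;
  for (arma::uword k = 0; k < idx.n_elem; ++k) {
    arma::uword j = idx[k];
    if (xnorm2[j] <= 0.0) { beta[j] = 0.0; continue; }
    double bj = beta[j];
    // gradient of RSS wrt beta_j at beta with j-th contribution removed
    double z = 2.0 * arma::dot(X.col(j), r) + 2.0 * xnorm2[j] * bj;
    double bnew = soft_threshold(z, lam_a) / (2.0 * xnorm2[j] + lam_b);
    double del = bnew - bj;
    if (del != 0.0) {
      r -= del * X.col(j);
      beta[j] = bnew;
      double ad = std::fabs(del);
      if (ad > maxdel) maxdel = ad;
    }
  }
  return maxdel;
}

// Solve the elastic net along a (descending) lambda sequence with warm starts.
// Returns p x nlambda coefficient matrix on the scale of the supplied X.
// [[Rcpp::export]]
arma::mat cd_enet_path(const arma::mat& X, const arma::vec& y,
                       const arma::vec& lambda, double alpha,
                       double tol, int max_iter) {
  const arma::uword p = X.n_cols, nl = lambda.n_elem;
  arma::vec xnorm2(p);
  for (arma::uword j = 0; j < p; ++j) xnorm2[j] = arma::dot(X.col(j), X.col(j));
  arma::uvec all_idx = arma::regspace<arma::uvec>(0, p - 1);

  arma::mat out(p, nl, arma::fill::zeros);
  arma::vec beta(p, arma::fill::zeros);
  arma::vec r = y;

  for (arma::uword l = 0; l < nl; ++l) {
    double lam_a = lambda[l] * alpha;           // l1 part (on 2*grad scale)
    double lam_b = lambda[l] * (1.0 - alpha);   // l2 part
    int it = 0;
    for (; it < max_iter; ++it) {
      double d = cd_pass(X, r, beta, xnorm2, lam_a, lam_b, all_idx);
      if (d < tol) break;
      // inner iterations restricted to the active set until stable
      arma::uvec act = arma::find(beta != 0.0);
      while (act.n_elem > 0) {
        double da = cd_pass(X, r, beta, xnorm2, lam_a, lam_b, act);
        ++it;
        if (da < tol || it >= max_iter) break;
      }
    }
    out.col(l) = beta;
  }
  return out;
}

// Same path solve with covariance updating: the gradient 2*(X'y - X'X b)
// is maintained across coordinate updates, so passes over inactive
// coordinates cost O(1) each. Used for all path/CV work; inputs are the
// cross-product matrices of the (centered, scaled) problem.
// [[Rcpp::export]]
arma::mat cd_enet_cov(const arma::mat& XtX, const arma::vec& Xty,
                      const arma::vec& lambda, double alpha,
                      double tol, int max_iter) {
  const arma::uword p = XtX.n_cols, nl = lambda.n_elem;
  arma::mat out(p, nl, arma::fill::zeros);
  arma::vec beta(p, arma::fill::zeros);
  arma::vec diag = XtX.diag();
  arma::vec grad = 2.0 * Xty;

  for (arma::uword l = 0; l < nl; ++l) {
    double lam_a = lambda[l] * alpha;
    double lam_b = lambda[l] * (1.0 - alpha);
    // refresh the gradient at each grid point to stop drift accumulating
    grad = 2.0 * (Xty - XtX * beta);
    for (int it = 0; it < max_iter; ++it) {
      double maxdel = 0.0;
      for (arma::uword j = 0; j < p; ++j) {
        if (diag[j] <= 0.0) { beta[j] = 0.0; continue; }
        double z = grad[j] + 2.0 * diag[j] * beta[j];
        double bnew = soft_threshold(z, lam_a) / (2.0 * diag[j] + lam_b);
        double del = bnew - beta[j];
        if (del != 0.0) {
          grad -= (2.0 * del) * XtX.col(j);
          beta[j] = bnew;
          double ad = std::fabs(del);
          if (ad > maxdel) maxdel = ad;
        }
      }
      if (maxdel < tol) break;
    }
    out.col(l) = beta;
  }
  return out;
}

// Max KKT (subgradient stationarity) violation of the same objective.
// For beta_j != 0:  2*x_j'r = lambda*(alpha*sign(beta_j) + (1-alpha)*beta_j)
// For beta_j == 0: |2*x_j'r| <= lambda*alpha
// [[Rcpp::export]]
double enet_kkt_violation(const arma::mat& X, const arma::vec& y,
                          const arma::vec& beta, double lambda, double alpha) {
  arma::vec r = y - X * beta;
  double worst = 0.0;
  for (arma::uword j = 0; j < X.n_cols; ++j) {
    double g = 2.0 * arma::dot(X.col(j), r);
    double v;
    if (beta[j] != 0.0) {
      double sgn = beta[j] > 0 ? 1.0 : -1.0;
      v = std::fabs(g - lambda * (alpha * sgn + (1.0 - alpha) * beta[j]));
    } else {
      v = std::max(0.0, std::fabs(g) - lambda * alpha);
    }
    if (v > worst) worst = v;
  }
  return worst;
}
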