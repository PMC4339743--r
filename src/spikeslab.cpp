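// Stochastic-search variable selection for the spike-and-slab linear model:
//   y | beta, sigma2          ~ N(X beta, sigma2 I)
//   beta_g | sigma2, gamma    ~ N(0, sigma2 * Omega_g^{-1})
//   1/sigma2                  ~ Gamma(shape = nu/2, rate = ss/2)
//   gamma_i                   ~ Bernoulli(pi_i)
// with Omega the sigma2-free part of the smoothed Fisher information,
//   Omega = (g/n) * (w * X'X + (1-w) * diag(X'X)).
// Beta and sigma2 are integrated out analytically for the gamma updates
// (single-site systematic scan); (sigma2, beta) are redrawn once per sweep.
// The Cholesky factors of the current active set are cached; both "add"
// (one-column extension) and "remove" (row deletion via a rank-one update
// of the trailing block) proposals cost O(q^2), so a sweep costs ~ p*q^2.
// The cache is refreshed from scratch once per sweep to stop fp drift.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct SSData {
  arma::mat XtX;
  arma::vec Xty;
  double yty;
  arma::mat Omega;
  double n, a0, b0;          // a0 = nu/2, b0 = ss/2
  arma::vec logit_prior;     // log(pi) - log(1-pi) per variable
};

// Cached factorization of one model state (active order = insertion order).
struct SSState {
  arma::uvec act;
  arma::mat L_V;     // chol lower of Vinv = XtX_act + Omega_act
  arma::mat L_O;     // chol lower of Omega_act
  arma::vec u;       // L_V^{-1} Xty_act
  double S;          // y'y - u'u
  double ld_V, ld_O; // log determinants
  double lm;         // cached log marginal (shared constants dropped)
};

static double state_lm(const SSData& d, const SSState& s) {
  double lp_gamma = 0.0;
  for (arma::uword k = 0; k < s.act.n_elem; ++k)
    lp_gamma += d.logit_prior[s.act[k]];
  return 0.5 * s.ld_O - 0.5 * s.ld_V -
         (d.a0 + d.n / 2.0) * std::log(d.b0 + 0.5 * s.S) + lp_gamma;
}

// full O(q^3) rebuild of the cached state for a given active set
static bool rebuild_state(const SSData& d, const arma::uvec& act,
                          SSState& s) {
  s.act = act;
  const arma::uword q = act.n_elem;
  if (q == 0) {
    s.L_V.reset(); s.L_O.reset(); s.u.reset();
    s.S = d.yty; s.ld_V = 0.0; s.ld_O = 0.0;
    s.lm = state_lm(d, s);
    return true;
  }
  arma::mat Om = d.Omega.submat(act, act);
  arma::mat Vinv = d.XtX.submat(act, act) + Om;
  if (!arma::chol(s.L_O, Om, "lower")) return false;
  if (!arma::chol(s.L_V, Vinv, "lower")) return false;
  s.ld_O = 2.0 * arma::sum(arma::log(s.L_O.diag()));
  s.ld_V = 2.0 * arma::sum(arma::log(s.L_V.diag()));
  s.u = arma::solve(arma::trimatl(s.L_V), d.Xty.elem(act));
  s.S = d.yty - arma::dot(s.u, s.u);
  if (s.S < 0.0) s.S = 0.0;
  s.lm = state_lm(d, s);
  return true;
}

// delete row/column k from a lower Cholesky factor in O((q-k)^2):
// the trailing block is rank-one-updated with the deleted column
static arma::mat chol_delete(const arma::mat& L, arma::uword k) {
  const arma::uword q = L.n_rows;
  arma::mat Lnew(q - 1, q - 1, arma::fill::zeros);
  if (k > 0) {
    Lnew.submat(0, 0, k - 1, k - 1) = L.submat(0, 0, k - 1, k - 1);
    if (q - 1 > k)
      Lnew.submat(k, 0, q - 2, k - 1) = L.submat(k + 1, 0, q - 1, k - 1);
  }
  if (q - 1 > k) {
    arma::uword m = q - 1 - k;
    arma::mat M = L.submat(k + 1, k + 1, q - 1, q - 1);
    arma::vec x = L.col(k).tail(m);
    for (arma::uword i = 0; i < m; ++i) {
      double r = std::sqrt(M(i, i) * M(i, i) + x[i] * x[i]);
      double c = r / M(i, i), sgn = x[i] / M(i, i);
      M(i, i) = r;
      for (arma::uword jj = i + 1; jj < m; ++jj) {
        M(jj, i) = (M(jj, i) + sgn * x[jj]) / c;
        x[jj] = c * x[jj] - sgn * M(jj, i);
      }
    }
    Lnew.submat(k, k, q - 2, q - 2) = M;
  }
  return Lnew;
}

// extension pieces for appending variable j to the current state
struct ExtPieces {
  arma::vec vV, vO;  // solves against the current factors
  double dV, dO;     // new diagonal entries
  double u_extra;
  double lm;         // log marginal of the extended state
};

static bool extend_lm(const SSData& d, const SSState& s, arma::uword j,
                      ExtPieces& e) {
  const arma::uword q = s.act.n_elem;
  double om_jj = d.Omega(j, j);
  double v_jj = d.XtX(j, j) + om_jj;
  double dO2, dV2;
  if (q == 0) {
    e.vV.reset(); e.vO.reset();
    dO2 = om_jj;
    dV2 = v_jj;
    if (dO2 <= 0.0 || dV2 <= 0.0) return false;
    e.u_extra = d.Xty[j] / std::sqrt(dV2);
  } else {
    arma::vec om_col(q), v_col(q);
    for (arma::uword k = 0; k < q; ++k) {
      om_col[k] = d.Omega(s.act[k], j);
      v_col[k] = d.XtX(s.act[k], j) + om_col[k];
    }
    e.vO = arma::solve(arma::trimatl(s.L_O), om_col);
    e.vV = arma::solve(arma::trimatl(s.L_V), v_col);
    dO2 = om_jj - arma::dot(e.vO, e.vO);
    dV2 = v_jj - arma::dot(e.vV, e.vV);
    if (dO2 <= 0.0 || dV2 <= 0.0) return false;
    e.u_extra = (d.Xty[j] - arma::dot(e.vV, s.u)) / std::sqrt(dV2);
  }
  e.dV = std::sqrt(dV2);
  e.dO = std::sqrt(dO2);
  double S_new = s.S - e.u_extra * e.u_extra;
  if (S_new < 0.0) S_new = 0.0;
  double lp_gamma = d.logit_prior[j];
  for (arma::uword k = 0; k < s.act.n_elem; ++k)
    lp_gamma += d.logit_prior[s.act[k]];
  e.lm = 0.5 * (s.ld_O + std::log(dO2)) - 0.5 * (s.ld_V + std::log(dV2)) -
         (d.a0 + d.n / 2.0) * std::log(d.b0 + 0.5 * S_new) + lp_gamma;
  return true;
}

static void append_factor(arma::mat& L, const arma::vec& v, double dnew) {
  const arma::uword q = L.n_rows;
  arma::mat Lnew(q + 1, q + 1, arma::fill::zeros);
  if (q > 0) {
    Lnew.submat(0, 0, q - 1, q - 1) = L;
    Lnew.row(q).head(q) = v.t();
  }
  Lnew(q, q) = dnew;
  L = Lnew;
}

// Closed-form log marginal (full constants) for an indicator vector;
// exported for enumeration oracles and the R-level log_marginal().
// [[Rcpp::export]]
double ss_log_marginal(const arma::mat& XtX, const arma::vec& Xty, double yty,
                       const arma::mat& Omega, const arma::vec& pi,
                       double nu, double ss, double n,
                       const arma::uvec& gamma) {
  SSData d;
  d.XtX = XtX; d.Xty = Xty; d.yty = yty; d.Omega = Omega;
  d.n = n; d.a0 = nu / 2.0; d.b0 = ss / 2.0;
  d.logit_prior = arma::log(pi) - arma::log(1.0 - pi);
  SSState s;
  if (!rebuild_state(d, arma::find(gamma != 0), s))
    stop("slab precision submatrix is not positive definite");
  double cons = -(n / 2.0) * std::log(2.0 * M_PI) + d.a0 * std::log(d.b0) -
                R::lgammafn(d.a0) + R::lgammafn(d.a0 + n / 2.0) +
                arma::accu(arma::log(1.0 - pi));
  return s.lm + cons;
}

// [[Rcpp::export]]
List gibbs_spikeslab_cpp(const arma::mat& X, const arma::vec& y,
                         const arma::mat& Omega, const arma::vec& pi,
                         double nu, double ss, int n_iterations, int burn_in,
                         const arma::uvec& gamma_init, bool record_beta) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  SSData d;
  d.XtX = X.t() * X;
  d.Xty = X.t() * y;
  d.yty = arma::dot(y, y);
  d.Omega = Omega;
  d.n = (double)n;
  d.a0 = nu / 2.0;
  d.b0 = ss / 2.0;
  d.logit_prior = arma::log(pi) - arma::log(1.0 - pi);

  std::vector<char> gam(p, 0);
  for (arma::uword j = 0; j < p; ++j)
    if (j < gamma_init.n_elem && gamma_init[j] != 0) gam[j] = 1;

  auto active_of = [&](void) {
    std::vector<arma::uword> v;
    for (arma::uword j = 0; j < p; ++j) if (gam[j]) v.push_back(j);
    return arma::uvec(v);
  };

  SSState s;
  if (!rebuild_state(d, active_of(), s))
    stop("initial model has a singular slab precision");

  const int D = n_iterations - burn_in;
  arma::imat gamma_draws(D, p);
  arma::mat beta_draws;
  if (record_beta) beta_draws.zeros(D, p);
  arma::vec sigma2_draws(D);

  RNGScope scope;
  for (int it = 0; it < n_iterations; ++it) {
    // refresh the cached factorization once per sweep (stops fp drift)
    if (!rebuild_state(d, s.act, s))
      stop("singular slab precision at iteration %d", it + 1);
    for (arma::uword j = 0; j < p; ++j) {
      if (!gam[j]) {
        ExtPieces e;
        if (!extend_lm(d, s, j, e)) continue;
        double pr_flip = 1.0 / (1.0 + std::exp(s.lm - e.lm));
        if (unif_rand() < pr_flip) {
          gam[j] = 1;
          const arma::uword q = s.act.n_elem;
          append_factor(s.L_V, e.vV, e.dV);
          append_factor(s.L_O, e.vO, e.dO);
          s.ld_V += 2.0 * std::log(e.dV);
          s.ld_O += 2.0 * std::log(e.dO);
          arma::vec u(q + 1);
          u.head(q) = s.u;
          u[q] = e.u_extra;
          s.u = u;
          s.S -= e.u_extra * e.u_extra;
          if (s.S < 0.0) s.S = 0.0;
          arma::uvec act(q + 1);
          act.head(q) = s.act;
          act[q] = j;
          s.act = act;
          s.lm = e.lm;
        }
      } else {
        // removal proposal: delete j from the cached factors in O(q^2)
        const arma::uword q = s.act.n_elem;
        arma::uword pos = q;
        for (arma::uword k = 0; k < q; ++k)
          if (s.act[k] == j) { pos = k; break; }
        SSState s_alt;
        s_alt.act.set_size(q - 1);
        arma::uword c = 0;
        for (arma::uword k = 0; k < q; ++k)
          if (k != pos) s_alt.act[c++] = s.act[k];
        if (q == 1) {
          s_alt.L_V.reset(); s_alt.L_O.reset(); s_alt.u.reset();
          s_alt.S = d.yty; s_alt.ld_V = 0.0; s_alt.ld_O = 0.0;
        } else {
          s_alt.L_V = chol_delete(s.L_V, pos);
          s_alt.L_O = chol_delete(s.L_O, pos);
          s_alt.ld_V = 2.0 * arma::sum(arma::log(s_alt.L_V.diag()));
          s_alt.ld_O = 2.0 * arma::sum(arma::log(s_alt.L_O.diag()));
          s_alt.u = arma::solve(arma::trimatl(s_alt.L_V),
                                d.Xty.elem(s_alt.act));
          s_alt.S = d.yty - arma::dot(s_alt.u, s_alt.u);
          if (s_alt.S < 0.0) s_alt.S = 0.0;
        }
        s_alt.lm = state_lm(d, s_alt);
        double pr_flip = 1.0 / (1.0 + std::exp(s.lm - s_alt.lm));
        if (unif_rand() < pr_flip) {
          gam[j] = 0;
          s = s_alt;
        }
      }
    }

    // joint draw of (sigma2, beta_gamma) from exact conditionals
    double shape = d.a0 + d.n / 2.0, rate = d.b0 + 0.5 * s.S;
    double prec = R::rgamma(shape, 1.0 / rate);  // R::rgamma takes scale
    double sigma2 = 1.0 / prec;
    arma::vec beta(p, arma::fill::zeros);
    if (s.act.n_elem > 0) {
      arma::vec z(s.act.n_elem);
      for (arma::uword k = 0; k < s.act.n_elem; ++k) z[k] = norm_rand();
      arma::vec btilde = arma::solve(arma::trimatu(s.L_V.t()), s.u);
      arma::vec bdraw = btilde +
        std::sqrt(sigma2) * arma::solve(arma::trimatu(s.L_V.t()), z);
      beta.elem(s.act) = bdraw;
    }

    if (it >= burn_in) {
      int row = it - burn_in;
      for (arma::uword j = 0; j < p; ++j) gamma_draws(row, j) = gam[j];
      if (record_beta) beta_draws.row(row) = beta.t();
      sigma2_draws[row] = sigma2;
    }
    if (!std::isfinite(s.lm))
      stop("non-finite log marginal likelihood at iteration %d", it + 1);
  }

  List out = List::create(_["gamma_draws"] = gamma_draws,
                          _["sigma2_draws"] = sigma2_draws);
  if (record_beta) out["beta_draws"] = beta_draws;
  return out;
}
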