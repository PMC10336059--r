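// Gibbs samplers for Gaussian random-intercept mixed models.
// All randomness goes through R's RNG (RNGScope), so set.seed() in the
// calling R code makes draws bit-reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double rinvgamma(double shape, double rate) {
  // X ~ IG(shape, rate) <=> 1/X ~ Gamma(shape, rate); R::rgamma takes scale
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// Wishart(df, Sigma) via Bartlett decomposition; df need not be integer
// (df > dim - 1).
static arma::mat rwishart(double df, const arma::mat& Sigma) {
  const int d = Sigma.n_rows;
  arma::mat L = arma::chol(Sigma, "lower");
  arma::mat A(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// Draw from N(mean, Prec^-1) given the precision matrix.
static arma::vec rmvnorm_prec(const arma::vec& b, const arma::mat& Prec) {
  // Prec = L L'; mean solves Prec m = b; draw = m + L'^{-1} z
  arma::mat L = arma::chol(Prec, "lower");
  arma::vec m = arma::solve(arma::trimatu(L.t()),
                            arma::solve(arma::trimatl(L), b));
  arma::vec z(b.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = R::norm_rand();
  return m + arma::solve(arma::trimatu(L.t()), z);
}

// Univariate Gaussian LMM: y = X beta + u[id] + e,
// u_i ~ N(0, vu), e ~ N(0, ve).
// Priors: beta ~ N(0, beta_prior_var * I); vu, ve ~ IG(nu/2, nu*V/2).
// include_random = false drops the random intercept (constrained model).
// [[Rcpp::export]]
List gibbs_uni_cpp(const arma::vec& y, const arma::mat& X,
                   const arma::ivec& id, int nid,
                   int n_iter, int burn_in, int thin,
                   double beta_prior_var, double nu, double V,
                   bool include_random) {
  RNGScope scope;
  const int n = y.n_elem, p = X.n_cols;
  const int nkeep = (n_iter - burn_in) / thin;
  arma::mat XtX = X.t() * X;

  arma::vec nobs(nid, arma::fill::zeros);
  for (int i = 0; i < n; ++i) nobs(id(i)) += 1.0;

  const double vy = arma::var(y);
  arma::vec beta(p, arma::fill::zeros);
  arma::vec u(nid, arma::fill::zeros);
  double vu = include_random ? std::max(vy / 2.0, 1e-8) : 0.0;
  double ve = std::max(vy / 2.0, 1e-8);

  arma::mat beta_keep(nkeep, p);
  arma::vec vu_keep(nkeep), ve_keep(nkeep), dev_keep(nkeep);
  arma::vec u_sum(nid, arma::fill::zeros);
  arma::vec beta_sum(p, arma::fill::zeros);
  double ve_sum = 0.0;

  int k = 0;
  for (int iter = 0; iter < n_iter; ++iter) {
    // beta | rest
    arma::vec r1 = y;
    if (include_random)
      for (int i = 0; i < n; ++i) r1(i) -= u(id(i));
    arma::mat A = XtX / ve;
    A.diag() += 1.0 / beta_prior_var;
    beta = rmvnorm_prec(X.t() * r1 / ve, A);

    arma::vec r2 = y - X * beta;

    if (include_random) {
      // u_i | rest and vu | u
      arma::vec s(nid, arma::fill::zeros);
      for (int i = 0; i < n; ++i) s(id(i)) += r2(i);
      for (int j = 0; j < nid; ++j) {
        double d = nobs(j) / ve + 1.0 / vu;
        u(j) = (s(j) / ve) / d + R::norm_rand() / std::sqrt(d);
      }
      vu = rinvgamma((nu + nid) / 2.0, (nu * V + arma::dot(u, u)) / 2.0);
    }

    arma::vec e = r2;
    if (include_random)
      for (int i = 0; i < n; ++i) e(i) -= u(id(i));
    double sse = arma::dot(e, e);
    ve = rinvgamma((nu + n) / 2.0, (nu * V + sse) / 2.0);

    double dev = n * std::log(2.0 * M_PI * ve) + sse / ve;

    if (iter >= burn_in && (iter - burn_in) % thin == 0 && k < nkeep) {
      beta_keep.row(k) = beta.t();
      vu_keep(k) = vu;
      ve_keep(k) = ve;
      dev_keep(k) = dev;
      beta_sum += beta;
      u_sum += u;
      ve_sum += ve;
      ++k;
    }
  }

  return List::create(
      _["beta"] = beta_keep, _["v_ind"] = vu_keep, _["v_e"] = ve_keep,
      _["deviance"] = dev_keep, _["beta_mean"] = beta_sum / k,
      _["u_mean"] = u_sum / k, _["ve_mean"] = ve_sum / k,
      _["n_kept"] = k);
}

// Bivariate Gaussian LMM: Y (n x 2) = X B + U[id,] + E,
// rows of U ~ N2(0, G), rows of E ~ N2(0, R).
// Priors: vec(B) ~ N(0, beta_prior_var I); G, R ~ IW(S0, df0) or, with
// constrain_cov, independent IG(nu/2, nu*V/2) diagonals (covariances == 0).
// [[Rcpp::export]]
List gibbs_biv_cpp(const arma::mat& Y, const arma::mat& X,
                   const arma::ivec& id, int nid,
                   int n_iter, int burn_in, int thin,
                   double beta_prior_var,
                   const arma::mat& S0, double df0,
                   double nu, double V,
                   bool constrain_cov) {
  RNGScope scope;
  const int n = Y.n_rows, p = X.n_cols;
  const int nkeep = (n_iter - burn_in) / thin;
  arma::mat XtX = X.t() * X;

  arma::vec nobs(nid, arma::fill::zeros);
  for (int i = 0; i < n; ++i) nobs(id(i)) += 1.0;

  arma::mat B(p, 2, arma::fill::zeros);
  arma::mat U(nid, 2, arma::fill::zeros);
  arma::mat G = arma::diagmat(arma::var(Y, 0, 0).t() / 2.0 + 1e-8);
  arma::mat Rm = G;

  arma::mat beta_keep(nkeep, 2 * p);
  arma::mat g_keep(nkeep, 3), r_keep(nkeep, 3);
  arma::vec dev_keep(nkeep);
  arma::mat B_sum(p, 2, arma::fill::zeros), U_sum(nid, 2, arma::fill::zeros);
  arma::mat R_sum(2, 2, arma::fill::zeros);

  int k = 0;
  for (int iter = 0; iter < n_iter; ++iter) {
    // closed-form 2x2 inverse of R
    double detR = Rm(0, 0) * Rm(1, 1) - Rm(0, 1) * Rm(0, 1);
    arma::mat Rinv = {{Rm(1, 1) / detR, -Rm(0, 1) / detR},
                      {-Rm(0, 1) / detR, Rm(0, 0) / detR}};

    // B | rest: vec(B) has precision Rinv (x) XtX + I/lambda
    arma::mat M = Y;
    for (int i = 0; i < n; ++i) M.row(i) -= U.row(id(i));
    arma::mat P = arma::kron(Rinv, XtX);
    P.diag() += 1.0 / beta_prior_var;
    arma::vec b = arma::vectorise(X.t() * M * Rinv);
    arma::vec vecB = rmvnorm_prec(b, P);
    B = arma::reshape(vecB, p, 2);

    arma::mat E0 = Y - X * B;

    // U | rest (2x2 algebra inlined: chol/solve per individual)
    arma::mat S(nid, 2, arma::fill::zeros);
    for (int i = 0; i < n; ++i) S.row(id(i)) += E0.row(i);
    double detG = G(0, 0) * G(1, 1) - G(0, 1) * G(0, 1);
    double gi11 = G(1, 1) / detG, gi12 = -G(0, 1) / detG,
           gi22 = G(0, 0) / detG;
    for (int j = 0; j < nid; ++j) {
      double a = nobs(j) * Rinv(0, 0) + gi11;
      double bb = nobs(j) * Rinv(0, 1) + gi12;
      double c = nobs(j) * Rinv(1, 1) + gi22;
      double r1 = Rinv(0, 0) * S(j, 0) + Rinv(0, 1) * S(j, 1);
      double r2 = Rinv(0, 1) * S(j, 0) + Rinv(1, 1) * S(j, 1);
      double det = a * c - bb * bb;
      double m1 = (c * r1 - bb * r2) / det;
      double m2 = (a * r2 - bb * r1) / det;
      double l11 = std::sqrt(a), l21 = bb / l11;
      double l22 = std::sqrt(c - l21 * l21);
      double z1 = R::norm_rand(), z2 = R::norm_rand();
      U(j, 0) = m1 + z1 / l11 - z2 * l21 / (l11 * l22);
      U(j, 1) = m2 + z2 / l22;
    }

    // G | U
    if (constrain_cov) {
      G.zeros();
      G(0, 0) = rinvgamma((nu + nid) / 2.0,
                          (nu * V + arma::dot(U.col(0), U.col(0))) / 2.0);
      G(1, 1) = rinvgamma((nu + nid) / 2.0,
                          (nu * V + arma::dot(U.col(1), U.col(1))) / 2.0);
    } else {
      arma::mat Sn = S0 + U.t() * U;
      G = arma::inv_sympd(rwishart(df0 + nid, arma::inv_sympd(Sn)));
    }

    // R | rest
    arma::mat E = E0;
    for (int i = 0; i < n; ++i) E.row(i) -= U.row(id(i));
    if (constrain_cov) {
      Rm.zeros();
      Rm(0, 0) = rinvgamma((nu + n) / 2.0,
                           (nu * V + arma::dot(E.col(0), E.col(0))) / 2.0);
      Rm(1, 1) = rinvgamma((nu + n) / 2.0,
                           (nu * V + arma::dot(E.col(1), E.col(1))) / 2.0);
    } else {
      arma::mat Sn = S0 + E.t() * E;
      Rm = arma::inv_sympd(rwishart(df0 + n, arma::inv_sympd(Sn)));
    }

    double detR2 = Rm(0, 0) * Rm(1, 1) - Rm(0, 1) * Rm(0, 1);
    arma::mat Rinv2 = {{Rm(1, 1) / detR2, -Rm(0, 1) / detR2},
                       {-Rm(0, 1) / detR2, Rm(0, 0) / detR2}};
    double dev = n * (2.0 * std::log(2.0 * M_PI) + std::log(detR2)) +
                 arma::trace(Rinv2 * (E.t() * E));

    if (iter >= burn_in && (iter - burn_in) % thin == 0 && k < nkeep) {
      beta_keep.row(k) = vecB.t();
      g_keep(k, 0) = G(0, 0); g_keep(k, 1) = G(0, 1); g_keep(k, 2) = G(1, 1);
      r_keep(k, 0) = Rm(0, 0); r_keep(k, 1) = Rm(0, 1); r_keep(k, 2) = Rm(1, 1);
      dev_keep(k) = dev;
      B_sum += B;
      U_sum += U;
      R_sum += Rm;
      ++k;
    }
  }

  return List::create(
      _["beta"] = beta_keep, _["g"] = g_keep, _["r"] = r_keep,
      _["deviance"] = dev_keep, _["beta_mean"] = B_sum / k,
      _["u_mean"] = U_sum / k, _["r_mat_mean"] = R_sum / k,
      _["n_kept"] = k);
}
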