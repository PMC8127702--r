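// Gibbs samplers for the nested paternal half-sib mixed model
//
//   y_ijkl = mu + B_i + S_j + D_k(j) + e_l(ijk)
//
// with fixed intercept + block, random sire and dam-within-sire effects, and
// conjugate inverse-Wishart priors on the sire, dam and residual covariance
// matrices.  The univariate model is the p = 1 special case (inverse-Wishart
// reduces to scaled-inverse-chi-squared).  All randomness comes from R's RNG,
// so set.seed() on the R side makes runs bitwise reproducible.
//
// Inverse-Wishart convention: S ~ IW(nu, Psi) means inv(S) ~ Wishart(nu,
// inv(Psi)); the prior "expectation matrix" V with degree of belief nu enters
// as Psi = V * nu (the usual variance-component prior parameterisation).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static mat rnorm_mat(uword r, uword c) {
  mat M(r, c);
  for (uword j = 0; j < c; ++j)
    for (uword i = 0; i < r; ++i)
      M(i, j) = R::norm_rand();
  return M;
}

// Wishart_p(df, Sigma) via Bartlett decomposition; df > p - 1 required.
static mat rwishart(double df, const mat& Sigma) {
  const uword p = Sigma.n_rows;
  mat L = chol(symmatu(Sigma), "lower");
  mat A(p, p, fill::zeros);
  for (uword i = 0; i < p; ++i)
    A(i, i) = std::sqrt(R::rchisq(df - static_cast<double>(i)));
  for (uword i = 1; i < p; ++i)
    for (uword j = 0; j < i; ++j)
      A(i, j) = R::norm_rand();
  mat LA = L * A;
  return LA * LA.t();
}

static mat riwishart(double nu, const mat& Psi) {
  return inv_sympd(symmatu(rwishart(nu, inv_sympd(symmatu(Psi)))));
}

// Draw x ~ N(mean, Cov) for a p-vector.
static vec rmvnorm_vec(const vec& mean, const mat& Cov) {
  mat L = chol(symmatu(Cov), "lower");
  vec z(mean.n_elem);
  for (uword i = 0; i < z.n_elem; ++i) z(i) = R::norm_rand();
  return mean + L * z;
}

// Sum of r_j r_j' over group effects (rows of U).
static mat crossprod_rows(const mat& U) { return U.t() * U; }

// [[Rcpp::export]]
Rcpp::List gibbs_halfsib_cpp(arma::mat Y,
                             arma::mat X,
                             arma::uvec sire,
                             arma::uvec dam,
                             arma::umat miss,
                             bool impute,
                             arma::mat priorS, double nuS,
                             arma::mat priorD, double nuD,
                             arma::mat priorE, double nuE,
                             int burn_in, int n_iter, int thin) {
  const uword n = Y.n_rows, p = Y.n_cols, q = X.n_cols;
  const uword n_sire = sire.max() + 1, n_dam = dam.max() + 1;
  const uword n_save = static_cast<uword>(n_iter / thin);

  // prior scale matrices Psi = V * nu (see header comment)
  const mat PsiS = priorS * nuS, PsiD = priorD * nuD, PsiE = priorE * nuE;

  mat XtX = X.t() * X;
  mat XtXinv = inv_sympd(symmatu(XtX));
  mat Lx = chol(symmatu(XtXinv), "lower");

  // initial values: fixed effects at OLS, random effects at zero,
  // covariances at their prior expectations
  mat B = XtXinv * (X.t() * Y);
  mat S(n_sire, p, fill::zeros), D(n_dam, p, fill::zeros);
  mat Smat = symmatu(priorS), Dmat = symmatu(priorD), Emat = symmatu(priorE);

  // per-group counts
  vec ns(n_sire, fill::zeros), nd(n_dam, fill::zeros);
  for (uword i = 0; i < n; ++i) { ns(sire(i)) += 1.0; nd(dam(i)) += 1.0; }

  // rows with missing entries (only relevant when impute = true)
  std::vector<uword> miss_rows;
  if (impute && miss.n_elem == Y.n_elem) {
    for (uword i = 0; i < n; ++i)
      if (any(miss.row(i) == 1u)) miss_rows.push_back(i);
  }

  cube Sdraws(p, p, n_save), Ddraws(p, p, n_save), Edraws(p, p, n_save);
  cube Bdraws(q, p, n_save);

  const int total = burn_in + n_iter;
  uword isave = 0;

  for (int it = 1; it <= total; ++it) {
    // --- impute missing trait values from their conditional normal ---
    if (!miss_rows.empty()) {
      mat Mu = X * B + S.rows(sire) + D.rows(dam);
      for (uword r : miss_rows) {
        uvec m = find(miss.row(r).t() == 1u), o = find(miss.row(r).t() == 0u);
        if (o.n_elem == 0) {
          vec d = rmvnorm_vec(Mu.row(r).t(), Emat);
          Y.row(r) = d.t();
        } else {
          mat Emm = Emat.submat(m, m), Emo = Emat.submat(m, o),
              Eoo = Emat.submat(o, o);
          mat K = Emo * inv_sympd(symmatu(Eoo));
          vec mu_r = Mu.row(r).t();
          vec y_r = Y.row(r).t();
          vec cond_mean = mu_r.elem(m) + K * (y_r.elem(o) - mu_r.elem(o));
          mat cond_cov = Emm - K * Emo.t();
          vec d = rmvnorm_vec(cond_mean, cond_cov);
          for (uword t = 0; t < m.n_elem; ++t) Y(r, m(t)) = d(t);
        }
      }
    }

    // --- fixed effects (flat prior): vec(B) ~ N(Bhat, XtXinv (x) E) ---
    {
      mat R = Y - S.rows(sire) - D.rows(dam);
      mat Bhat = XtXinv * (X.t() * R);
      mat Le = chol(symmatu(Emat), "lower");
      B = Bhat + Lx * rnorm_mat(q, p) * Le.t();
    }

    mat Einv = inv_sympd(symmatu(Emat));

    // --- sire effects ---
    {
      mat R = Y - X * B - D.rows(dam);
      mat rs(n_sire, p, fill::zeros);
      for (uword i = 0; i < n; ++i) rs.row(sire(i)) += R.row(i);
      mat Sinv = inv_sympd(symmatu(Smat));
      for (uword j = 0; j < n_sire; ++j) {
        mat Cov = inv_sympd(symmatu(Sinv + ns(j) * Einv));
        vec mean = Cov * (Einv * rs.row(j).t());
        S.row(j) = rmvnorm_vec(mean, Cov).t();
      }
    }

    // --- dam effects ---
    {
      mat R = Y - X * B - S.rows(sire);
      mat rd(n_dam, p, fill::zeros);
      for (uword i = 0; i < n; ++i) rd.row(dam(i)) += R.row(i);
      mat Dinv = inv_sympd(symmatu(Dmat));
      for (uword k = 0; k < n_dam; ++k) {
        mat Cov = inv_sympd(symmatu(Dinv + nd(k) * Einv));
        vec mean = Cov * (Einv * rd.row(k).t());
        D.row(k) = rmvnorm_vec(mean, Cov).t();
      }
    }

    // --- covariance matrices (conjugate inverse-Wishart updates) ---
    Smat = riwishart(nuS + static_cast<double>(n_sire), PsiS + crossprod_rows(S));
    Dmat = riwishart(nuD + static_cast<double>(n_dam), PsiD + crossprod_rows(D));
    mat Rfull = Y - X * B - S.rows(sire) - D.rows(dam);
    Emat = riwishart(nuE + static_cast<double>(n), PsiE + crossprod_rows(Rfull));

    if (it > burn_in && (it - burn_in) % thin == 0) {
      Sdraws.slice(isave) = Smat;
      Ddraws.slice(isave) = Dmat;
      Edraws.slice(isave) = Emat;
      Bdraws.slice(isave) = B;
      ++isave;
    }
  }

  return Rcpp::List::create(Rcpp::Named("S") = Sdraws,
                            Rcpp::Named("D") = Ddraws,
                            Rcpp::Named("E") = Edraws,
                            Rcpp::Named("B") = Bdraws);
}
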