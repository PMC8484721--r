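// Gibbs sampler for the multi-response phylogenetic mixed model.
//
// Observation model (long format, one virus response per row):
//   y_i = x_i' beta + u_p[sp_i, vir_i] + u_s[sp_i, vir_i] + e_i
// with vec(u_p) ~ N(0, V_p (x) A), vec(u_s) ~ N(0, V_s (x) I),
// e_i ~ N(0, v_e[vir_i]) (residual covariances across viruses fixed at 0,
// estimable only within-replicate and each replicate sees one virus).
//
// Parameter-expanded representation: u_p = W_p diag(alpha_p) with
// vec(W_p) ~ N(0, Vt_p (x) A), alpha_p ~ N(0, alpha_var I); the implied
// prior on V_p = diag(alpha_p) Vt_p diag(alpha_p) is heavy-tailed
// (multivariate-F-like) with marginal variances scaled by alpha_var.
//
// Sampling scheme per iteration:
//   (i)   joint Gaussian draw of (beta, W_p, W_s) from the mixed-model
//         equations (flat prior on beta);
//   (ii)  per-virus Gaussian draw of the working parameters alpha;
//   (iii) inverse-Wishart draws of Vt_p | W_p and Vt_s | W_s;
//   (iv)  per-virus inverse-gamma draws of the residual variances.
// All randomness comes from R's RNG, so set.seed() gives exact replay.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat chol_upper_jitter(const arma::mat& M) {
  arma::mat R;
  if (arma::chol(R, M)) return R;
  for (double jit = 1e-10; jit <= 1.0000001e-6; jit *= 10) {
    if (arma::chol(R, M + jit * arma::eye(M.n_rows, M.n_cols))) return R;
  }
  stop("Cholesky factorization failed (jitter escalated to 1e-6)");
  return R;  // not reached
}

static arma::vec rnorm_vec(arma::uword n) {
  arma::vec z(n);
  for (arma::uword i = 0; i < n; i++) z(i) = R::norm_rand();
  return z;
}

static arma::mat rnorm_mat(arma::uword r, arma::uword c) {
  arma::mat Z(r, c);
  for (arma::uword j = 0; j < c; j++)
    for (arma::uword i = 0; i < r; i++) Z(i, j) = R::norm_rand();
  return Z;
}

// Inverse-Wishart(df, S) via the Bartlett decomposition of Wishart(df, S^-1).
static arma::mat riwish(double df, const arma::mat& S) {
  const arma::uword d = S.n_rows;
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(arma::symmatu(Sinv), "lower");
  arma::mat T(d, d, arma::fill::zeros);
  for (arma::uword i = 0; i < d; i++) {
    T(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (arma::uword j = 0; j < i; j++) T(i, j) = R::norm_rand();
  }
  arma::mat LT = L * T;
  return arma::symmatu(arma::inv_sympd(arma::symmatu(LT * LT.t())));
}

// [[Rcpp::export]]
List gibbs_vpmm_cpp(const arma::vec& y, const arma::mat& X,
                    const arma::uvec& sp, const arma::uvec& vir,
                    const arma::mat& A, const arma::mat& Ainv,
                    const int d, const bool use_phylo, const bool use_species,
                    const bool sample_prior,
                    const int n_iter, const int burn_in, const int thin,
                    const double nu_p, const arma::mat& S0p,
                    const double nu_s, const arma::mat& S0s,
                    const double alpha_var,
                    const double resid_shape, const double resid_scale) {
  const arma::uword N = y.n_elem;
  const arma::uword n = A.n_rows;
  const arma::uword p = X.n_cols;
  const arma::uword off_p = p;
  const arma::uword off_s = p + (use_phylo ? n * (arma::uword)d : 0);
  const arma::uword q = off_s + (use_species ? n * (arma::uword)d : 0);

  arma::vec beta(p, arma::fill::zeros);
  arma::mat Wp(n, d, arma::fill::zeros), Ws(n, d, arma::fill::zeros);
  arma::vec alpha_p(d, arma::fill::ones), alpha_s(d, arma::fill::ones);
  arma::mat Vtp = arma::eye(d, d), Vts = arma::eye(d, d);
  arma::vec ve(d, arma::fill::ones);
  if (use_phylo) Wp = 0.1 * rnorm_mat(n, d);
  if (use_species) Ws = 0.1 * rnorm_mat(n, d);

  arma::mat L_A;  // lower Cholesky of A, only needed for prior sampling
  if (sample_prior && use_phylo) L_A = chol_upper_jitter(A).t();

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat beta_draws(std::max(n_keep, 1), p, arma::fill::zeros);
  arma::cube Vp_draws(d, d, std::max(n_keep, 1), arma::fill::zeros);
  arma::cube Vs_draws(use_species ? d : 1, use_species ? d : 1,
                      std::max(n_keep, 1), arma::fill::zeros);
  arma::mat ve_draws(std::max(n_keep, 1), d, arma::fill::zeros);
  arma::mat up_sum(n, d, arma::fill::zeros), us_sum(n, d, arma::fill::zeros);

  arma::mat M(q, q);
  arma::vec rhs(q);
  // per-row nonzero pattern of the combined design [X, Z_p, Z_s]
  std::vector<arma::uword> cid(p + 2);
  std::vector<double> cval(p + 2);

  // per-virus observation indices, fixed across iterations
  std::vector<arma::uvec> rows_v(d), sp_v(d);
  for (int v = 0; v < d; v++) {
    rows_v[v] = arma::find(vir == (arma::uword)v);
    sp_v[v] = sp.elem(rows_v[v]);
  }

  int kept = 0;
  for (int it = 1; it <= n_iter; it++) {
    if (it % 1000 == 0) checkUserInterrupt();

    // ---- (i) joint update of beta and working random effects -------------
    if (!sample_prior) {
      M.zeros();
      rhs.zeros();
      arma::mat invVtp, invVts;
      if (use_phylo) invVtp = arma::inv_sympd(arma::symmatu(Vtp));
      if (use_species) invVts = arma::inv_sympd(arma::symmatu(Vts));

      for (arma::uword i = 0; i < N; i++) {
        arma::uword m = 0;
        for (arma::uword j = 0; j < p; j++) {
          if (X(i, j) != 0.0) { cid[m] = j; cval[m] = X(i, j); m++; }
        }
        if (use_phylo) {
          cid[m] = off_p + (arma::uword)vir(i) * n + sp(i);
          cval[m] = alpha_p(vir(i));
          m++;
        }
        if (use_species) {
          cid[m] = off_s + (arma::uword)vir(i) * n + sp(i);
          cval[m] = alpha_s(vir(i));
          m++;
        }
        const double w = 1.0 / ve(vir(i));
        const double wy = w * y(i);
        for (arma::uword a = 0; a < m; a++) {
          rhs(cid[a]) += cval[a] * wy;
          for (arma::uword b = 0; b < m; b++) {
            M(cid[a], cid[b]) += cval[a] * cval[b] * w;
          }
        }
      }
      if (use_phylo) {
        for (int a = 0; a < d; a++)
          for (int b = 0; b < d; b++)
            M.submat(off_p + a * n, off_p + b * n,
                     off_p + a * n + n - 1, off_p + b * n + n - 1) +=
              invVtp(a, b) * Ainv;
      }
      if (use_species) {
        for (int a = 0; a < d; a++)
          for (int b = 0; b < d; b++)
            for (arma::uword i = 0; i < n; i++)
              M(off_s + a * n + i, off_s + b * n + i) += invVts(a, b);
      }
      arma::mat R = chol_upper_jitter(M);
      arma::vec mu = arma::solve(arma::trimatu(R),
                     arma::solve(arma::trimatl(R.t()), rhs));
      arma::vec theta = mu + arma::solve(arma::trimatu(R), rnorm_vec(q));
      beta = theta.head(p);
      if (use_phylo)
        Wp = arma::reshape(theta.subvec(off_p, off_p + n * d - 1), n, d);
      if (use_species)
        Ws = arma::reshape(theta.subvec(off_s, off_s + n * d - 1), n, d);
    } else {
      if (use_phylo) {
        arma::mat Lv = chol_upper_jitter(arma::symmatu(Vtp)).t();
        Wp = L_A * rnorm_mat(n, d) * Lv.t();
      }
      if (use_species) {
        arma::mat Lv = chol_upper_jitter(arma::symmatu(Vts)).t();
        Ws = rnorm_mat(n, d) * Lv.t();
      }
    }

    // ---- (ii) working-parameter (expansion) update -----------------------
    const int k = (use_phylo ? 1 : 0) + (use_species ? 1 : 0);
    if (k > 0) {
      if (sample_prior) {
        for (int v = 0; v < d; v++) {
          if (use_phylo) alpha_p(v) = std::sqrt(alpha_var) * R::norm_rand();
          if (use_species) alpha_s(v) = std::sqrt(alpha_var) * R::norm_rand();
        }
      } else {
        arma::vec r = y - X * beta;
        for (int v = 0; v < d; v++) {
          const arma::uvec& rows = rows_v[v];
          arma::mat G(rows.n_elem, k);
          arma::uword c = 0;
          if (use_phylo) {
            arma::vec wc = Wp.col(v);
            G.col(c) = wc.elem(sp_v[v]);
            c++;
          }
          if (use_species) {
            arma::vec wc = Ws.col(v);
            G.col(c) = wc.elem(sp_v[v]);
          }
          arma::mat P = G.t() * G / ve(v) +
                        arma::eye(k, k) / alpha_var;
          arma::vec b = G.t() * r.elem(rows) / ve(v);
          arma::mat Rk = chol_upper_jitter(arma::symmatu(P));
          arma::vec mu = arma::solve(arma::trimatu(Rk),
                         arma::solve(arma::trimatl(Rk.t()), b));
          arma::vec av = mu + arma::solve(arma::trimatu(Rk), rnorm_vec(k));
          arma::uword c2 = 0;
          if (use_phylo) { alpha_p(v) = av(c2); c2++; }
          if (use_species) { alpha_s(v) = av(c2); }
        }
      }
    }

    // ---- (iii) inner covariance updates ----------------------------------
    if (use_phylo) {
      arma::mat S = S0p + Wp.t() * Ainv * Wp;
      Vtp = riwish(nu_p + (double)n, S);
    }
    if (use_species) {
      arma::mat S = S0s + Ws.t() * Ws;
      Vts = riwish(nu_s + (double)n, S);
    }

    // ---- (iv) residual variances -----------------------------------------
    if (sample_prior) {
      for (int v = 0; v < d; v++) {
        ve(v) = 1.0 / R::rgamma(resid_shape, 1.0 / resid_scale);
      }
    } else {
      arma::vec e = y - X * beta;
      for (arma::uword i = 0; i < N; i++) {
        if (use_phylo) e(i) -= alpha_p(vir(i)) * Wp(sp(i), vir(i));
        if (use_species) e(i) -= alpha_s(vir(i)) * Ws(sp(i), vir(i));
      }
      for (int v = 0; v < d; v++) {
        const arma::uvec& rows = rows_v[v];
        const double ss = arma::dot(e.elem(rows), e.elem(rows));
        ve(v) = 1.0 / R::rgamma(resid_shape + 0.5 * rows.n_elem,
                                1.0 / (resid_scale + 0.5 * ss));
      }
    }

    if (!beta.is_finite() || !ve.is_finite()) {
      if (!sample_prior)
        stop("sampler diverged (non-finite state) at iteration %d", it);
    }

    // ---- record ----------------------------------------------------------
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      beta_draws.row(kept) = beta.t();
      arma::mat Dp = arma::diagmat(alpha_p);
      Vp_draws.slice(kept) = arma::symmatu(Dp * Vtp * Dp);
      if (use_species) {
        arma::mat Ds = arma::diagmat(alpha_s);
        Vs_draws.slice(kept) = arma::symmatu(Ds * Vts * Ds);
      }
      ve_draws.row(kept) = ve.t();
      up_sum += Wp * arma::diagmat(alpha_p);
      if (use_species) us_sum += Ws * arma::diagmat(alpha_s);
      kept++;
    }
  }

  return List::create(
    _["beta"] = beta_draws, _["Vp"] = Vp_draws,
    _["Vs"] = Vs_draws, _["ve"] = ve_draws,
    _["u_p_mean"] = up_sum / std::max(kept, 1),
    _["u_s_mean"] = us_sum / std::max(kept, 1),
    _["n_kept"] = kept);
}
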