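// Core numerics for the NIT joint model: joint log-likelihood evaluation,
// adaptive Metropolis-Hastings-within-Gibbs sampling, and conditional
// random-effect sampling for dynamic prediction.
//
// All randomness goes through R's RNG so that set.seed() in R makes every
// run bit-reproducible. Quadrature nodes, design rows and piece indices are
// precomputed in R and passed in flattened form (see prepare_joint_data()).

#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double NEGINF = -arma::datum::inf;

struct ObsBlock {
  arma::vec y;
  arma::mat X;   // n_obs x q
  arma::mat Z;   // n_obs x d
  arma::mat Zt;  // d x n_obs (transposed copy for contiguous access)
  arma::ivec off; // n+1 offsets into rows, by patient
};

struct JointData {
  int n, p, J, q, d, K;
  arma::mat omega;      // n x p
  arma::vec T;
  arma::ivec delta;
  arma::vec tt;         // -1 for no intervention
  arma::vec node_w;
  arma::ivec node_piece;
  arma::ivec node_off;  // n+1
  arma::mat Xnode, Znode;
  arma::mat Znodet;     // d x n_nodes (transposed copy)
  arma::mat Xev, Zev;   // n x q, n x d
  arma::ivec piece_ev;
  std::vector<ObsBlock> obs;
};

static JointData unpack_data(const List& data) {
  JointData D;
  D.n = as<int>(data["n"]);
  D.p = as<int>(data["p"]);
  D.J = as<int>(data["J"]);
  D.q = as<int>(data["q"]);
  D.d = as<int>(data["d"]);
  D.K = as<int>(data["K"]);
  D.omega = as<arma::mat>(data["omega"]);
  D.T = as<arma::vec>(data["T"]);
  D.delta = as<arma::ivec>(data["delta"]);
  D.tt = as<arma::vec>(data["tt"]);
  D.node_w = as<arma::vec>(data["node_w"]);
  D.node_piece = as<arma::ivec>(data["node_piece"]);
  D.node_off = as<arma::ivec>(data["node_off"]);
  D.Xnode = as<arma::mat>(data["Xnode"]);
  D.Znode = as<arma::mat>(data["Znode"]);
  D.Znodet = D.Znode.t();
  D.Xev = as<arma::mat>(data["Xev"]);
  D.Zev = as<arma::mat>(data["Zev"]);
  D.piece_ev = as<arma::ivec>(data["piece_ev"]);
  List ob = data["obs"];
  for (int j = 0; j < D.J; ++j) {
    List oj = ob[j];
    ObsBlock blk;
    blk.y = as<arma::vec>(oj["y"]);
    blk.X = as<arma::mat>(oj["X"]);
    blk.Z = as<arma::mat>(oj["Z"]);
    blk.Zt = blk.Z.t();
    blk.off = as<arma::ivec>(oj["off"]);
    D.obs.push_back(blk);
  }
  return D;
}

struct ParamState {
  arma::vec gamma;   // p
  arma::vec alpha;   // J
  arma::mat beta;    // J x q (row j = fixed effects of covariate j)
  arma::vec lambda;  // K
  arma::vec sigma2;  // J
  arma::cube Dmat;   // d x d x J
};

static ParamState unpack_params(const List& par, int p, int J, int q, int d,
                                int K) {
  ParamState s;
  s.gamma = as<arma::vec>(par["gamma"]);
  s.alpha = as<arma::vec>(par["alpha"]);
  s.beta = as<arma::mat>(par["beta"]);
  s.lambda = as<arma::vec>(par["lambda"]);
  arma::vec sig = as<arma::vec>(par["sigma"]);
  s.sigma2 = sig % sig;
  s.Dmat.set_size(d, d, J);
  List Dl = par["D"];
  for (int j = 0; j < J; ++j) s.Dmat.slice(j) = as<arma::mat>(Dl[j]);
  if ((int)s.gamma.n_elem != p || (int)s.alpha.n_elem != J ||
      (int)s.beta.n_rows != J || (int)s.beta.n_cols != q ||
      (int)s.lambda.n_elem != K)
    stop("parameter dimensions do not match data");
  return s;
}

// survival log-likelihood contribution of one patient given caches
static inline double surv_one(const JointData& D, int i,
                              const arma::vec& lambda, double eta0i,
                              const arma::vec& anode, double aevi) {
  double H = 0.0;
  for (int k = D.node_off[i]; k < D.node_off[i + 1]; ++k) {
    double lp = lambda[D.node_piece[k]] + eta0i + anode[k];
    if (lp > 700.0) return NEGINF;
    H += D.node_w[k] * std::exp(lp);
  }
  double lh = lambda[D.piece_ev[i]] + eta0i + aevi;
  double out = D.delta[i] * lh - H;
  return std::isnan(out) ? NEGINF : out;
}

static arma::vec rnormv(int k) {
  arma::vec v(k);
  for (int i = 0; i < k; ++i) v[i] = norm_rand();
  return v;
}

// [[Rcpp::export(name = ".cpp_joint_loglik")]]
List cpp_joint_loglik(List data, List par, arma::cube b) {
  // b: d x n x J cube of random effects
  JointData D = unpack_data(data);
  ParamState s = unpack_params(par, D.p, D.J, D.q, D.d, D.K);
  double ll_long = 0.0, ll_surv = 0.0, ll_prior = 0.0;

  arma::vec eta0 = D.p ? arma::vec(D.omega * s.gamma)
                       : arma::vec(D.n, arma::fill::zeros);
  // longitudinal + random-effect prior
  for (int j = 0; j < D.J; ++j) {
    const ObsBlock& ob = D.obs[j];
    arma::mat Dj = s.Dmat.slice(j);
    arma::mat Dinv = arma::inv_sympd(Dj);
    double ldet = arma::log_det_sympd(Dj);
    double s2 = s.sigma2[j];
    for (int i = 0; i < D.n; ++i) {
      arma::vec bij = b.slice(j).col(i);
      for (int r = ob.off[i]; r < ob.off[i + 1]; ++r) {
        double mu = arma::dot(ob.X.row(r), s.beta.row(j)) +
          arma::dot(ob.Z.row(r), bij);
        double e = ob.y[r] - mu;
        ll_long += -0.5 * (std::log(2.0 * M_PI * s2) + e * e / s2);
      }
      ll_prior += -0.5 * (D.d * std::log(2.0 * M_PI) + ldet +
                          arma::as_scalar(bij.t() * Dinv * bij));
    }
  }
  // survival
  for (int i = 0; i < D.n; ++i) {
    double H = 0.0;
    for (int k = D.node_off[i]; k < D.node_off[i + 1]; ++k) {
      double a = 0.0;
      for (int j = 0; j < D.J; ++j)
        a += s.alpha[j] * (arma::dot(D.Xnode.row(k), s.beta.row(j)) +
                           arma::dot(D.Znode.row(k), b.slice(j).col(i)));
      H += D.node_w[k] * std::exp(s.lambda[D.node_piece[k]] + eta0[i] + a);
    }
    double aev = 0.0;
    for (int j = 0; j < D.J; ++j)
      aev += s.alpha[j] * (arma::dot(D.Xev.row(i), s.beta.row(j)) +
                           arma::dot(D.Zev.row(i), b.slice(j).col(i)));
    ll_surv += D.delta[i] * (s.lambda[D.piece_ev[i]] + eta0[i] + aev) - H;
  }
  return List::create(_["total"] = ll_long + ll_surv + ll_prior,
                      _["longitudinal"] = ll_long,
                      _["survival"] = ll_surv,
                      _["ranef_prior"] = ll_prior);
}

// Marginal Gaussian negative log-likelihood of a linear mixed model,
// patient by patient: V_i = Z_i D Z_i' + sigma^2 I. When `beta0` is empty
// the fixed effects are profiled out by generalized least squares.
// theta = (log-Cholesky of D, log sigma).
// [[Rcpp::export(name = ".cpp_lmm_nll")]]
List cpp_lmm_nll(arma::vec theta, arma::vec y, arma::mat X, arma::mat Z,
                 arma::ivec off, arma::vec beta0) {
  const int q = X.n_cols, d = Z.n_cols, n = off.n_elem - 1;
  arma::mat L(d, d, arma::fill::zeros);
  int pos = 0;
  for (int c = 0; c < d; ++c) L(c, c) = std::exp(theta[pos++]);
  for (int c = 0; c < d; ++c)
    for (int r = c + 1; r < d; ++r) L(r, c) = theta[pos++];
  arma::mat Dm = L * L.t();
  double sigma2 = std::exp(2.0 * theta[theta.n_elem - 1]);

  arma::mat XtVX(q, q, arma::fill::zeros);
  arma::vec XtVy(q, arma::fill::zeros);
  double ytVy = 0.0, logdet = 0.0;
  int N = y.n_elem;
  try {
  for (int i = 0; i < n; ++i) {
    int r0 = off[i], r1 = off[i + 1];
    if (r1 <= r0) continue;
    arma::mat Zi = Z.rows(r0, r1 - 1);
    arma::mat Xi = X.rows(r0, r1 - 1);
    arma::vec yi = y.subvec(r0, r1 - 1);
    arma::mat V = Zi * Dm * Zi.t();
    V = 0.5 * (V + V.t());
    V.diag() += sigma2;
    arma::mat R;
    if (!arma::chol(R, V)) {
      return List::create(_["nll"] = 1e10, _["beta"] = arma::vec(q),
                          _["ok"] = false);
    }
    logdet += 2.0 * arma::accu(arma::log(R.diag()));
    arma::mat Xs = arma::solve(arma::trimatl(R.t()), Xi);
    arma::vec ys = arma::solve(arma::trimatl(R.t()), yi);
    XtVX += Xs.t() * Xs;
    XtVy += Xs.t() * ys;
    ytVy += arma::dot(ys, ys);
  }
  arma::vec beta;
  if (beta0.n_elem == (unsigned)q) {
    beta = beta0;
  } else if (!arma::solve(beta, XtVX, XtVy, arma::solve_opts::no_approx)) {
    return List::create(_["nll"] = 1e10, _["beta"] = arma::vec(q),
                        _["ok"] = false);
  }
  double rss = ytVy - 2.0 * arma::dot(beta, XtVy) +
    arma::as_scalar(beta.t() * XtVX * beta);
  double nll = 0.5 * (N * std::log(2.0 * M_PI) + logdet + rss);
  if (std::isnan(nll)) nll = 1e10;
  return List::create(_["nll"] = nll, _["beta"] = beta, _["ok"] = true);
  } catch (...) {
    return List::create(_["nll"] = 1e10, _["beta"] = arma::vec(q),
                        _["ok"] = false);
  }
}

// Robbins-Monro adaptation of a log proposal scale (warmup only).
static inline void adapt_scale(double& ls, bool acc, double target,
                               int sweep) {
  double g = std::min(0.25, 3.0 / std::sqrt((double)(sweep + 1)));
  ls += g * ((acc ? 1.0 : 0.0) - target);
  if (ls < -12.0) ls = -12.0;
  if (ls > 6.0) ls = 6.0;
}

// Draw from inverse-Wishart(df, Psi) via Bartlett; returns D and fills Dinv.
static arma::mat riwish(double df, const arma::mat& Psi, arma::mat& Dinv) {
  int d = Psi.n_rows;
  arma::mat Psiinv = arma::inv_sympd(Psi);
  arma::mat Lw = arma::chol(Psiinv, "lower");
  arma::mat A(d, d, arma::fill::zeros);
  for (int r = 0; r < d; ++r) {
    A(r, r) = std::sqrt(R::rchisq(df - r));
    for (int c = 0; c < r; ++c) A(r, c) = norm_rand();
  }
  arma::mat LA = Lw * A;
  Dinv = LA * LA.t();
  return arma::inv_sympd(Dinv);
}

// [[Rcpp::export(name = ".cpp_run_mcmc")]]
List cpp_run_mcmc(List data, List priors, List init, int n_iter, int n_warmup,
                  int thin, int b_thin, bool store_b) {
  JointData D = unpack_data(data);
  const int n = D.n, p = D.p, J = D.J, q = D.q, d = D.d, K = D.K;

  // priors
  arma::vec pg_m = as<arma::vec>(priors["gamma_mean"]);
  arma::vec pg_s = as<arma::vec>(priors["gamma_sd"]);
  arma::vec pa_m = as<arma::vec>(priors["alpha_mean"]);
  arma::vec pa_s = as<arma::vec>(priors["alpha_sd"]);
  arma::mat pb_m = as<arma::mat>(priors["beta_mean"]); // J x q
  arma::mat pb_s = as<arma::mat>(priors["beta_sd"]);
  arma::vec pl_m = as<arma::vec>(priors["lambda_mean"]);
  arma::vec pl_s = as<arma::vec>(priors["lambda_sd"]);
  arma::vec ps_a = as<arma::vec>(priors["sigma2_a"]);
  arma::vec ps_b = as<arma::vec>(priors["sigma2_b"]);
  arma::vec pD_nu = as<arma::vec>(priors["D_nu"]);
  arma::cube pD_S = as<arma::cube>(priors["D_S"]); // d x d x J

  // state
  ParamState s = unpack_params(init, p, J, q, d, K);
  std::vector<arma::mat> b(J);
  for (int j = 0; j < J; ++j) b[j] = arma::mat(d, n, arma::fill::zeros);

  // caches
  arma::vec eta0 = p ? arma::vec(D.omega * s.gamma)
                     : arma::vec(n, arma::fill::zeros);
  int n_nodes = D.node_w.n_elem;
  arma::mat Mnode(n_nodes, J), Mev(n, J);
  std::vector<arma::vec> resid(J);
  for (int j = 0; j < J; ++j) {
    Mnode.col(j) = D.Xnode * s.beta.row(j).t(); // b = 0 initially
    Mev.col(j) = D.Xev * s.beta.row(j).t();
    resid[j] = D.obs[j].y - D.obs[j].X * s.beta.row(j).t();
  }
  arma::vec anode = Mnode * s.alpha;
  arma::vec aev = Mev * s.alpha;
  arma::vec survll(n);
  for (int i = 0; i < n; ++i)
    survll[i] = surv_one(D, i, s.lambda, eta0[i], anode, aev[i]);
  if (!survll.is_finite())
    stop("initial survival log-likelihood is not finite; check starting values");

  std::vector<arma::mat> Dinv(J), Lch(J);
  for (int j = 0; j < J; ++j) {
    Dinv[j] = arma::inv_sympd(s.Dmat.slice(j));
    Lch[j] = arma::chol(s.Dmat.slice(j), "lower");
  }

  // proposal scales
  double ls_gamma = std::log(0.1), ls_alpha = std::log(0.1),
         ls_lambda = std::log(0.1);
  arma::vec ls_beta(J, arma::fill::value(std::log(0.1)));
  arma::vec ls_b(n, arma::fill::value(std::log(0.5)));
  double tg_vec = 0.234, tg_one = 0.44;
  arma::vec gamma_base = p ? arma::vec(arma::clamp(pg_s, 0.01, 1.0))
                           : arma::vec();
  arma::vec alpha_base(J, arma::fill::value(0.25));
  arma::mat beta_base = arma::clamp(pb_s, 0.01, 1.0);
  arma::vec lambda_base(K, arma::fill::value(0.5));

  // acceptance accounting (post-warmup)
  double acc_gamma = 0, acc_alpha = 0, acc_lambda = 0, n_post = 0;
  arma::vec acc_beta(J, arma::fill::zeros);
  double acc_b = 0;

  int n_keep = (n_iter - n_warmup + thin - 1) / thin;
  int npar = p + J + J * q + K + J + J * d * (d + 1) / 2;
  arma::mat draws(n_keep, npar);
  int n_bkeep = store_b ? (n_iter - n_warmup + b_thin - 1) / b_thin : 0;
  arma::cube bdraws(store_b ? d * J : 1, store_b ? n : 1,
                    std::max(n_bkeep, 1), arma::fill::zeros);

  arma::vec survll_p(n);
  int keep_row = 0, bkeep_row = 0;

  // workspaces for the per-patient random-effect block
  int max_nodes = 0;
  for (int i = 0; i < n; ++i)
    max_nodes = std::max(max_nodes, (int)(D.node_off[i + 1] - D.node_off[i]));
  arma::mat bprop_ws(d, J), db_ws(d, J), dM_ws(std::max(max_nodes, 1), J);
  arma::vec dan_ws(std::max(max_nodes, 1));
  std::vector<arma::vec> dres_ws(J);

  for (int it = 0; it < n_iter; ++it) {
    bool warm = it < n_warmup;

    // --- gamma block (random-walk MH on the survival likelihood) ---
    if (p > 0) {
      arma::vec prop = s.gamma + std::exp(ls_gamma) * (gamma_base % rnormv(p));
      arma::vec eta0p = D.omega * prop;
      double lp = 0.0;
      for (int i = 0; i < n; ++i) {
        survll_p[i] = surv_one(D, i, s.lambda, eta0p[i], anode, aev[i]);
        lp += survll_p[i];
      }
      double dl = lp - arma::accu(survll);
      for (int k = 0; k < p; ++k)
        dl += -0.5 * (std::pow((prop[k] - pg_m[k]) / pg_s[k], 2) -
                      std::pow((s.gamma[k] - pg_m[k]) / pg_s[k], 2));
      bool acc = std::isfinite(dl) && std::log(unif_rand()) < dl;
      if (acc) { s.gamma = prop; eta0 = eta0p; survll = survll_p; }
      if (warm) adapt_scale(ls_gamma, acc, p > 1 ? tg_vec : tg_one, it);
      else acc_gamma += acc;
    }

    // --- alpha block ---
    {
      arma::vec prop = s.alpha + std::exp(ls_alpha) * (alpha_base % rnormv(J));
      arma::vec anode_p = anode + Mnode * (prop - s.alpha);
      arma::vec aev_p = aev + Mev * (prop - s.alpha);
      double lp = 0.0;
      for (int i = 0; i < n; ++i) {
        survll_p[i] = surv_one(D, i, s.lambda, eta0[i], anode_p, aev_p[i]);
        lp += survll_p[i];
      }
      double dl = lp - arma::accu(survll);
      for (int j = 0; j < J; ++j)
        dl += -0.5 * (std::pow((prop[j] - pa_m[j]) / pa_s[j], 2) -
                      std::pow((s.alpha[j] - pa_m[j]) / pa_s[j], 2));
      bool acc = std::isfinite(dl) && std::log(unif_rand()) < dl;
      if (acc) { s.alpha = prop; anode = anode_p; aev = aev_p;
                 survll = survll_p; }
      if (warm) adapt_scale(ls_alpha, acc, J > 1 ? tg_vec : tg_one, it);
      else acc_alpha += acc;
    }

    // --- beta blocks (enter both longitudinal mean and hazard) ---
    for (int j = 0; j < J; ++j) {
      arma::vec bj = s.beta.row(j).t();
      arma::vec prop = bj + std::exp(ls_beta[j]) *
        (beta_base.row(j).t() % rnormv(q));
      arma::vec dbeta = prop - bj;
      arma::vec dFnode = D.Xnode * dbeta;
      arma::vec dFev = D.Xev * dbeta;
      arma::vec anode_p = anode + s.alpha[j] * dFnode;
      arma::vec aev_p = aev + s.alpha[j] * dFev;
      double lp = 0.0;
      for (int i = 0; i < n; ++i) {
        survll_p[i] = surv_one(D, i, s.lambda, eta0[i], anode_p, aev_p[i]);
        lp += survll_p[i];
      }
      double dl = lp - arma::accu(survll);
      arma::vec resid_p = resid[j] - D.obs[j].X * dbeta;
      dl += -0.5 * (arma::dot(resid_p, resid_p) -
                    arma::dot(resid[j], resid[j])) / s.sigma2[j];
      for (int k = 0; k < q; ++k)
        dl += -0.5 * (std::pow((prop[k] - pb_m(j, k)) / pb_s(j, k), 2) -
                      std::pow((bj[k] - pb_m(j, k)) / pb_s(j, k), 2));
      bool acc = std::isfinite(dl) && std::log(unif_rand()) < dl;
      if (acc) {
        s.beta.row(j) = prop.t();
        Mnode.col(j) += dFnode;
        Mev.col(j) += dFev;
        anode = anode_p; aev = aev_p;
        resid[j] = resid_p;
        survll = survll_p;
      }
      if (warm) adapt_scale(ls_beta[j], acc, q > 1 ? tg_vec : tg_one, it);
      else acc_beta[j] += acc;
    }

    // --- log baseline hazard block ---
    {
      arma::vec prop = s.lambda + std::exp(ls_lambda) *
        (lambda_base % rnormv(K));
      double lp = 0.0;
      for (int i = 0; i < n; ++i) {
        survll_p[i] = surv_one(D, i, prop, eta0[i], anode, aev[i]);
        lp += survll_p[i];
      }
      double dl = lp - arma::accu(survll);
      for (int k = 0; k < K; ++k)
        dl += -0.5 * (std::pow((prop[k] - pl_m[k]) / pl_s[k], 2) -
                      std::pow((s.lambda[k] - pl_m[k]) / pl_s[k], 2));
      bool acc = std::isfinite(dl) && std::log(unif_rand()) < dl;
      if (acc) { s.lambda = prop; survll = survll_p; }
      if (warm) adapt_scale(ls_lambda, acc, K > 1 ? tg_vec : tg_one, it);
      else acc_lambda += acc;
    }

    // --- residual variances: conjugate inverse-gamma Gibbs ---
    for (int j = 0; j < J; ++j) {
      double a_post = ps_a[j] + 0.5 * D.obs[j].y.n_elem;
      double b_post = ps_b[j] + 0.5 * arma::dot(resid[j], resid[j]);
      s.sigma2[j] = b_post / R::rgamma(a_post, 1.0);
    }

    // --- random-effect covariances: conjugate inverse-Wishart Gibbs ---
    for (int j = 0; j < J; ++j) {
      arma::mat Sb = pD_S.slice(j) + b[j] * b[j].t();
      Sb = 0.5 * (Sb + Sb.t());
      arma::mat Dinv_j;
      arma::mat Dj = riwish(pD_nu[j] + n, Sb, Dinv_j);
      s.Dmat.slice(j) = Dj;
      Dinv[j] = Dinv_j;
      Lch[j] = arma::chol(Dj, "lower");
    }

    // --- per-patient random effects: joint random-walk MH ---
    for (int i = 0; i < n; ++i) {
      double scale = std::exp(ls_b[i]);
      double dl = 0.0;
      for (int j = 0; j < J; ++j) {
        arma::vec cur = b[j].col(i);
        bprop_ws.col(j) = cur + scale * (Lch[j] * rnormv(d));
        db_ws.col(j) = bprop_ws.col(j) - cur;
        dl += -0.5 *
          (arma::as_scalar(bprop_ws.col(j).t() * Dinv[j] * bprop_ws.col(j)) -
           arma::as_scalar(cur.t() * Dinv[j] * cur));
      }
      // longitudinal terms of this patient
      for (int j = 0; j < J; ++j) {
        const ObsBlock& ob = D.obs[j];
        int r0 = ob.off[i], r1 = ob.off[i + 1];
        dres_ws[j].set_size(std::max(r1 - r0, 0));
        if (r1 > r0) {
          const double* dbj = db_ws.colptr(j);
          double s_new = 0.0, s_old = 0.0;
          for (int r = r0; r < r1; ++r) {
            const double* z = ob.Zt.colptr(r);
            double dr = 0.0;
            for (int c = 0; c < d; ++c) dr += z[c] * dbj[c];
            double rc = resid[j][r];
            double rn = rc - dr;
            dres_ws[j][r - r0] = rn;
            s_new += rn * rn;
            s_old += rc * rc;
          }
          dl += -0.5 * (s_new - s_old) / s.sigma2[j];
        }
      }
      // survival term with proposed random effects
      int k0 = D.node_off[i], k1 = D.node_off[i + 1];
      double H = 0.0;
      bool overflow = false;
      for (int k = k0; k < k1; ++k) {
        const double* z = D.Znodet.colptr(k);
        double da = 0.0;
        for (int j = 0; j < J; ++j) {
          const double* dbj = db_ws.colptr(j);
          double dm = 0.0;
          for (int c = 0; c < d; ++c) dm += z[c] * dbj[c];
          dM_ws(k - k0, j) = dm;
          da += s.alpha[j] * dm;
        }
        dan_ws[k - k0] = da;
        double lph = s.lambda[D.node_piece[k]] + eta0[i] + anode[k] + da;
        if (lph > 700.0) { overflow = true; break; }
        H += D.node_w[k] * std::exp(lph);
      }
      double sll_p = NEGINF, daev = 0.0;
      arma::rowvec dMev(J, arma::fill::zeros);
      if (!overflow) {
        for (int j = 0; j < J; ++j) {
          double dmev = arma::dot(D.Zev.row(i), db_ws.col(j));
          dMev[j] = dmev;
          daev += s.alpha[j] * dmev;
        }
        double lh = s.lambda[D.piece_ev[i]] + eta0[i] + aev[i] + daev;
        sll_p = D.delta[i] * lh - H;
        if (std::isnan(sll_p)) sll_p = NEGINF;
      }
      dl += sll_p - survll[i];
      bool acc = std::isfinite(dl) && std::log(unif_rand()) < dl;
      if (acc) {
        for (int j = 0; j < J; ++j) {
          const ObsBlock& ob = D.obs[j];
          int r0 = ob.off[i], r1 = ob.off[i + 1];
          if (r1 > r0) resid[j].subvec(r0, r1 - 1) = dres_ws[j];
          b[j].col(i) = bprop_ws.col(j);
        }
        for (int k = k0; k < k1; ++k) {
          anode[k] += dan_ws[k - k0];
          Mnode.row(k) += dM_ws.row(k - k0);
        }
        Mev.row(i) += dMev;
        aev[i] += daev;
        survll[i] = sll_p;
      }
      if (warm) adapt_scale(ls_b[i], acc, tg_vec, it);
      else acc_b += acc;
    }

    // --- storage ---
    if (!warm) {
      n_post += 1;
      int rel = it - n_warmup;
      if (rel % thin == 0) {
        arma::rowvec row(npar);
        int pos = 0;
        for (int k = 0; k < p; ++k) row[pos++] = s.gamma[k];
        for (int j = 0; j < J; ++j) row[pos++] = s.alpha[j];
        for (int j = 0; j < J; ++j)
          for (int k = 0; k < q; ++k) row[pos++] = s.beta(j, k);
        for (int k = 0; k < K; ++k) row[pos++] = s.lambda[k];
        for (int j = 0; j < J; ++j) row[pos++] = std::sqrt(s.sigma2[j]);
        for (int j = 0; j < J; ++j)
          for (int c = 0; c < d; ++c)
            for (int r = c; r < d; ++r) row[pos++] = s.Dmat.slice(j)(r, c);
        draws.row(keep_row++) = row;
      }
      if (store_b && rel % b_thin == 0 && bkeep_row < n_bkeep) {
        for (int j = 0; j < J; ++j)
          bdraws.slice(bkeep_row).rows(j * d, (j + 1) * d - 1) = b[j];
        ++bkeep_row;
      }
    }
  }

  double denom = std::max(n_post, 1.0);
  return List::create(
    _["draws"] = draws.rows(0, keep_row - 1),
    _["b_draws"] = bdraws,
    _["n_b_kept"] = bkeep_row,
    _["accept"] = List::create(
      _["gamma"] = acc_gamma / denom, _["alpha"] = acc_alpha / denom,
      _["beta"] = acc_beta / denom, _["lambda"] = acc_lambda / denom,
      _["b"] = acc_b / (denom * n)),
    _["scales"] = List::create(
      _["gamma"] = std::exp(ls_gamma), _["alpha"] = std::exp(ls_alpha),
      _["beta"] = arma::exp(ls_beta), _["lambda"] = std::exp(ls_lambda)));
}

// Conditional dynamic prediction: for each risk-set patient, MH sampling of
// random effects given observations up to Ts and survival past Ts, then the
// conditional event probability 1 - S(Ts+dt)/S(Ts) averaged over posterior
// draws and retained random-effect samples.
//
// `data` has the prepare_joint_data layout but with quadrature nodes over
// (0, Ts] and observations truncated at Ts; `ext` is a list (one element per
// dt) of node blocks over (Ts, Ts+dt] with fields w, piece, off, X, Z.
// [[Rcpp::export(name = ".cpp_cond_predict")]]
List cpp_cond_predict(List data, List ext, arma::mat theta, int n_burn,
                      int n_keep) {
  JointData D = unpack_data(data);
  const int n = D.n, p = D.p, J = D.J, q = D.q, d = D.d, K = D.K;
  const int L = theta.n_rows;
  const int ndt = ext.size();

  std::vector<arma::vec> ext_w(ndt);
  std::vector<arma::ivec> ext_piece(ndt), ext_off(ndt);
  std::vector<arma::mat> ext_X(ndt), ext_Zt(ndt);
  for (int e = 0; e < ndt; ++e) {
    List ee = ext[e];
    ext_w[e] = as<arma::vec>(ee["w"]);
    ext_piece[e] = as<arma::ivec>(ee["piece"]);
    ext_off[e] = as<arma::ivec>(ee["off"]);
    ext_X[e] = as<arma::mat>(ee["X"]);
    ext_Zt[e] = as<arma::mat>(ee["Z"]).t();
  }

  arma::mat pi_acc(n, ndt, arma::fill::zeros);
  double acc_total = 0.0, acc_n = 0.0;

  for (int l = 0; l < L; ++l) {
    // unpack one posterior draw
    int pos = 0;
    arma::vec gamma(p), alpha(J), lambda(K), sigma2(J);
    arma::mat beta(J, q);
    arma::cube Dm(d, d, J);
    for (int k = 0; k < p; ++k) gamma[k] = theta(l, pos++);
    for (int j = 0; j < J; ++j) alpha[j] = theta(l, pos++);
    for (int j = 0; j < J; ++j)
      for (int k = 0; k < q; ++k) beta(j, k) = theta(l, pos++);
    for (int k = 0; k < K; ++k) lambda[k] = theta(l, pos++);
    for (int j = 0; j < J; ++j) {
      double sg = theta(l, pos++);
      sigma2[j] = sg * sg;
    }
    for (int j = 0; j < J; ++j) {
      arma::mat M(d, d, arma::fill::zeros);
      for (int c = 0; c < d; ++c)
        for (int r = c; r < d; ++r) {
          M(r, c) = theta(l, pos++);
          M(c, r) = M(r, c);
        }
      Dm.slice(j) = M;
    }
    std::vector<arma::mat> Dinv(J), Lch(J);
    for (int j = 0; j < J; ++j) {
      Dinv[j] = arma::inv_sympd(Dm.slice(j));
      Lch[j] = arma::chol(Dm.slice(j), "lower");
    }
    arma::vec eta0 = p ? arma::vec(D.omega * gamma)
                       : arma::vec(n, arma::fill::zeros);

    for (int i = 0; i < n; ++i) {
      // Fixed parts per node/observation for this (draw, patient): the MH
      // steps then only touch the random-effect contributions.
      int k0 = D.node_off[i], k1 = D.node_off[i + 1];
      arma::vec node_base(std::max(k1 - k0, 0));
      for (int k = k0; k < k1; ++k) {
        double a = 0.0;
        for (int j = 0; j < J; ++j)
          a += alpha[j] * arma::dot(D.Xnode.row(k), beta.row(j));
        node_base[k - k0] = lambda[D.node_piece[k]] + eta0[i] + a;
      }
      std::vector<arma::vec> resid0(J);
      for (int j = 0; j < J; ++j) {
        const ObsBlock& ob = D.obs[j];
        int r0 = ob.off[i], r1 = ob.off[i + 1];
        resid0[j].set_size(std::max(r1 - r0, 0));
        for (int r = r0; r < r1; ++r)
          resid0[j][r - r0] = ob.y[r] - arma::dot(ob.X.row(r), beta.row(j));
      }
      std::vector<arma::vec> ebase(ndt);
      for (int e = 0; e < ndt; ++e) {
        int e0 = ext_off[e][i], e1 = ext_off[e][i + 1];
        ebase[e].set_size(std::max(e1 - e0, 0));
        for (int k = e0; k < e1; ++k) {
          double a = 0.0;
          for (int j = 0; j < J; ++j)
            a += alpha[j] * arma::dot(ext_X[e].row(k).head(q), beta.row(j));
          ebase[e][k - e0] = lambda[ext_piece[e][k]] + eta0[i] + a;
        }
      }

      auto logtarget = [&](const arma::mat& bv) { // bv: d x J
        double ll = 0.0;
        for (int j = 0; j < J; ++j) {
          ll += -0.5 * arma::as_scalar(bv.col(j).t() * Dinv[j] * bv.col(j));
          const ObsBlock& ob = D.obs[j];
          int r0 = ob.off[i], r1 = ob.off[i + 1];
          const double* bj = bv.colptr(j);
          for (int r = r0; r < r1; ++r) {
            const double* z = ob.Zt.colptr(r);
            double zb = 0.0;
            for (int c = 0; c < d; ++c) zb += z[c] * bj[c];
            double e = resid0[j][r - r0] - zb;
            ll += -0.5 * e * e / sigma2[j];
          }
        }
        double H = 0.0;
        for (int k = k0; k < k1; ++k) {
          const double* z = D.Znodet.colptr(k);
          double a = 0.0;
          for (int j = 0; j < J; ++j) {
            const double* bj = bv.colptr(j);
            double zb = 0.0;
            for (int c = 0; c < d; ++c) zb += z[c] * bj[c];
            a += alpha[j] * zb;
          }
          double lp = node_base[k - k0] + a;
          if (lp > 700.0) return NEGINF;
          H += D.node_w[k] * std::exp(lp);
        }
        double out = ll - H;
        return std::isnan(out) ? NEGINF : out;
      };
      auto ext_cumhaz = [&](int e, const arma::mat& bv) {
        double H = 0.0;
        int e0 = ext_off[e][i], e1 = ext_off[e][i + 1];
        for (int k = e0; k < e1; ++k) {
          const double* z = ext_Zt[e].colptr(k);
          double a = 0.0;
          for (int j = 0; j < J; ++j) {
            const double* bj = bv.colptr(j);
            double zb = 0.0;
            for (int c = 0; c < d; ++c) zb += z[c] * bj[c];
            a += alpha[j] * zb;
          }
          double lp = ebase[e][k - e0] + a;
          H += ext_w[e][k] * std::exp(std::min(lp, 700.0));
        }
        return H;
      };

      arma::rowvec pl(ndt, arma::fill::zeros);
      int attempts = 0;
      double ls = std::log(0.6);
      bool done = false;
      arma::mat bcur(d, J), bprop(d, J);
      while (!done) {
        bcur.zeros();
        double cur = logtarget(bcur);
        int n_acc = 0;
        pl.zeros();
        for (int m = 0; m < n_burn + n_keep; ++m) {
          double scale = std::exp(ls);
          for (int j = 0; j < J; ++j)
            bprop.col(j) = bcur.col(j) + scale * (Lch[j] * rnormv(d));
          double lp = logtarget(bprop);
          bool acc = std::isfinite(lp - cur) &&
            std::log(unif_rand()) < lp - cur;
          if (acc) { bcur = bprop; cur = lp; ++n_acc; }
          if (m < n_burn) adapt_scale(ls, acc, 0.234, m);
          else {
            for (int e = 0; e < ndt; ++e)
              pl[e] += 1.0 - std::exp(-ext_cumhaz(e, bcur));
          }
        }
        if (n_acc > 0 || d * J == 0) {
          done = true;
          acc_total += (double)n_acc / (n_burn + n_keep);
          acc_n += 1.0;
        } else if (++attempts >= 3) {
          stop("conditional random-effect sampler for patient %d accepted no proposals after %d retries",
               i + 1, attempts);
        } else {
          ls -= std::log(5.0);
        }
      }
      pi_acc.row(i) += pl / n_keep;
    }
  }
  return List::create(_["pi"] = pi_acc / L,
                      _["mean_accept"] = acc_n > 0 ? acc_total / acc_n : 1.0);
}
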