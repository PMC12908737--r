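// EM estimation for finite mixtures of linear latent growth curves with
// missing occasions. Model: y_i = Lambda eta_i + eps_i, eta_i | z_i = k ~
// N(mu_k, Psi), eps_it ~ N(0, theta_t); Psi and theta shared across classes.
// Patients are grouped by missingness pattern so the per-pattern marginal
// covariance (Lo Psi Lo' + diag(theta_o)) is factorised once per iteration.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = std::log(2.0 * M_PI);

struct Pattern {
  arma::uvec obs;   // observed occasion indices (0-based)
  arma::uvec rows;  // patient rows with this pattern (0-based)
};

static std::vector<Pattern> find_patterns(const arma::umat& M) {
  std::map<std::string, std::vector<arma::uword>> groups;
  const arma::uword n = M.n_rows, T = M.n_cols;
  for (arma::uword i = 0; i < n; ++i) {
    std::string key(T, '0');
    for (arma::uword t = 0; t < T; ++t) if (M(i, t)) key[t] = '1';
    groups[key].push_back(i);
  }
  std::vector<Pattern> out;
  out.reserve(groups.size());
  for (auto& kv : groups) {
    Pattern p;
    std::vector<arma::uword> obs;
    for (arma::uword t = 0; t < kv.first.size(); ++t)
      if (kv.first[t] == '1') obs.push_back(t);
    p.obs = arma::uvec(obs);
    p.rows = arma::uvec(kv.second);
    out.push_back(p);
  }
  return out;
}

// One EM sweep. If `do_mstep` is false only the E quantities are computed.
// Returns loglik; fills resp (n x K). On M-step, updates pi/Mu/Psi/Theta.
static double em_sweep(const arma::mat& Y, const std::vector<Pattern>& pats,
                       const arma::mat& Lambda, arma::vec& pi, arma::mat& Mu,
                       arma::mat& Psi, arma::vec& Theta, arma::mat& resp,
                       bool do_mstep, double theta_floor, bool theta_pooled,
                       const CharacterVector& ids) {
  const arma::uword n = Y.n_rows, T = Y.n_cols, K = pi.n_elem,
                    q = Lambda.n_cols;
  arma::vec logpi = arma::log(pi);
  arma::mat logd(n, K);

  // cached per-pattern factorisations for the M pass
  std::vector<arma::mat> chols(pats.size()), Gs(pats.size()), Vs(pats.size());

  for (size_t pi_ = 0; pi_ < pats.size(); ++pi_) {
    const Pattern& p = pats[pi_];
    const arma::uword m = p.obs.n_elem;
    arma::mat Lo = Lambda.rows(p.obs);
    arma::mat So = Lo * Psi * Lo.t();
    So.diag() += Theta.elem(p.obs);
    arma::mat R;
    if (!arma::chol(R, So)) {
      So.diag() += 1e-10;
      if (!arma::chol(R, So)) {
        double rc = arma::rcond(So);
        std::string id = as<std::string>(ids[p.rows(0)]);
        stop("singular observed-occasion covariance for patient '%s' "
             "(reciprocal condition number %.3e)", id.c_str(), rc);
      }
    }
    double logdet = 2.0 * arma::sum(arma::log(R.diag()));
    arma::mat LoPsi = Lo * Psi;                        // m x q
    arma::mat SoInvLoPsi = arma::solve(So, LoPsi);     // m x q
    arma::mat G = SoInvLoPsi.t();                      // q x m: Psi Lo' So^-1
    arma::mat V = Psi - G * LoPsi;                     // q x q
    arma::mat Yo = Y.submat(p.rows, p.obs);            // np x m

    chols[pi_] = R; Gs[pi_] = G; Vs[pi_] = V;

    for (arma::uword k = 0; k < K; ++k) {
      arma::rowvec muk = (Lo * Mu.row(k).t()).t();
      arma::mat Rk = Yo.each_row() - muk;              // np x m
      arma::mat Z = arma::solve(arma::trimatl(R.t()), Rk.t());
      arma::rowvec quad = arma::sum(arma::square(Z), 0);
      for (arma::uword j = 0; j < p.rows.n_elem; ++j)
        logd(p.rows(j), k) =
            -0.5 * (m * LOG2PI + logdet + quad(j));
    }
  }

  // responsibilities + loglik via log-sum-exp
  double loglik = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    arma::rowvec a = logd.row(i) + logpi.t();
    double mx = a.max();
    double lse = mx + std::log(arma::sum(arma::exp(a - mx)));
    loglik += lse;
    resp.row(i) = arma::exp(a - lse);
  }

  if (!do_mstep) return loglik;

  arma::vec Nk(K, arma::fill::zeros);
  arma::mat MuAcc(K, q, arma::fill::zeros);
  arma::cube S(q, q, K, arma::fill::zeros);
  arma::mat Vsum(q, q, arma::fill::zeros);
  arma::vec thAcc(T, arma::fill::zeros), thCnt(T, arma::fill::zeros);

  for (size_t pi_ = 0; pi_ < pats.size(); ++pi_) {
    const Pattern& p = pats[pi_];
    arma::mat Lo = Lambda.rows(p.obs);
    arma::mat Yo = Y.submat(p.rows, p.obs);
    const arma::mat& G = Gs[pi_];
    const arma::mat& V = Vs[pi_];
    const double np = static_cast<double>(p.rows.n_elem);
    arma::vec lVl = arma::diagvec(Lo * V * Lo.t());    // m

    for (arma::uword k = 0; k < K; ++k) {
      arma::rowvec muk = (Lo * Mu.row(k).t()).t();
      arma::mat Rk = Yo.each_row() - muk;
      arma::mat Mik = Rk * G.t();                      // np x q
      Mik.each_row() += Mu.row(k);
      arma::vec w = resp.submat(p.rows, arma::uvec{k});
      Nk(k) += arma::sum(w);
      MuAcc.row(k) += (w.t() * Mik);
      S.slice(k) += Mik.t() * (Mik.each_col() % w);
      arma::mat E = Yo - Mik * Lo.t();                 // np x m
      arma::vec e2 = (arma::square(E).t() * w);        // m
      for (arma::uword j = 0; j < p.obs.n_elem; ++j)
        thAcc(p.obs(j)) += e2(j) + arma::sum(w) * lVl(j);
    }
    Vsum += np * V;
    for (arma::uword j = 0; j < p.obs.n_elem; ++j) thCnt(p.obs(j)) += np;
  }

  pi = Nk / static_cast<double>(n);
  for (arma::uword k = 0; k < K; ++k) Mu.row(k) = MuAcc.row(k) / Nk(k);
  arma::mat PsiNew = Vsum;
  for (arma::uword k = 0; k < K; ++k)
    PsiNew += S.slice(k) - Nk(k) * (Mu.row(k).t() * Mu.row(k));
  PsiNew /= static_cast<double>(n);
  Psi = 0.5 * (PsiNew + PsiNew.t());
  if (theta_pooled) {
    double pooled = std::max(arma::sum(thAcc) / arma::sum(thCnt),
                             theta_floor);
    Theta.fill(pooled);
  } else {
    for (arma::uword t = 0; t < T; ++t)
      Theta(t) = thCnt(t) > 0 ? std::max(thAcc(t) / thCnt(t), theta_floor)
                              : Theta(t);
  }
  return loglik;
}

// Project a symmetric matrix onto the PSD cone; returns true if clamping
// was needed.
static bool psd_project(arma::mat& A) {
  arma::vec ev; arma::mat U;
  arma::eig_sym(ev, U, A);
  if (ev.min() >= 0.0) return false;
  ev.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  A = U * arma::diagmat(ev) * U.t();
  A = 0.5 * (A + A.t());
  return true;
}

// [[Rcpp::export(name = ".gmm_em_cpp")]]
List gmm_em_cpp(const arma::mat& Y, const arma::umat& M,
                const arma::mat& Lambda, arma::vec pi, arma::mat Mu,
                arma::mat Psi, arma::vec Theta, int max_iter, double tol,
                double theta_floor, double pi_floor, bool theta_pooled,
                CharacterVector ids) {
  const arma::uword n = Y.n_rows, K = pi.n_elem;
  std::vector<Pattern> pats = find_patterns(M);
  arma::mat resp(n, K);
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  double ll_prev = -arma::datum::inf, ll = -arma::datum::inf;
  bool converged = false, hit_theta = false, hit_psi = false,
       empty_class = false, mono_warn = false;

  int it = 0;
  for (;; ++it) {
    bool last = (it >= max_iter);
    ll = em_sweep(Y, pats, Lambda, pi, Mu, Psi, Theta, resp, !last,
                  theta_floor, theta_pooled, ids);
    trace.push_back(ll);
    if (it > 0) {
      if (ll < ll_prev - 1e-8) mono_warn = true;
      double rel = std::fabs(ll - ll_prev) / (std::fabs(ll_prev) + 1.0);
      if (rel < tol) {
        converged = true;
        if (!last) {
          // parameters were just updated past the converged E-step; one
          // final E-only pass keeps loglik/resp consistent with them
          ll = em_sweep(Y, pats, Lambda, pi, Mu, Psi, Theta, resp, false,
                        theta_floor, theta_pooled, ids);
          trace.push_back(ll);
        }
        break;
      }
    }
    if (last) break;
    ll_prev = ll;
    // post-M hygiene
    if (Theta.min() <= theta_floor * (1.0 + 1e-12)) hit_theta = true;
    if (psd_project(Psi)) hit_psi = true;
    if (pi.min() < pi_floor) {
      empty_class = true;
      pi.transform([pi_floor](double v) { return std::max(v, pi_floor); });
      pi /= arma::sum(pi);
    }
  }

  CharacterVector flags;
  if (hit_theta) flags.push_back("residual-variance-floor");
  if (hit_psi) flags.push_back("nonpositive-definite-growth-covariance");
  if (empty_class) flags.push_back("empty-class");
  if (mono_warn) flags.push_back("loglik-decrease");

  return List::create(
      _["pi"] = pi, _["mu"] = Mu, _["psi"] = Psi, _["theta"] = Theta,
      _["resp"] = resp, _["loglik"] = ll, _["trace"] = arma::vec(trace),
      _["n_iter"] = it, _["converged"] = converged, _["flags"] = flags);
}
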