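// Observed-data likelihood for the latent-probit serial mediation system.
//
// Structural model per offspring (group-specific):
//   M1* = eta + e1,            e1 ~ N(0, 1), eta = alpha' x4,  M1 = 1{M1* > 0}
//   M2  = nu  + d M1* + e2,    e2 ~ N(0, sigma2^2)
//   Y_k = kap_k + b1k M1* + b2k M2 + e_k,  e ~ N_K(0, Sigma)
// Internally the mean structure is held in reduced form: the observed block
// w = (M2, Y) has mean linear in the designs (x4 for M2; x6 for Y) and a
// covariance Omega = lam lam' + sigma2^2 psi psi' + J Sigma J' where
// lam = (d, b1k + b2k d) are loadings on e1 and psi = (1, b2k) on e2.
// Marginalising e1 exactly gives
//   log p(row) = log N(w; mu, Omega) + log Phi(t (eta + lam'Omega^-1 r)/s),
// with r = w - mu, s^2 = 1 - lam'Omega^-1 lam, t = 2 M1 - 1.
//
// Parameter vector theta (reduced form), K outcomes:
//   alpha (4) | piM2 (4) | piY_k (6 each) | d | b1 (K) | b2 (K) |
//   log sigma2 | chol(Sigma): K=1 -> log sd ; K=2 -> log L11, L21, log L22.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Unpacked {
  arma::vec alpha;      // 4
  arma::vec piM2;       // 4
  arma::mat piY;        // 6 x K
  double d;
  arma::vec b1, b2;     // K
  double lsig2;
  arma::vec chol_par;   // 1 or 3
  int K;
};

static Unpacked unpack(const arma::vec& th, int K) {
  Unpacked u; u.K = K;
  int p = 0;
  u.alpha = th.subvec(p, p + 3); p += 4;
  u.piM2  = th.subvec(p, p + 3); p += 4;
  u.piY.set_size(6, K);
  for (int k = 0; k < K; ++k) { u.piY.col(k) = th.subvec(p, p + 5); p += 6; }
  u.d = th(p++);
  u.b1 = th.subvec(p, p + K - 1); p += K;
  u.b2 = th.subvec(p, p + K - 1); p += K;
  u.lsig2 = th(p++);
  int nc = (K == 1) ? 1 : 3;
  u.chol_par = th.subvec(p, p + nc - 1); p += nc;
  return u;
}

// Builds Omega, loadings, Sigma chol L from unpacked params.
struct CovParts {
  arma::vec lam, psi;    // K+1
  arma::mat L;           // K x K lower chol of Sigma
  arma::mat Omega, Oinv;
  double sig2, logdetO, s2, s;
  arma::vec v;           // Oinv * lam
  bool ok;
};

static CovParts build_cov(const Unpacked& u) {
  CovParts c; c.ok = true;
  int K = u.K, M = K + 1;
  c.sig2 = std::exp(u.lsig2);
  c.lam.set_size(M); c.psi.set_size(M);
  c.lam(0) = u.d; c.psi(0) = 1.0;
  for (int k = 0; k < K; ++k) {
    c.lam(k + 1) = u.b1(k) + u.b2(k) * u.d;
    c.psi(k + 1) = u.b2(k);
  }
  c.L.zeros(K, K);
  if (K == 1) {
    c.L(0, 0) = std::exp(u.chol_par(0));
  } else {
    c.L(0, 0) = std::exp(u.chol_par(0));
    c.L(1, 0) = u.chol_par(1);
    c.L(1, 1) = std::exp(u.chol_par(2));
  }
  arma::mat Sig = c.L * c.L.t();
  c.Omega = c.lam * c.lam.t() + (c.sig2 * c.sig2) * (c.psi * c.psi.t());
  c.Omega.submat(1, 1, K, K) += Sig;
  arma::mat Oinv;
  if (!arma::inv_sympd(Oinv, c.Omega)) { c.ok = false; return c; }
  c.Oinv = Oinv;
  double sign;
  arma::log_det(c.logdetO, sign, c.Omega);
  if (sign <= 0) { c.ok = false; return c; }
  c.v = c.Oinv * c.lam;
  c.s2 = 1.0 - arma::dot(c.lam, c.v);
  if (c.s2 <= 1e-12) { c.ok = false; return c; }
  c.s = std::sqrt(c.s2);
  return c;
}

static const double BIG = 1e10;
static const double LOG_SQRT_2PI = 0.9189385332046727;

// log Phi(x) via erfc, falling back to R's tail-accurate pnorm when the
// erfc path underflows
static inline double log_phi_cdf(double x) {
  double p = 0.5 * std::erfc(-x * M_SQRT1_2);
  if (p > 1e-290) return std::log(p);
  return R::pnorm(x, 0.0, 1.0, 1, 1);
}

// Core evaluation on pre-subset data. If grad != nullptr, fills analytic
// gradient of the *negative* log-likelihood.
static double eval_core(const arma::vec& th, int K,
                        const arma::mat& X4s, const arma::mat& X6s,
                        const arma::ivec& m1s, const arma::mat& Ws,
                        arma::vec* grad) {
  const Unpacked u = unpack(th, K);
  const CovParts c = build_cov(u);
  const int M = K + 1;
  const int n = Ws.n_rows;
  if (!c.ok) { if (grad) grad->zeros(th.n_elem); return BIG; }

  arma::mat MU(n, M);
  MU.col(0) = X4s * u.piM2;
  for (int k = 0; k < K; ++k) MU.col(k + 1) = X6s * u.piY.col(k);
  arma::mat R = Ws - MU;
  arma::mat Q = R * c.Oinv;                       // rows are q_i'
  arma::vec quad = arma::sum(Q % R, 1);
  arma::vec eta = X4s * u.alpha;
  arma::vec z = (eta + Q * c.lam) / c.s;

  double ll = -0.5 * n * (M * std::log(2.0 * M_PI) + c.logdetO)
              - 0.5 * arma::accu(quad);
  arma::vec G(n);
  for (int i = 0; i < n; ++i) {
    double t = m1s(i) == 1 ? 1.0 : -1.0;
    double lp = log_phi_cdf(t * z(i));
    double ld = -0.5 * z(i) * z(i) - LOG_SQRT_2PI;
    ll += lp;
    G(i) = t * std::exp(ld - lp);
  }
  if (!std::isfinite(ll)) { if (grad) grad->zeros(th.n_elem); return BIG; }
  if (!grad) return -ll;

  // ---- analytic gradient (of loglik; negated at the end) ----
  arma::vec g(th.n_elem, arma::fill::zeros);
  int p = 0;
  // alpha: dl/dalpha = X4' G / s
  g.subvec(p, p + 3) = X4s.t() * G / c.s; p += 4;
  // mean params: dl/dmu_i = q_i - (G_i/s) v
  arma::mat A = Q - (G / c.s) * c.v.t();
  g.subvec(p, p + 3) = X4s.t() * A.col(0); p += 4;
  for (int k = 0; k < K; ++k) { g.subvec(p, p + 5) = X6s.t() * A.col(k + 1); p += 6; }

  // accumulators for covariance-parameter derivatives
  arma::mat Sqq = Q.t() * Q;
  arma::vec SGq = Q.t() * G;
  double SGz = arma::dot(G, z);

  // assemble d/dxi for each covariance-side parameter
  const int n_xi = 1 + 2 * K + 1 + ((K == 1) ? 1 : 3);
  for (int j = 0; j < n_xi; ++j) {
    arma::mat dO(M, M, arma::fill::zeros);
    arma::vec dlam(M, arma::fill::zeros);
    if (j == 0) {                                  // d
      dlam = c.psi;                                // dlam/dd = (1, b2k)
      dO = c.psi * c.lam.t() + c.lam * c.psi.t();
    } else if (j <= K) {                           // b1k
      int k = j - 1;
      dlam(k + 1) = 1.0;
      dO = dlam * c.lam.t() + c.lam * dlam.t();
    } else if (j <= 2 * K) {                       // b2k
      int k = j - K - 1;
      dlam(k + 1) = u.d;
      arma::vec dpsi(M, arma::fill::zeros); dpsi(k + 1) = 1.0;
      dO = dlam * c.lam.t() + c.lam * dlam.t()
         + (c.sig2 * c.sig2) * (dpsi * c.psi.t() + c.psi * dpsi.t());
    } else if (j == 2 * K + 1) {                   // log sigma2
      dO = 2.0 * (c.sig2 * c.sig2) * (c.psi * c.psi.t());
    } else {                                       // chol(Sigma) params
      int jc = j - (2 * K + 2);
      arma::mat dL(K, K, arma::fill::zeros);
      if (K == 1) {
        dL(0, 0) = c.L(0, 0);
      } else {
        if (jc == 0) dL(0, 0) = c.L(0, 0);
        else if (jc == 1) dL(1, 0) = 1.0;
        else dL(1, 1) = c.L(1, 1);
      }
      arma::mat dSig = dL * c.L.t() + c.L * dL.t();
      dO.submat(1, 1, K, K) = dSig;
    }
    double tr_data = arma::accu(Sqq % dO);
    double tr_O = arma::accu(c.Oinv % dO);
    double term_gauss = 0.5 * (tr_data - n * tr_O);
    arma::vec dOSGq = dO * SGq;
    double ds2 = -(2.0 * arma::dot(c.v, dlam) - arma::as_scalar(c.v.t() * dO * c.v));
    // dz = (dlam'q - v'dO q)/s - z * ds/s, with ds = ds2/(2 s)
    double term_probit = (arma::dot(dlam, SGq) - arma::dot(c.v, dOSGq)) / c.s
                         - (SGz / (2.0 * c.s2)) * ds2;
    g(p + j) = term_gauss + term_probit;
  }
  *grad = -g;
  return -ll;
}

// subset helper (R passes 1-based row indices)
struct SubData {
  arma::mat X4, X6, W;
  arma::ivec m1;
  SubData(const arma::mat& X4f, const arma::mat& X6f, const arma::ivec& m1f,
          const arma::mat& Wf, const arma::uvec& idx)
    : X4(X4f.rows(idx)), X6(X6f.rows(idx)), W(Wf.rows(idx)),
      m1(idx.n_elem) {
    for (unsigned int i = 0; i < idx.n_elem; ++i) m1(i) = m1f(idx(i));
  }
};

// [[Rcpp::export(name = ".cpp_negloglik")]]
double cpp_negloglik(const arma::vec& theta, int K,
                     const arma::mat& X4, const arma::mat& X6,
                     const arma::ivec& m1, const arma::mat& W,
                     const arma::uvec& rows1) {
  SubData d(X4, X6, m1, W, rows1 - 1);
  return eval_core(theta, K, d.X4, d.X6, d.m1, d.W, nullptr);
}

// [[Rcpp::export(name = ".cpp_negloglik_grad")]]
List cpp_negloglik_grad(const arma::vec& theta, int K,
                        const arma::mat& X4, const arma::mat& X6,
                        const arma::ivec& m1, const arma::mat& W,
                        const arma::uvec& rows1) {
  SubData d(X4, X6, m1, W, rows1 - 1);
  arma::vec gr;
  double v = eval_core(theta, K, d.X4, d.X6, d.m1, d.W, &gr);
  return List::create(_["value"] = v, _["gradient"] = gr);
}

// Minimal BFGS with Armijo backtracking; parameters are expected to be on
// a standardized scale so an identity initial inverse Hessian is adequate.
// H0 (optional) preconditions warm-started refits with the inverse-Hessian
// approximation of a previous fit on comparable data.
struct FitOut {
  arma::vec theta; double value; bool converged; int iter; double gnorm;
  arma::mat H;
};

static FitOut bfgs_fit(arma::vec th, int K, const SubData& d,
                       int maxit, double tol_ll, double tol_g,
                       const arma::mat* H0 = nullptr) {
  const int P = th.n_elem;
  arma::mat H = H0 ? *H0 : arma::eye(P, P);
  arma::vec gr(P);
  double f = eval_core(th, K, d.X4, d.X6, d.m1, d.W, &gr);
  bool conv = false;
  int it = 0;
  for (; it < maxit; ++it) {
    // gradient tolerance is relative to the objective's magnitude so the
    // criterion is attainable in double precision for any sample size
    double tol_g_eff = tol_g * std::max(1.0, std::fabs(f));
    double gn = arma::abs(gr).max();
    if (gn < tol_g_eff) { conv = true; break; }
    arma::vec pdir = -(H * gr);
    double slope = arma::dot(gr, pdir);
    if (slope >= 0) { H = arma::eye(P, P); pdir = -gr; slope = arma::dot(gr, pdir); }
    double step = 1.0, fnew = BIG;
    arma::vec thnew;
    bool ok = false;
    for (int ls = 0; ls < 50; ++ls) {
      thnew = th + step * pdir;
      fnew = eval_core(thnew, K, d.X4, d.X6, d.m1, d.W, nullptr);
      if (fnew <= f + 1e-4 * step * slope) { ok = true; break; }
      step *= 0.5;
    }
    if (!ok) { conv = (gn < 1e3 * tol_g_eff); break; }
    arma::vec grnew(P);
    eval_core(thnew, K, d.X4, d.X6, d.m1, d.W, &grnew);
    arma::vec sv = thnew - th, yv = grnew - gr;
    double sy = arma::dot(sv, yv);
    if (sy > 1e-10) {
      arma::vec Hy = H * yv;
      double yHy = arma::dot(yv, Hy);
      H += ((sy + yHy) / (sy * sy)) * (sv * sv.t())
         - (Hy * sv.t() + sv * Hy.t()) / sy;
    }
    double rel = std::fabs(f - fnew) / (std::fabs(f) + 1.0);
    th = thnew; gr = grnew;
    bool small_ll = rel < tol_ll;
    f = fnew;
    if (small_ll && arma::abs(gr).max() < tol_g * std::max(1.0, std::fabs(f))) {
      conv = true; ++it; break;
    }
  }
  FitOut out;
  out.theta = th; out.value = f; out.converged = conv; out.iter = it;
  out.gnorm = arma::abs(gr).max();
  out.H = H;
  return out;
}

// [[Rcpp::export(name = ".cpp_fit")]]
List cpp_fit(const arma::vec& theta0, int K,
             const arma::mat& X4, const arma::mat& X6,
             const arma::ivec& m1, const arma::mat& W,
             const arma::uvec& rows1,
             int maxit, double tol_ll, double tol_g) {
  SubData d(X4, X6, m1, W, rows1 - 1);
  FitOut f = bfgs_fit(theta0, K, d, maxit, tol_ll, tol_g);
  return List::create(_["theta"] = f.theta, _["value"] = f.value,
                      _["converged"] = f.converged, _["iter"] = f.iter,
                      _["grad_norm"] = f.gnorm, _["H"] = f.H);
}

// Cluster bootstrap driver: resamples parent clusters with replacement
// (preserving the original parent count), re-forms the two sex groups, and
// refits each group warm-started from the full-sample estimates.
// cluster_of: 1-based cluster index per row; group_of: 1 or 2 per row.
// Returns one theta draw per group per resample plus convergence flags.
// [[Rcpp::export(name = ".cpp_bootstrap")]]
List cpp_bootstrap(int B, int K,
                   const arma::mat& X4, const arma::mat& X6,
                   const arma::ivec& m1, const arma::mat& W,
                   const arma::ivec& cluster_of, const arma::ivec& group_of,
                   int n_clusters,
                   const arma::vec& theta1, const arma::vec& theta2,
                   const arma::mat& H1, const arma::mat& H2,
                   int maxit, double tol_ll, double tol_g) {
  const int P = theta1.n_elem;
  arma::mat draws1(B, P), draws2(B, P);
  LogicalVector conv1(B), conv2(B);
  // cluster -> rows map
  std::vector<std::vector<unsigned int>> rows_of(n_clusters);
  for (unsigned int i = 0; i < cluster_of.n_elem; ++i)
    rows_of[cluster_of(i) - 1].push_back(i);

  for (int b = 0; b < B; ++b) {
    // draw clusters with R's RNG for reproducibility from set.seed()
    std::vector<unsigned int> g1rows, g2rows;
    for (int cpick = 0; cpick < n_clusters; ++cpick) {
      int cl = (int)(unif_rand() * n_clusters);
      if (cl == n_clusters) cl = n_clusters - 1;
      for (unsigned int r : rows_of[cl]) {
        if (group_of(r) == 1) g1rows.push_back(r); else g2rows.push_back(r);
      }
    }
    if (g1rows.empty() || g2rows.empty()) {
      conv1[b] = false; conv2[b] = false;
      draws1.row(b).zeros(); draws2.row(b).zeros();
      continue;
    }
    arma::uvec i1(g1rows), i2(g2rows);
    SubData d1(X4, X6, m1, W, i1), d2(X4, X6, m1, W, i2);
    FitOut f1 = bfgs_fit(theta1, K, d1, maxit, tol_ll, tol_g, &H1);
    FitOut f2 = bfgs_fit(theta2, K, d2, maxit, tol_ll, tol_g, &H2);
    draws1.row(b) = f1.theta.t(); conv1[b] = f1.converged;
    draws2.row(b) = f2.theta.t(); conv2[b] = f2.converged;
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["draws1"] = draws1, _["draws2"] = draws2,
                      _["conv1"] = conv1, _["conv2"] = conv2);
}
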