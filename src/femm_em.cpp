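#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Functional mixed-effects model, per gene:
//   y_s = Phi_s (A_s theta + u_s) + eps_s,  eps_sc ~ N(0, sigma_s^2)
//   u_s ~ N(0, sigma_s^2 Omega),            sigma_s^2 ~ IG(alpha, eta)
// Phi_s: C_s x (K+1) B-spline evaluations; A_s: (K+1) x p coefficient-space
// design mapping the p free mean parameters to spline coefficients.
// Marginalizing (u_s, sigma_s^2) gives a multivariate-t likelihood; the EM
// treats (u_s, sigma_s^2) as latent with a conjugate normal-inverse-gamma
// posterior, so every E-step is closed form.

struct SampleWork {
  arma::vec y;
  arma::mat Phi;   // C x (K+1)
  arma::mat A;     // (K+1) x p
  arma::mat D;     // C x p = Phi * A
  arma::mat PtP;   // (K+1) x (K+1)
  arma::vec Pty;   // (K+1)
  arma::mat PtD;   // (K+1) x p
  arma::mat DtD;   // p x p
  arma::vec Dty;   // p
  double yty;
  int C;
};

// log |I + Omega * PtP| and V = (PtP + Omega^{-1})^{-1} = (Omega*PtP + I)^{-1} Omega
// (valid also for singular Omega).
static void estep_sample(const SampleWork& w, const arma::vec& theta,
                         const arma::mat& Omega, arma::vec& m, arma::mat& V,
                         double& q, double& logdetM) {
  arma::uword d = w.PtP.n_rows;
  arma::mat G = Omega * w.PtP + arma::eye(d, d);
  V = arma::solve(G, Omega);
  V = 0.5 * (V + V.t());
  arma::vec Ptr = w.Pty - w.PtD * theta;
  m = V * Ptr;
  arma::vec Dth = w.DtD * theta;
  double rtr = w.yty - 2.0 * arma::dot(w.Dty, theta) + arma::dot(theta, Dth);
  q = rtr - arma::dot(Ptr, m);
  if (q < 0) q = 0;
  double val = 0, sign = 1;
  arma::log_det(val, sign, G);
  logdetM = val;
}

static double marg_loglik_all(const std::vector<SampleWork>& W,
                              const arma::vec& theta, const arma::mat& Omega,
                              double alpha, double eta) {
  double ll = 0;
  arma::vec m;
  arma::mat V;
  double q, ld;
  for (size_t s = 0; s < W.size(); ++s) {
    estep_sample(W[s], theta, Omega, m, V, q, ld);
    double C = W[s].C;
    ll += std::lgamma(alpha + C / 2.0) - std::lgamma(alpha) +
          alpha * std::log(eta) - (C / 2.0) * std::log(2.0 * M_PI) -
          0.5 * ld - (alpha + C / 2.0) * std::log(eta + q / 2.0);
  }
  return ll;
}

// Profile objective for alpha with eta profiled out (eta = S*alpha/W):
// g(a) = S*a*log(S*a/W) - S*lgamma(a) - (a+1)*L - S*a
static double alpha_profile(double a, double S, double Wsum, double Lsum) {
  return S * a * std::log(S * a / Wsum) - S * std::lgamma(a) - (a + 1.0) * Lsum -
         S * a;
}

static double optimize_alpha(double S, double Wsum, double Lsum) {
  // golden-section search on log(alpha) in [log 1.01, log 1e6]
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double lo = std::log(1.01), hi = std::log(1e3);  // cap: IG degenerates to a point mass as alpha grows
  double c = hi - gr * (hi - lo), d = lo + gr * (hi - lo);
  double fc = alpha_profile(std::exp(c), S, Wsum, Lsum);
  double fd = alpha_profile(std::exp(d), S, Wsum, Lsum);
  for (int it = 0; it < 100; ++it) {
    if (fc > fd) {
      hi = d; d = c; fd = fc;
      c = hi - gr * (hi - lo);
      fc = alpha_profile(std::exp(c), S, Wsum, Lsum);
    } else {
      lo = c; c = d; fc = fd;
      d = lo + gr * (hi - lo);
      fd = alpha_profile(std::exp(d), S, Wsum, Lsum);
    }
    if (hi - lo < 1e-10) break;
  }
  double a = std::exp(0.5 * (lo + hi));
  return a < 1.01 ? 1.01 : a;
}

static arma::mat regularize_pd(const arma::mat& X, double mineig) {
  arma::vec ev;
  arma::mat U;
  arma::eig_sym(ev, U, 0.5 * (X + X.t()));
  for (arma::uword i = 0; i < ev.n_elem; ++i)
    if (ev(i) < mineig) ev(i) = mineig;
  return U * arma::diagmat(ev) * U.t();
}

// [[Rcpp::export(name = ".femm_em_cpp")]]
List femm_em_cpp(List y_list, List Phi_list, List A_list, bool scalar_omega,
                 double tol, int max_iter, double alpha0, double eta0,
                 arma::mat Omega0, arma::vec theta0, bool fix_omega) {
  int S = y_list.size();
  std::vector<SampleWork> W(S);
  int p = theta0.n_elem;
  for (int s = 0; s < S; ++s) {
    W[s].y = as<arma::vec>(y_list[s]);
    W[s].Phi = as<arma::mat>(Phi_list[s]);
    W[s].A = as<arma::mat>(A_list[s]);
    W[s].D = W[s].Phi * W[s].A;
    W[s].PtP = W[s].Phi.t() * W[s].Phi;
    W[s].Pty = W[s].Phi.t() * W[s].y;
    W[s].PtD = W[s].PtP * W[s].A;
    W[s].DtD = W[s].D.t() * W[s].D;
    W[s].Dty = W[s].D.t() * W[s].y;
    W[s].yty = arma::dot(W[s].y, W[s].y);
    W[s].C = W[s].y.n_elem;
  }
  arma::uword d = W[0].PtP.n_rows;  // K+1
  arma::vec theta = theta0;
  arma::mat Omega = Omega0;
  double alpha = alpha0, eta = eta0;

  std::vector<double> trace;
  double ll = marg_loglik_all(W, theta, Omega, alpha, eta);
  trace.push_back(ll);
  bool converged = false;
  int iter = 0;

  arma::vec m;
  arma::mat V;
  double q, ld;
  std::vector<arma::vec> m_all(S);
  std::vector<arma::mat> V_all(S);
  arma::vec q_all(S), w_all(S);

  for (iter = 1; iter <= max_iter; ++iter) {
    // E-step
    double Wsum = 0, Lsum = 0;
    arma::mat Euu_w(d, d, arma::fill::zeros);
    for (int s = 0; s < S; ++s) {
      estep_sample(W[s], theta, Omega, m, V, q, ld);
      double C = W[s].C;
      double w = (alpha + C / 2.0) / (eta + q / 2.0);           // E[1/sigma^2]
      double elog = std::log(eta + q / 2.0) - R::digamma(alpha + C / 2.0);
      m_all[s] = m;
      V_all[s] = V;
      q_all(s) = q;
      w_all(s) = w;
      Wsum += w;
      Lsum += elog;
      Euu_w += w * (m * m.t()) + V;
    }
    // M-step: theta (weighted LS on residual after removing E[u])
    arma::mat LHS(p, p, arma::fill::zeros);
    arma::vec RHS(p, arma::fill::zeros);
    for (int s = 0; s < S; ++s) {
      LHS += w_all(s) * W[s].DtD;
      RHS += w_all(s) * (W[s].Dty - W[s].PtD.t() * m_all[s]);
    }
    LHS.diag() += 1e-10;
    theta = arma::solve(LHS, RHS);
    // M-step: Omega
    if (!fix_omega) {
      arma::mat Onew = Euu_w / (double)S;
      if (scalar_omega) {
        double w2 = arma::trace(Onew) / (double)d;
        Omega = w2 * arma::eye(d, d);
        if (w2 < 1e-10) Omega.diag().fill(1e-10);
      } else {
        Omega = regularize_pd(Onew, 1e-10);
      }
    }
    // M-step: (alpha, eta)
    alpha = optimize_alpha((double)S, Wsum, Lsum);
    eta = S * alpha / Wsum;

    double llnew = marg_loglik_all(W, theta, Omega, alpha, eta);
    trace.push_back(llnew);
    if (std::abs(llnew - ll) < tol) {
      ll = llnew;
      converged = true;
      break;
    }
    ll = llnew;
  }

  // final E-step at the returned parameters
  List post_m(S), post_V(S);
  arma::vec Einv(S), Esig(S), qfin(S);
  for (int s = 0; s < S; ++s) {
    estep_sample(W[s], theta, Omega, m, V, q, ld);
    double C = W[s].C;
    post_m[s] = m;
    post_V[s] = V;
    qfin(s) = q;
    Einv(s) = (alpha + C / 2.0) / (eta + q / 2.0);
    double shape = alpha + C / 2.0 - 1.0;
    Esig(s) = shape > 0 ? (eta + q / 2.0) / shape : NA_REAL;
  }

  return List::create(
      _["theta"] = theta, _["Omega"] = Omega, _["alpha"] = alpha,
      _["eta"] = eta, _["loglik"] = ll, _["trace"] = trace,
      _["converged"] = converged, _["n_iter"] = (int)trace.size() - 1,
      _["post_mean_u"] = post_m, _["post_V"] = post_V, _["q"] = qfin,
      _["E_inv_sigma2"] = Einv, _["E_sigma2"] = Esig);
}

// [[Rcpp::export(name = ".femm_loglik_cpp")]]
double femm_loglik_cpp(List y_list, List Phi_list, List A_list,
                       arma::vec theta, arma::mat Omega, double alpha,
                       double eta) {
  int S = y_list.size();
  std::vector<SampleWork> W(S);
  for (int s = 0; s < S; ++s) {
    W[s].y = as<arma::vec>(y_list[s]);
    W[s].Phi = as<arma::mat>(Phi_list[s]);
    W[s].A = as<arma::mat>(A_list[s]);
    W[s].D = W[s].Phi * W[s].A;
    W[s].PtP = W[s].Phi.t() * W[s].Phi;
    W[s].Pty = W[s].Phi.t() * W[s].y;
    W[s].PtD = W[s].PtP * W[s].A;
    W[s].DtD = W[s].D.t() * W[s].D;
    W[s].Dty = W[s].D.t() * W[s].y;
    W[s].yty = arma::dot(W[s].y, W[s].y);
    W[s].C = W[s].y.n_elem;
  }
  return marg_loglik_all(W, theta, Omega, alpha, eta);
}
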