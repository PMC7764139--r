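#include <Rcpp.h>
using namespace Rcpp;

// Marginal log-likelihood of a random-intercept logistic model, integrated by
// adaptive Gauss-Hermite quadrature with per-facility mode recentring.
//
// Rows must be sorted by facility; grp_start/grp_end are 0-based inclusive row
// ranges, one entry per facility. gh_nodes are standard Gauss-Hermite nodes
// x_j for the weight e^{-x^2}; gh_logw_adj = log(w_j) + x_j^2 so that
// integral e^{h(u)} du ~ sqrt(2) * sigma * sum_j exp(gh_logw_adj[j] + h(u_j)).

static inline double qp_log1pexp(double x) {
  // stable log(1 + e^x)
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Bernoulli log-likelihood of one facility's rows at latent intercept u.
static double grp_loglik(const double* eta, const double* y, int a, int b,
                         double u) {
  double ll = 0.0;
  for (int i = a; i <= b; ++i) {
    double z = eta[i] + u;
    // y*z - log(1+e^z)
    ll += y[i] * z - qp_log1pexp(z);
  }
  return ll;
}

// [[Rcpp::export]]
List agq_loglik_cpp(NumericVector beta, double log_vg, NumericVector y,
                    NumericMatrix X, IntegerVector grp_start,
                    IntegerVector grp_end, NumericVector gh_nodes,
                    NumericVector gh_logw_adj, bool want_modes) {
  const int n = X.nrow(), p = X.ncol(), k = grp_start.size();
  const int q = gh_nodes.size();
  const double vg = std::max(std::exp(log_vg), 1e-12);
  const double sqrt2 = std::sqrt(2.0);
  const double log_norm = -0.5 * std::log(2.0 * M_PI * vg);

  std::vector<double> eta(n, 0.0);
  for (int j = 0; j < p; ++j) {
    const double bj = beta[j];
    if (bj == 0.0) continue;
    for (int i = 0; i < n; ++i) eta[i] += X(i, j) * bj;
  }

  NumericVector modes(want_modes ? k : 0), sds(want_modes ? k : 0);
  double total = 0.0;
  const double* etap = eta.data();
  const double* yp = REAL(y);

  for (int g = 0; g < k; ++g) {
    const int a = grp_start[g], b = grp_end[g];
    // Newton for the mode of h(u) = loglik_g(u) - u^2/(2 vg) + log_norm;
    // h is strictly concave so damped Newton converges.
    double u = 0.0, hneg = 1.0 / vg;
    for (int it = 0; it < 100; ++it) {
      double grad = -u / vg, w = 1.0 / vg;
      for (int i = a; i <= b; ++i) {
        double pr = 1.0 / (1.0 + std::exp(-(etap[i] + u)));
        grad += yp[i] - pr;
        w += pr * (1.0 - pr);
      }
      hneg = w;
      double step = grad / w;
      if (step > 5.0) step = 5.0;
      if (step < -5.0) step = -5.0;
      u += step;
      if (std::fabs(step) < 1e-11) break;
    }
    const double sigma = 1.0 / std::sqrt(hneg);

    // log sum exp over recentred nodes
    double m = R_NegInf;
    std::vector<double> t(q);
    for (int j = 0; j < q; ++j) {
      double uj = u + sqrt2 * sigma * gh_nodes[j];
      double hj = grp_loglik(etap, yp, a, b, uj) -
                  uj * uj / (2.0 * vg) + log_norm;
      t[j] = gh_logw_adj[j] + hj;
      if (t[j] > m) m = t[j];
    }
    double s = 0.0;
    for (int j = 0; j < q; ++j) s += std::exp(t[j] - m);
    total += std::log(sqrt2 * sigma) + m + std::log(s);

    if (want_modes) {
      modes[g] = u;
      sds[g] = sigma;
    }
  }

  if (want_modes)
    return List::create(_["loglik"] = total, _["mode"] = modes,
                        _["cond_sd"] = sds);
  return List::create(_["loglik"] = total);
}
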