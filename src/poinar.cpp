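#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Conditional log-likelihood of a PoINAR(1) path:
//   sum_{t=2}^n log f(x_t | x_{t-1}),
//   f(k|l) = sum_{j=0}^{min(k,l)} C(l,j) a^j (1-a)^(l-j) e^-lam lam^(k-j)/(k-j)!
// The inner sum is accumulated in the linear domain relative to the j=0 term
// via the term ratio
//   t_{j+1}/t_j = ((l-j)/(j+1)) * (a/(1-a)) * ((k-j)/lam),
// rescaling when the running sum grows past 1e250, so no per-term exp/log is
// needed; one log per transition.
static double cloglik_core(const int *x, int n, double alpha, double lam) {
  const double l1a = std::log1p(-alpha);
  const double llam = std::log(lam);
  const double odds = alpha / (1.0 - alpha);
  double ll = 0.0;
  for (int t = 1; t < n; ++t) {
    const int k = x[t], l = x[t - 1];
    const int m = std::min(k, l);
    double logt0 = l * l1a + k * llam - R::lgammafn(k + 1.0) - lam;
    double s = 1.0, term = 1.0, logscale = 0.0;
    for (int j = 0; j < m; ++j) {
      term *= ((double)(l - j) / (j + 1.0)) * odds * ((double)(k - j) / lam);
      s += term;
      if (s > 1e250) {
        s *= 1e-250;
        term *= 1e-250;
        logscale += 250.0 * M_LN10;
      }
    }
    const double lf = logt0 + std::log(s) + logscale;
    if (!R_finite(lf))
      stop("non-finite transition log-probability at t = %d", t + 1);
    ll += lf;
  }
  return ll;
}

// [[Rcpp::export]]
double poinar_cloglik_cpp(IntegerVector x, double alpha, double lam) {
  int n = x.size();
  if (n < 2) stop("series must have length >= 2");
  if (!(alpha > 0.0 && alpha < 1.0)) stop("alpha must lie in (0, 1)");
  if (!(lam > 0.0)) stop("lam must be positive");
  return cloglik_core(INTEGER(x), n, alpha, lam);
}

// one draw from Poisson(mu) conditioned on X >= lo (lo <= 0 means untruncated),
// inverse-CDF on the renormalised tail
static double rtpois_lower(double mu, int lo) {
  if (lo <= 0) return R::rpois(mu);
  double tail = R::ppois(lo - 1.0, mu, 0, 0); // P(X >= lo)
  if (tail < 1e-300)
    stop("truncated Poisson: limit %d is unreachable at mean %g", lo, mu);
  double u = unif_rand();
  double q = R::qpois(tail * (1.0 - u), mu, 0, 0);
  return q < lo ? (double)lo : q;
}

// one draw from Poisson(mu) conditioned on X <= hi
static double rtpois_upper(double mu, int hi) {
  double head = R::ppois((double)hi, mu, 1, 0);
  if (head < 1e-300)
    stop("truncated Poisson: limit %d is unreachable at mean %g", hi, mu);
  double q = R::qpois(unif_rand() * head, mu, 1, 0);
  return q > hi ? (double)hi : q;
}

struct LamTarget {
  const std::vector<int> *z;
  double alpha, shape, rate;
  double operator()(double lam) const {
    return (shape - 1.0) * std::log(lam) - rate * lam +
           cloglik_core(z->data(), (int)z->size(), alpha, lam);
  }
};

struct AlphaTarget {
  const std::vector<int> *z;
  double lam, a, b;
  double operator()(double alpha) const {
    return (a - 1.0) * std::log(alpha) + (b - 1.0) * std::log1p(-alpha) +
           cloglik_core(z->data(), (int)z->size(), alpha, lam);
  }
};

// shrinkage slice sampler on a bounded interval (exact stationarity)
template <class F>
static double slice_step(const F &logf, double x0, double lo, double hi) {
  double y = logf(x0) - exp_rand();
  double L = lo, R_ = hi;
  for (int it = 0; it < 1000; ++it) {
    double x1 = L + unif_rand() * (R_ - L);
    if (logf(x1) >= y) return x1;
    if (x1 < x0) L = x1; else R_ = x1;
    if (R_ - L < 1e-14) break;
  }
  return x0;
}

// Gibbs sweep with data augmentation for censored PoINAR(1):
// per iteration sample lam | alpha, z then alpha | lam, z (slice within Gibbs),
// then re-impute each limit observation as ceil(median of m draws) from the
// Poisson(lam/(1-alpha)) marginal truncated at the limit. Uses R's RNG.
// [[Rcpp::export]]
List gda_chain_cpp(IntegerVector y, LogicalVector cens, int limit, bool left,
                   double alpha0, double lam0,
                   double a, double b, double shape, double rate,
                   int n_iter, int m, double eps, double lam_max) {
  const int n = y.size();
  if (m < 1 || m > 1024) stop("m must be in 1..1024");
  std::vector<int> z(n);
  for (int i = 0; i < n; ++i) z[i] = y[i];
  std::vector<int> cidx;
  for (int i = 0; i < n; ++i) if (cens[i]) cidx.push_back(i);

  NumericMatrix draws(n_iter, 2);
  double alpha = alpha0, lam = lam0;
  std::vector<double> w(m);

  LamTarget flam{&z, alpha, shape, rate};
  AlphaTarget falp{&z, lam, a, b};

  for (int k = 0; k < n_iter; ++k) {
    flam.alpha = alpha;
    lam = slice_step(flam, lam, eps, lam_max);
    falp.lam = lam;
    alpha = slice_step(falp, alpha, eps, 1.0 - eps);
    if (!cidx.empty()) {
      const double mu = lam / (1.0 - alpha);
      for (size_t ci = 0; ci < cidx.size(); ++ci) {
        for (int j = 0; j < m; ++j)
          w[j] = left ? rtpois_upper(mu, limit) : rtpois_lower(mu, limit);
        std::sort(w.begin(), w.end());
        double med = (m % 2) ? w[m / 2] : 0.5 * (w[m / 2 - 1] + w[m / 2]);
        z[cidx[ci]] = (int)std::ceil(med);
      }
    }
    draws(k, 0) = alpha;
    draws(k, 1) = lam;
    if ((k & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  IntegerVector zout(z.begin(), z.end());
  return List::create(_["draws"] = draws, _["z"] = zout);
}
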