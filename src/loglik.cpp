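#include <Rcpp.h>
#include <cmath>
#include <map>
using namespace Rcpp;

// ex-Gaussian density / survivor (clamped to non-negative support,
// mirroring the R-level dexgauss/sexgauss)
static inline double exg_dens(double t, double mu, double sigma, double tau) {
  if (t <= 0.0) return 0.0;
  double z = (t - mu) / sigma;
  double lg = -std::log(tau) + sigma * sigma / (2.0 * tau * tau) -
    (t - mu) / tau + R::pnorm(z - sigma / tau, 0.0, 1.0, 1, 1);
  double d = std::exp(lg);
  return std::isfinite(d) ? d : 0.0;
}

static inline double exg_cdf(double t, double mu, double sigma, double tau) {
  if (t <= 0.0) return 0.0;
  double z = (t - mu) / sigma;
  double p = R::pnorm(z, 0.0, 1.0, 1, 0) -
    std::exp(sigma * sigma / (2.0 * tau * tau) - (t - mu) / tau +
             R::pnorm(z - sigma / tau, 0.0, 1.0, 1, 1));
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

static inline double exg_surv(double t, double mu, double sigma, double tau) {
  return 1.0 - exg_cdf(t, mu, sigma, tau);
}

// 20-point Gauss-Legendre nodes/weights on [-1, 1], computed once by
// Newton iteration on the Legendre polynomial.
static const int GLN = 20;
static double gl_x[GLN], gl_w[GLN];
static bool gl_ready = false;

static void gl_init() {
  if (gl_ready) return;
  int m = (GLN + 1) / 2;
  for (int i = 0; i < m; ++i) {
    double x = std::cos(M_PI * (i + 0.75) / (GLN + 0.5));
    double pp = 0.0;
    for (int it = 0; it < 100; ++it) {
      double p0 = 1.0, p1 = 0.0;
      for (int j = 0; j < GLN; ++j) {
        double p2 = p1; p1 = p0;
        p0 = ((2.0 * j + 1.0) * x * p1 - j * p2) / (j + 1.0);
      }
      pp = GLN * (x * p0 - p1) / (x * x - 1.0);
      double x1 = x;
      x = x1 - p0 / pp;
      if (std::fabs(x - x1) < 1e-15) break;
    }
    gl_x[i] = -x; gl_x[GLN - 1 - i] = x;
    gl_w[i] = 2.0 / ((1.0 - x * x) * pp * pp);
    gl_w[GLN - 1 - i] = gl_w[i];
  }
  gl_ready = true;
}

// integral of f(s) over [a, b] via composite Gauss-Legendre
template <typename F>
static double gl_integrate(F f, double a, double b, int panels) {
  gl_init();
  if (b <= a) return 0.0;
  double h = (b - a) / panels, total = 0.0;
  for (int p = 0; p < panels; ++p) {
    double lo = a + p * h, mid = lo + h / 2.0, half = h / 2.0;
    double s = 0.0;
    for (int i = 0; i < GLN; ++i) s += gl_w[i] * f(mid + half * gl_x[i]);
    total += half * s;
  }
  return total;
}

struct Runner { double mu, sigma, tau; };

static inline double upper_bound(const Runner& r) {
  return r.mu + 8.0 * r.sigma + 45.0 * r.tau;
}

// P(stop beats go | both launched) = int f_S(s) S_G(d + s) ds
static double pwin(const Runner& go, const Runner& stop, double d) {
  double smax = upper_bound(stop);
  auto f = [&](double s) {
    return exg_dens(s, stop.mu, stop.sigma, stop.tau) *
      exg_surv(d + s, go.mu, go.sigma, go.tau);
  };
  return gl_integrate(f, 0.0, smax, 8);
}

// P(go wins with t_go > T) = int_T^inf f_G(t) S_S(t - d) dt
static double tail_go_win(const Runner& go, const Runner& stop,
                          double T, double d) {
  double tmax = upper_bound(go);
  if (tmax <= T) return 0.0;
  auto f = [&](double t) {
    return exg_dens(t, go.mu, go.sigma, go.tau) *
      exg_surv(t - d, stop.mu, stop.sigma, stop.tau);
  };
  return gl_integrate(f, T, tmax, 4);
}

// Per-trial SIS likelihoods.
//
// stim: 0 = DS, 1 = LS (right-stop, correct response LR via sel_left),
//       2 = RS (left-stop, correct response RR via sel_right)
// resp: 0 = NR, 1 = DR, 2 = LR, 3 = RR
// cond: 0-based row index into the runner parameter matrix
// parmat: n_cond x 12 (dual_go mu/sigma/tau, dual_stop ..., sel_left ...,
//         sel_right ...)
// [[Rcpp::export]]
NumericVector sis_loglik_cpp(IntegerVector stim, IntegerVector resp,
                             NumericVector rt, NumericVector ssd,
                             IntegerVector cond, NumericMatrix parmat,
                             double gf, double tf, double eps,
                             double p_floor, double deadline) {
  int n = stim.size();
  NumericVector out(n);
  int n_cond = parmat.nrow();
  std::vector<Runner> DG(n_cond), ST(n_cond), SL(n_cond), SR(n_cond);
  std::vector<double> SG_T(n_cond);
  for (int c = 0; c < n_cond; ++c) {
    DG[c] = {parmat(c, 0), parmat(c, 1), parmat(c, 2)};
    ST[c] = {parmat(c, 3), parmat(c, 4), parmat(c, 5)};
    SL[c] = {parmat(c, 6), parmat(c, 7), parmat(c, 8)};
    SR[c] = {parmat(c, 9), parmat(c, 10), parmat(c, 11)};
    SG_T[c] = exg_surv(deadline, DG[c].mu, DG[c].sigma, DG[c].tau);
  }
  // cache Pwin and the beyond-deadline go-win mass per (condition, SSD)
  std::map<std::pair<int, long long>, std::pair<double, double>> cache;
  auto get_integrals = [&](int c, double d) {
    std::pair<int, long long> key(c, (long long)std::llround(d * 1000.0));
    auto it = cache.find(key);
    if (it != cache.end()) return it->second;
    std::pair<double, double> v(pwin(DG[c], ST[c], d),
                                tail_go_win(DG[c], ST[c], deadline, d));
    cache[key] = v;
    return v;
  };

  for (int i = 0; i < n; ++i) {
    int c = cond[i], s = stim[i], r = resp[i];
    double p;
    if (s == 0) {                       // dual stimulus
      if (r == 1) {
        p = (1.0 - gf) * exg_dens(rt[i], DG[c].mu, DG[c].sigma, DG[c].tau);
      } else if (r == 0) {
        p = gf + (1.0 - gf) * SG_T[c];
      } else {
        p = p_floor;                    // rare unimanual motor error on DS
      }
    } else {                            // selective stop trial
      double d = ssd[i];
      const Runner& U = (s == 1) ? SL[c] : SR[c];  // continuing hand
      const Runner& W = (s == 1) ? SR[c] : SL[c];  // cued-to-stop hand
      int correct = (s == 1) ? 2 : 3;
      if (r == 1) {                     // failed stop: dual response
        double fg = exg_dens(rt[i], DG[c].mu, DG[c].sigma, DG[c].tau);
        double ss = (rt[i] <= d) ? 1.0 :
          exg_surv(rt[i] - d, ST[c].mu, ST[c].sigma, ST[c].tau);
        p = (1.0 - gf) * fg * (tf + (1.0 - tf) * ss);
      } else if (r == 0) {              // no response
        auto ints = get_integrals(c, d);
        double su = exg_surv(deadline - d, U.mu, U.sigma, U.tau);
        double sw = exg_surv(deadline - d, W.mu, W.sigma, W.tau);
        double smix = (1.0 - eps) * su + eps * sw;
        p = gf * tf + (1.0 - gf) * tf * SG_T[c] +
          gf * (1.0 - tf) * smix +
          (1.0 - gf) * (1.0 - tf) * (ints.second + ints.first * smix);
      } else {                          // unimanual response at rt
        auto ints = get_integrals(c, d);
        double launch = gf + (1.0 - gf) * ints.first;
        double dens;
        if (r == correct) {
          dens = (1.0 - eps) * exg_dens(rt[i] - d, U.mu, U.sigma, U.tau);
        } else {
          dens = eps * exg_dens(rt[i] - d, W.mu, W.sigma, W.tau);
        }
        p = (1.0 - tf) * dens * launch;
      }
    }
    if (!(p > p_floor)) p = p_floor;
    out[i] = std::log(p);
  }
  return out;
}

// [[Rcpp::export]]
double pwin_cpp(NumericVector go, NumericVector stop, double ssd) {
  Runner g = {go[0], go[1], go[2]}, s = {stop[0], stop[1], stop[2]};
  return pwin(g, s, ssd);
}
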