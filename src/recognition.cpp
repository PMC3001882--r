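#include <Rcpp.h>
using namespace Rcpp;

// Sequential mean-field recognition filter for the associative-learning
// observer.
//
// Generative model per trial k (single cue stream):
//   a_k | a_{k-1} ~ N(a_{k-1}, 1/lambda)   [dynamic]  or  a_k = a (fixed,
//                                           a ~ N(0, 1/lambda)) [static]
//   x_k | a_k     ~ Bernoulli(sigmoid(a_k))      (x = 1: house, 0: face)
//   u_k | x_k     ~ N(eta1, sigma_u^2)^x N(eta0, sigma_u^2)^(1-x)
//
// The posterior is factorised as q(x_k) Bernoulli(mu_x) times q(a_k)
// Gaussian(mu_a, s2_a).  Because log p(x|a) = x*a - log(1 + e^a), the
// optimal q(x) has log-odds LLR(u) + E_q[a].  The Gaussian factor matches
// the first two moments of the tilted association density
//   p~(a) proportional to N(a; m, V) * exp(mu_x * a - softplus(a)),
// computed by Gauss-Hermite quadrature recentred at the (unique) mode of
// the strictly log-concave tilt; the coordinate pair is iterated to a
// fixed point.

static const int GH_N = 20;
static const double GH_X[GH_N] = {
  -5.3874808900112301, -4.6036824495507433, -3.9447640401156248,
  -3.3478545673832114, -2.7888060584281282, -2.2549740020892743,
  -1.7385377121165817, -1.2340762153953211, -0.73747372854539517,
  -0.24534070830090116, 0.24534070830090382, 0.73747372854539783,
  1.2340762153953255, 1.7385377121165857, 2.2549740020892757,
  2.7888060584281296, 3.3478545673832163, 3.9447640401156265,
  4.6036824495507442, 5.3874808900112328};
static const double GH_W[GH_N] = {
  2.2293936455340942e-13, 4.3993409922731086e-10, 1.0860693707692345e-07,
  7.8025564785322259e-06, 0.00022833863601635519, 0.0032437733422378393,
  0.0248105208874634, 0.10901720602002382, 0.28667550536283232,
  0.4622436696006143, 0.46224366960060814, 0.28667550536283115,
  0.10901720602002409, 0.024810520887463858, 0.0032437733422378762,
  0.00022833863601635671, 7.8025564785321497e-06, 1.0860693707692734e-07,
  4.3993409922732032e-10, 2.2293936455341482e-13};

static inline double sigmoid(double z) {
  if (z >= 0.0) return 1.0 / (1.0 + std::exp(-z));
  double e = std::exp(z);
  return e / (1.0 + e);
}

static inline double softplus(double z) {
  if (z > 30.0) return z + std::exp(-z);
  return std::log1p(std::exp(z));
}

// first two moments of p~(a) ~ N(a; m, V) exp(mu_x a - softplus(a)),
// by mode-recentred Gauss-Hermite quadrature
static void tilted_moments(double mu_x, double m, double V,
                           double *mu_out, double *var_out) {
  double a = m;
  for (int j = 0; j < 50; ++j) {
    double s = sigmoid(a);
    double g = mu_x - s - (a - m) / V;
    double h = -s * (1.0 - s) - 1.0 / V;
    double step = -g / h;
    if (std::fabs(step) > 5.0) step = (step > 0 ? 5.0 : -5.0);
    a += step;
    if (std::fabs(step) < 1e-12) break;
  }
  double sl = sigmoid(a);
  double s2_lap = 1.0 / (1.0 / V + sl * (1.0 - sl));
  double sig = std::sqrt(2.0 * s2_lap);  // widened proposal scale
  double z[GH_N], lf[GH_N];
  double lmax = -INFINITY;
  for (int i = 0; i < GH_N; ++i) {
    z[i] = a + M_SQRT2 * sig * GH_X[i];
    lf[i] = mu_x * z[i] - softplus(z[i]) -
      (z[i] - m) * (z[i] - m) / (2.0 * V) +
      (z[i] - a) * (z[i] - a) / (2.0 * sig * sig);
    if (lf[i] > lmax) lmax = lf[i];
  }
  double s0 = 0.0, s1 = 0.0;
  for (int i = 0; i < GH_N; ++i) {
    double w = GH_W[i] * std::exp(lf[i] - lmax);
    s0 += w; s1 += w * z[i];
  }
  double mu = s1 / s0, s2 = 0.0;
  for (int i = 0; i < GH_N; ++i) {
    double w = GH_W[i] * std::exp(lf[i] - lmax);
    s2 += w * (z[i] - mu) * (z[i] - mu);
  }
  *mu_out = mu;
  *var_out = s2 / s0;
}

// [[Rcpp::export(name = ".recognition_filter_cpp")]]
NumericMatrix recognition_filter_cpp(NumericVector u,
                                     double eta0, double eta1,
                                     double sigma_u, double lambda,
                                     bool dynamic,
                                     double mu_a0, double s2_a0,
                                     double tol, int max_iter,
                                     double min_var) {
  const int n = u.size();
  NumericMatrix out(n, 6); // mu_x, mu_a, s2_a, xi, prior_mean, prior_var
  colnames(out) = CharacterVector::create("mu_x", "mu_a", "s2_a", "xi",
                                          "prior_mean", "prior_var");
  const double s2u = sigma_u * sigma_u;

  // posterior carried from the previous trial
  double mu_prev, s2_prev;
  if (dynamic) {
    mu_prev = mu_a0;            // initial belief (default (0, 1))
    s2_prev = s2_a0;
  } else {
    mu_prev = 0.0;              // trial-1 prior N(0, 1/lambda)
    s2_prev = 1.0 / lambda;
  }

  for (int k = 0; k < n; ++k) {
    // prediction step
    double m = mu_prev;
    double V = dynamic ? (s2_prev + 1.0 / lambda) : s2_prev;
    if (dynamic && k == 0) { m = mu_a0; V = s2_a0; }
    // pre-stimulus outcome prediction: Gaussian pushed through the logistic
    // (MacKay moment approximation)
    double xi = sigmoid(m / std::sqrt(1.0 + M_PI * V / 8.0));

    double llr = ((u[k] - eta0) * (u[k] - eta0) -
                  (u[k] - eta1) * (u[k] - eta1)) / (2.0 * s2u);

    // The coordinate fixed point satisfies mu_a = t(mu_a) with
    // t(a) = tilted_mean(sigmoid(llr + a)); t is increasing and maps
    // [t at mu_x=0, t at mu_x=1] into itself, so roots of g = t - id are
    // bracketed and found by scan + bisection.  Multiple roots (bistable
    // trials) are resolved by the trial free energy.
    double roots[3];
    int n_roots = 0;
    // fast path: damped fixed-point iteration from the prior mean; most
    // trials converge in a handful of sweeps
    {
      double a = m, d_prev = R_PosInf, relax = 1.0;
      for (int it = 0; it < 50; ++it) {
        double tm, dum2;
        tilted_moments(sigmoid(llr + a), m, V, &tm, &dum2);
        double d = std::fabs(tm - a);
        if (d < tol) { roots[n_roots++] = a; break; }
        if (d >= 0.99 * d_prev && relax > 0.2) relax *= 0.5;
        d_prev = d;
        a += relax * (tm - a);
      }
    }
    double lo, hi, dum;
    if (n_roots == 0) {
      tilted_moments(0.0, m, V, &lo, &dum);
      tilted_moments(1.0, m, V, &hi, &dum);
    }
    if (n_roots > 0) {
      // already solved
    } else if (hi - lo < tol) {
      roots[n_roots++] = 0.5 * (lo + hi);
    } else {
      const int NG = 33;
      double ga[NG], gv[NG];
      for (int i = 0; i < NG; ++i) {
        ga[i] = lo + (hi - lo) * i / (NG - 1.0);
        double tm;
        tilted_moments(sigmoid(llr + ga[i]), m, V, &tm, &dum);
        gv[i] = tm - ga[i];
      }
      for (int i = 0; i < NG && n_roots < 3; ++i) {
        if (std::fabs(gv[i]) < 1e-9 * (1.0 + std::fabs(ga[i]))) {
          roots[n_roots++] = ga[i];
          continue;
        }
        if (i == NG - 1) break;
        if (gv[i] > 0.0 && gv[i + 1] < 0.0) {
          double a_lo = ga[i], a_hi = ga[i + 1];
          for (int j = 0; j < 60; ++j) {
            double mid = 0.5 * (a_lo + a_hi), tm;
            tilted_moments(sigmoid(llr + mid), m, V, &tm, &dum);
            if (tm - mid > 0.0) a_lo = mid; else a_hi = mid;
            if (a_hi - a_lo < tol) break;
          }
          roots[n_roots++] = 0.5 * (a_lo + a_hi);
        }
      }
      if (n_roots == 0) {
        stop("recognition update failed to converge at trial %d", k + 1);
      }
    }
    // evaluate candidates; pick the one with the highest trial free energy
    const double ll1 = -0.5 * std::log(2.0 * M_PI * s2u) -
      (u[k] - eta1) * (u[k] - eta1) / (2.0 * s2u);
    const double ll0 = -0.5 * std::log(2.0 * M_PI * s2u) -
      (u[k] - eta0) * (u[k] - eta0) / (2.0 * s2u);
    double mu_x = 0.0, mu_a = 0.0, s2 = V, best_fe = -INFINITY;
    for (int rix = 0; rix < n_roots; ++rix) {
      double mx = sigmoid(llr + roots[rix]);
      double ma, sa;
      tilted_moments(mx, m, V, &ma, &sa);
      if (sa < min_var) sa = min_var;
      // E[softplus] under N(ma, sa) by Gauss-Hermite
      double esp = 0.0, sq = std::sqrt(2.0 * sa);
      for (int i = 0; i < GH_N; ++i) {
        esp += GH_W[i] * softplus(ma + sq * GH_X[i]);
      }
      esp /= std::sqrt(M_PI);
      double hb = 0.0;
      if (mx > 0.0) hb -= mx * std::log(mx);
      if (mx < 1.0) hb -= (1.0 - mx) * std::log(1.0 - mx);
      double fe = mx * ll1 + (1.0 - mx) * ll0 + mx * ma - esp -
        0.5 * std::log(2.0 * M_PI * V) -
        (sa + (ma - m) * (ma - m)) / (2.0 * V) +
        hb + 0.5 * std::log(2.0 * M_PI * M_E * sa);
      if (fe > best_fe) { best_fe = fe; mu_x = mx; mu_a = ma; s2 = sa; }
    }

    out(k, 0) = mu_x;
    out(k, 1) = mu_a;
    out(k, 2) = s2;
    out(k, 3) = xi;
    out(k, 4) = m;
    out(k, 5) = V;

    mu_prev = mu_a;
    s2_prev = s2;
  }
  return out;
}

// Optimal reaction times from a recognition trace: for each trial the
// belief relaxes exponentially (rate beta_sens) from the pre-stimulus
// prediction xi to the converged posterior mu_x; minimising
//   rho(t) = dtil * exp(-beta_sens * t) + beta_err * t
// (dtil = prediction-error magnitude for the chosen category) gives
//   t* = max(0, log(beta_sens * dtil / beta_err) / beta_sens),
// and t* = 0 whenever dtil <= 0 (categorisation-error sign).
// [[Rcpp::export(name = ".optimal_rt_series_cpp")]]
NumericVector optimal_rt_series_cpp(NumericVector mu_x, NumericVector xi,
                                    double beta_err, double beta_sens) {
  const int n = mu_x.size();
  NumericVector t(n);
  for (int k = 0; k < n; ++k) {
    double dtil = std::fabs(mu_x[k] - xi[k]); // correct-choice trials
    double ts = 0.0;
    if (dtil > 0.0) {
      ts = std::log(beta_sens * dtil / beta_err) / beta_sens;
      if (ts < 0.0) ts = 0.0;
    }
    t[k] = ts;
  }
  return t;
}
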