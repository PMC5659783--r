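#include <Rcpp.h>
using namespace Rcpp;

// Model codes shared with R/params.R (model_code()); keep in sync.
enum ModelCode { RACE = 0, NDD = 1, SNFI = 2, DNFI = 3,
                 CA = 4, SCA = 5, DCA = 6, SSCA = 7 };

// Gaussian noise via Box-Muller on R's uniform stream: one uniform pair per
// two alternatives (the second deviate of the last pair is discarded when m
// is odd). The R reference path (rnorm_bm in R/simulate.R) consumes the
// stream identically, so both routes agree exactly under a shared seed.
static inline void draw_noise(std::vector<double>& eps, int m) {
  for (int x = 0; x < m; x += 2) {
    const double u1 = unif_rand(), u2 = unif_rand();
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double th = 2.0 * M_PI * u2;
    eps[x] = r * std::cos(th);
    if (x + 1 < m) eps[x + 1] = r * std::sin(th);
  }
}

// Batch first-passage simulation of the discrete-time rectified accumulator
// recurrence d_x(t + dt) = max{0, d_x(t) + f_x(t) + sigma * eps}.
//
// Draw order per step is one Box-Muller pair per two alternatives, then one
// uniform only on a tie, through R's RNG, so that a given set.seed() yields
// results identical to the pure-R reference path in simulate_trial().
//
// V is n_trials x n_alternatives of latent values; the SSCA power law is
// applied here so value signals are V^a after onset. RT is the post-update
// time (step + 1) * dt of the first threshold crossing.
// [[Rcpp::export]]
DataFrame sim_trials_cpp(int model,
                         double b, double g, double sigma,
                         double iv, double s, double id, double a,
                         NumericMatrix V,
                         double D, double dt, double T0, double tmax) {
  const int n = V.nrow(), m = V.ncol();
  if (m < 2) stop("at least two alternatives are required");
  const int onset = (int) std::lround(T0 / dt);
  const int maxsteps = (int) std::lround(tmax / dt);
  IntegerVector choice(n);
  NumericVector rt(n);
  LogicalVector crossed(n);
  std::vector<double> v(m), d(m), f(m), eps(m + 1);

  for (int i = 0; i < n; ++i) {
    double vsum = 0.0;
    for (int x = 0; x < m; ++x) {
      double Vx = V(i, x);
      v[x] = (model == SSCA) ? std::pow(Vx, a) : Vx;
      vsum += v[x];
      d[x] = 0.0;
    }
    int win = -1;
    double rt_i = NA_REAL;
    bool hit = false;
    for (int step = 0; step < maxsteps && !hit; ++step) {
      const bool on = (step >= onset);
      const double vs = on ? vsum : 0.0;
      double dsum = 0.0;
      for (int x = 0; x < m; ++x) dsum += d[x];
      for (int x = 0; x < m; ++x) {
        const double vx = on ? v[x] : 0.0;
        const double voth = vs - vx;
        const double doth = dsum - d[x];
        double fx;
        switch (model) {
        case RACE: fx = b + g * vx; break;
        case NDD:  fx = b + g * (vx - voth / (m - 1)); break;
        case SNFI: fx = b + g * (vx - iv * voth); break;
        case DNFI: fx = g * (b + vx) / (s + vs); break;
        case CA:   fx = b + g * vx - id * doth; break;
        case SCA:
        case SSCA: fx = b + g * (vx - iv * voth) - id * doth; break;
        case DCA:  fx = g * (b + vx) / (s + vs) - id * doth; break;
        default: stop("unknown model code");
        }
        f[x] = fx;
      }
      draw_noise(eps, m);
      for (int x = 0; x < m; ++x) {
        const double nd = d[x] + f[x] + sigma * eps[x];
        d[x] = nd > 0.0 ? nd : 0.0;
      }
      int nhit = 0, first = -1;
      for (int x = 0; x < m; ++x) {
        if (d[x] >= D) { ++nhit; if (first < 0) first = x; }
      }
      if (nhit == 1) {
        win = first; hit = true;
      } else if (nhit > 1) {
        int k = (int) std::floor(unif_rand() * nhit);
        if (k >= nhit) k = nhit - 1;
        int c = -1;
        for (int x = 0; x < m; ++x) {
          if (d[x] >= D) { ++c; if (c == k) { win = x; break; } }
        }
        hit = true;
      }
      if (hit) rt_i = (step + 1) * dt;
    }
    if (hit) {
      choice[i] = win + 1;
      rt[i] = rt_i;
      crossed[i] = true;
    } else {
      choice[i] = NA_INTEGER;
      rt[i] = NA_REAL;
      crossed[i] = false;
    }
  }
  return DataFrame::create(_["choice"] = choice, _["rt_ms"] = rt,
                           _["crossed"] = crossed);
}
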