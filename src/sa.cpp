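// SGD-enhanced simulated annealing for the tanh rate model.
//
// One fit estimates theta = (alpha, beta, w_1..w_m) for a single target
// gene given the observed series of its candidate regulators, minimising
// E(theta) = SSE/Var with SSE the one-step-ahead squared prediction error.
// All randomness flows through R's RNG so set.seed() governs everything.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct SACtrl {
  int t_max, inner, n_c, n_f, max_restarts, polish_iters;
  double lambda, kappa, eps, sigma0;
};

SACtrl read_ctrl(const List& ctrl) {
  SACtrl c;
  c.t_max        = as<int>(ctrl["t_max"]);
  c.inner        = as<int>(ctrl["inner_iters"]);
  c.n_c          = as<int>(ctrl["n_c"]);
  c.n_f          = as<int>(ctrl["n_f"]);
  c.max_restarts = as<int>(ctrl["max_restarts"]);
  c.polish_iters = as<int>(ctrl["polish_iters"]);
  c.lambda       = as<double>(ctrl["lambda"]);
  c.kappa        = as<double>(ctrl["kappa"]);
  c.eps          = as<double>(ctrl["eps"]);
  c.sigma0       = as<double>(ctrl["sigma0"]);
  return c;
}

// D: Tp x m design (regulator values at times 1..T-1), dy: observed
// one-step changes. theta = [alpha, beta, w_1..w_m].
double energy(const std::vector<double>& dy, const double* D, int Tp, int m,
              const std::vector<double>& th, double inv_var) {
  const double alpha = th[0], beta = th[1];
  double s = 0.0;
  for (int t = 0; t < Tp; ++t) {
    double u = -beta;
    for (int j = 0; j < m; ++j) u += th[2 + j] * D[j * Tp + t];
    const double r = dy[t] - alpha * std::tanh(u);
    s += r * r;
  }
  return s * inv_var;
}

// Analytic gradient of E = SSE/Var. With u(t) the tanh argument and
// r(t) the residual:
//   dSSE/dalpha = -2 sum r tanh(u)
//   dSSE/dbeta  = +2 sum r alpha sech^2(u)
//   dSSE/dw_j   = -2 sum r alpha sech^2(u) g_j(t)
void gradient(const std::vector<double>& dy, const double* D, int Tp, int m,
              const std::vector<double>& th, double inv_var,
              std::vector<double>& g) {
  const double alpha = th[0], beta = th[1];
  std::fill(g.begin(), g.end(), 0.0);
  for (int t = 0; t < Tp; ++t) {
    double u = -beta;
    for (int j = 0; j < m; ++j) u += th[2 + j] * D[j * Tp + t];
    const double th_u = std::tanh(u);
    const double sech2 = 1.0 - th_u * th_u;
    const double r = dy[t] - alpha * th_u;
    g[0] += -2.0 * r * th_u;
    g[1] += 2.0 * r * alpha * sech2;
    const double common = -2.0 * r * alpha * sech2;
    for (int j = 0; j < m; ++j) g[2 + j] += common * D[j * Tp + t];
  }
  for (size_t k = 0; k < g.size(); ++k) g[k] *= inv_var;
}

struct FitResult {
  std::vector<double> theta;
  double energy;
  int restarts;
};

// Full annealing loop: temperature countdown t_max -> 1, inner_iters
// proposals per temperature, per-temperature energies checked for
// N_C consecutive flat pairs, multiplicative restart of the incumbent
// best, stop after n_f restarts without improvement of E_best.
FitResult sa_fit_core(const std::vector<double>& dy, const double* D,
                      int Tp, int m, double var, const SACtrl& c) {
  const int np = 2 + m;
  const double inv_var = 1.0 / var;
  std::vector<double> th(np), thn(np), g(np), best(np);

  for (int k = 0; k < np; ++k) th[k] = unif_rand() * 2.0 - 1.0;
  double E = energy(dy, D, Tp, m, th, inv_var);
  best = th;
  double E_best = E;

  int fails = 0, restarts = 0;
  for (;;) {
    const double E_best_before = E_best;
    std::vector<double> temps;  // per-temperature energies this pass
    temps.reserve(c.t_max);
    for (int t = c.t_max; t >= 1; --t) {
      for (int it = 0; it < c.inner; ++it) {
        const double p_grad = 0.2 + 0.3 * double(t) / double(c.t_max);
        if (unif_rand() > p_grad) {
          gradient(dy, D, Tp, m, th, inv_var, g);
          for (int k = 0; k < np; ++k) thn[k] = th[k] - c.lambda * g[k];
        } else {
          const double sig = c.sigma0 * double(t) / double(c.t_max);
          for (int k = 0; k < np; ++k) thn[k] = th[k] + sig * norm_rand();
        }
        const double En = energy(dy, D, Tp, m, thn, inv_var);
        bool accept = false;
        if (R_finite(En)) {
          if (En < E) {
            accept = true;
          } else {
            const double p_mh = std::exp((E - En) / (c.kappa * double(t)));
            if (unif_rand() < p_mh) accept = true;
          }
        }
        if (accept) {
          th = thn;
          E = En;
          if (E < E_best) { E_best = E; best = th; }
        }
      }
      temps.push_back(E);
      // converged at this pass when the last N_C consecutive
      // temperature-to-temperature energy differences are all < eps
      // (only checked once enough temperatures have been visited)
      const int sz = (int)temps.size();
      if (sz >= c.n_c + 2) {
        bool flat = true;
        for (int k = 0; k < c.n_c; ++k) {
          if (std::fabs(temps[sz - 1 - k] - temps[sz - 2 - k]) >= c.eps) {
            flat = false;
            break;
          }
        }
        if (flat) break;
      }
    }
    ++restarts;
    if (E_best < E_best_before - c.eps) fails = 0; else ++fails;
    if (fails >= c.n_f || restarts >= c.max_restarts) break;
    // multiplicative perturbation of the incumbent best, r_k ~ U(0.75,1.25)
    for (int k = 0; k < np; ++k) th[k] = best[k] * (0.75 + 0.5 * unif_rand());
    E = energy(dy, D, Tp, m, th, inv_var);
  }

  // final polish: strict-descent gradient steps (the t -> 0 limit of the
  // acceptance rule) with an adaptive step length, tightening the energy
  // floor so structures of different size are compared fairly
  if (c.polish_iters > 0) {
    double lam = c.lambda;
    th = best;
    double Ep = E_best;
    for (int it = 0; it < c.polish_iters && lam > 1e-14; ++it) {
      gradient(dy, D, Tp, m, th, inv_var, g);
      for (int k = 0; k < np; ++k) thn[k] = th[k] - lam * g[k];
      const double En = energy(dy, D, Tp, m, thn, inv_var);
      if (R_finite(En) && En < Ep) {
        th = thn;
        Ep = En;
        lam *= 1.3;
      } else {
        lam *= 0.5;
      }
    }
    if (Ep < E_best) { E_best = Ep; best = th; }
  }

  FitResult res;
  res.theta = best;
  res.energy = E_best;
  res.restarts = restarts;
  return res;
}

std::vector<double> diff_series(const NumericVector& y) {
  const int T = y.size();
  std::vector<double> dy(T - 1);
  for (int t = 0; t < T - 1; ++t) dy[t] = y[t + 1] - y[t];
  return dy;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_sa_energy")]]
double cpp_sa_energy(NumericVector y, NumericMatrix D, NumericVector theta,
                     double var) {
  std::vector<double> dy = diff_series(y);
  std::vector<double> th(theta.begin(), theta.end());
  return energy(dy, REAL(D), D.nrow(), D.ncol(), th, 1.0 / var);
}

// [[Rcpp::export(name = ".cpp_sa_gradient")]]
NumericVector cpp_sa_gradient(NumericVector y, NumericMatrix D,
                              NumericVector theta, double var) {
  std::vector<double> dy = diff_series(y);
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> g(th.size());
  gradient(dy, REAL(D), D.nrow(), D.ncol(), th, 1.0 / var, g);
  return NumericVector(g.begin(), g.end());
}

// [[Rcpp::export(name = ".cpp_sa_fit")]]
List cpp_sa_fit(NumericVector y, NumericMatrix D, double var, List ctrl) {
  if (y.size() < 2) stop("need at least two time points");
  SACtrl c = read_ctrl(ctrl);
  std::vector<double> dy = diff_series(y);
  RNGScope scope;
  FitResult r = sa_fit_core(dy, REAL(D), D.nrow(), D.ncol(), var, c);
  return List::create(_["theta"] = NumericVector(r.theta.begin(), r.theta.end()),
                      _["energy"] = r.energy,
                      _["restarts"] = r.restarts);
}

// Enumerate candidate regulator sets for one target gene. Xfull holds all
// candidate series at times 1..T-1 (one column per candidate); `sets` are
// 1-based column index vectors. When self_col > 0 every set is fitted
// both ways — without and with the self column appended — and the best
// set is retained independently under each toggle. Returns the energy of
// every (set, toggle) fit plus the parameters of the best fit per toggle.
// [[Rcpp::export(name = ".cpp_sa_enum_fit")]]
List cpp_sa_enum_fit(NumericVector y, NumericMatrix Xfull, List sets,
                     int self_col, double var, List ctrl) {
  SACtrl c = read_ctrl(ctrl);
  std::vector<double> dy = diff_series(y);
  const int Tp = Xfull.nrow();
  const int nsets = sets.size();
  const bool with_self = self_col > 0;
  NumericMatrix energies(nsets, 2);
  std::fill(energies.begin(), energies.end(), NA_REAL);

  RNGScope scope;
  std::vector<double> best_theta0, best_theta1;
  int best_i0 = -1, best_i1 = -1;
  double best_e0 = R_PosInf, best_e1 = R_PosInf;
  std::vector<double> D;

  for (int i = 0; i < nsets; ++i) {
    IntegerVector s = sets[i];
    const int d = s.size();
    for (int toggle = 0; toggle <= (with_self ? 1 : 0); ++toggle) {
      const int m = d + toggle;
      D.assign((size_t)Tp * std::max(m, 1), 0.0);
      for (int j = 0; j < d; ++j) {
        const int col = s[j] - 1;
        std::copy(&Xfull(0, col), &Xfull(0, col) + Tp, &D[(size_t)j * Tp]);
      }
      if (toggle == 1)
        std::copy(&Xfull(0, self_col - 1), &Xfull(0, self_col - 1) + Tp,
                  &D[(size_t)d * Tp]);
      FitResult r = sa_fit_core(dy, D.data(), Tp, m, var, c);
      energies(i, toggle) = r.energy;
      if (toggle == 0 && r.energy < best_e0) {
        best_e0 = r.energy; best_i0 = i; best_theta0 = r.theta;
      }
      if (toggle == 1 && r.energy < best_e1) {
        best_e1 = r.energy; best_i1 = i; best_theta1 = r.theta;
      }
    }
  }

  List out = List::create(
      _["energies"] = energies,
      _["best_set"] = IntegerVector::create(best_i0 + 1, best_i1 + 1),
      _["best_energy"] = NumericVector::create(
          best_e0, with_self ? best_e1 : NA_REAL),
      _["best_theta_noself"] = NumericVector(best_theta0.begin(), best_theta0.end()),
      _["best_theta_self"] = NumericVector(best_theta1.begin(), best_theta1.end()));
  return out;
}

// Forward simulation of a whole network, vectorised over replicates.
// W: (n+K) x n weight matrix (rows = regulator index over genes then
// factors, cols = target gene), alpha/beta: length n, Fser: the factor
// series actually driving each replicate as a flat (T x K x nsim)
// array, init: length n, sd_noise: length n (0 = noise free).
// Returns a numeric vector with dim (n, T, nsim).
// [[Rcpp::export(name = ".cpp_simulate")]]
NumericVector cpp_simulate(NumericMatrix W, NumericVector alpha,
                           NumericVector beta, NumericVector Fser,
                           NumericVector init, NumericVector sd_noise,
                           int T, int K, int nsim) {
  const int n = alpha.size();
  NumericVector out(Dimension(n, T, nsim));
  RNGScope scope;
  std::vector<double> state(n), incr(n);
  for (int s = 0; s < nsim; ++s) {
    const double* F = K > 0 ? &Fser[(size_t)T * K * s] : (double*)0;
    for (int i = 0; i < n; ++i) {
      state[i] = init[i];
      out[i + (size_t)n * (0 + (size_t)T * s)] = init[i];
    }
    for (int t = 1; t < T; ++t) {
      for (int i = 0; i < n; ++i) {
        double u = -beta[i];
        for (int j = 0; j < n; ++j) u += W(j, i) * state[j];
        for (int k = 0; k < K; ++k) u += W(n + k, i) * F[(t - 1) + (size_t)T * k];
        double v = state[i] + alpha[i] * std::tanh(u);
        if (sd_noise[i] > 0) v += sd_noise[i] * norm_rand();
        if (!R_finite(v))
          stop("trajectory diverged for gene %d at time %d", i + 1, t + 1);
        incr[i] = v;
      }
      for (int i = 0; i < n; ++i) {
        state[i] = incr[i];
        out[i + (size_t)n * ((size_t)t + (size_t)T * s)] = incr[i];
      }
    }
  }
  return out;
}
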