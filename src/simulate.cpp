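#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Network of exact mean-field E/I populations (quadratic integrate-and-fire
// reduction), one pair per region, coupled through the excitatory rates by a
// weighted directed structural connectivity matrix. Long-range excitation
// targets both the E population (gain G_ee) and the I population (gain
// Gamma * G_ee). Integration: deterministic Heun (predictor-corrector),
// fixed step dt, instantaneous coupling, no noise.
//
// State layout (length 8N): r_e, V_e, s_ee, s_ei, r_i, V_i, s_ie, s_ii,
// each a contiguous block of N regions.

struct Params {
  double tau_e, tau_i, tau_s;
  double delta_e, delta_i;
  double eta_e, eta_i;
  double J_ee, J_ii, J_ei, J_ie;
  double gamma_ratio, G_ee, I_ext;
};

static inline void derivs(const double *x, double *dx, int N,
                          const double *sc, const Params &p,
                          const double *stim) {
  const double *re = x,       *Ve = x + N,   *see = x + 2 * N, *sei = x + 3 * N;
  const double *ri = x + 4*N, *Vi = x + 5*N, *sie = x + 6 * N, *sii = x + 7 * N;
  double *dre = dx,         *dVe = dx + N,   *dsee = dx + 2*N, *dsei = dx + 3*N;
  double *dri = dx + 4*N,   *dVi = dx + 5*N, *dsie = dx + 6*N, *dsii = dx + 7*N;
  const double pi = M_PI;
  const double pi2 = pi * pi;
  for (int j = 0; j < N; ++j) {
    // long-range excitatory input: sum_k SC[j,k] * r_e[k] (j = target row)
    double coup = 0.0;
    const double *row = sc + (size_t)j; // column-major: SC[j + N*k]
    for (int k = 0; k < N; ++k) coup += row[(size_t)N * k] * re[k];
    double Istim = stim ? stim[j] : 0.0;

    dre[j] = (p.delta_e / (pi * p.tau_e) + 2.0 * Ve[j] * re[j]) / p.tau_e;
    dVe[j] = (Ve[j] * Ve[j] + p.eta_e + p.I_ext + Istim +
              p.tau_e * see[j] - p.tau_e * sei[j] -
              p.tau_e * p.tau_e * pi2 * re[j] * re[j]) / p.tau_e;
    dsee[j] = (-see[j] + p.J_ee * re[j] + p.G_ee * coup) / p.tau_s;
    dsei[j] = (-sei[j] + p.J_ei * ri[j]) / p.tau_s;

    dri[j] = (p.delta_i / (pi * p.tau_i) + 2.0 * Vi[j] * ri[j]) / p.tau_i;
    dVi[j] = (Vi[j] * Vi[j] + p.eta_i + p.I_ext + Istim +
              p.tau_i * sie[j] - p.tau_i * sii[j] -
              p.tau_i * p.tau_i * pi2 * ri[j] * ri[j]) / p.tau_i;
    dsie[j] = (-sie[j] + p.J_ie * re[j] + p.gamma_ratio * p.G_ee * coup) / p.tau_s;
    dsii[j] = (-sii[j] + p.J_ii * ri[j]) / p.tau_s;
  }
}

// [[Rcpp::export]]
List simulate_network_cpp(NumericMatrix sc, List params, NumericVector state0,
                          double dt, int downsample, int n_burn_steps,
                          int n_save,
                          IntegerVector stim_region,   // 0-based
                          IntegerVector stim_onset,    // integration step index
                          IntegerVector stim_nsteps,   // duration in steps
                          NumericVector stim_amp,
                          bool save_v, bool save_full) {
  int N = sc.nrow();
  if (sc.ncol() != N) stop("structural connectivity matrix must be square");
  if (state0.size() != 8 * N) stop("state vector must have length 8N");

  Params p;
  p.tau_e = params["tau_e"];   p.tau_i = params["tau_i"];
  p.tau_s = params["tau_s"];
  p.delta_e = params["delta_e"]; p.delta_i = params["delta_i"];
  p.eta_e = params["eta_e"];   p.eta_i = params["eta_i"];
  p.J_ee = params["J_ee"];     p.J_ii = params["J_ii"];
  p.J_ei = params["J_ei"];     p.J_ie = params["J_ie"];
  p.gamma_ratio = params["gamma_ratio"];
  p.G_ee = params["G_ee"];     p.I_ext = params["I_ext"];

  int n_stim = stim_region.size();
  std::vector<double> x(state0.begin(), state0.end());
  std::vector<double> k1(8 * N), k2(8 * N), xp(8 * N), stim(N, 0.0);

  NumericMatrix re_out(N, n_save);
  NumericMatrix ve_out(save_v ? N : 0, save_v ? n_save : 0);
  NumericMatrix vi_out(save_v ? N : 0, save_v ? n_save : 0);
  NumericMatrix full_out(save_full ? 8 * N : 0, save_full ? n_save : 0);

  long total_steps = (long)n_burn_steps + (long)n_save * downsample;
  int saved = 0;
  long next_save = n_burn_steps + downsample;
  int r_neg = 0;
  const double *scp = &sc[0];

  for (long step = 0; step < total_steps; ++step) {
    bool any_stim = false;
    if (n_stim > 0) {
      std::fill(stim.begin(), stim.end(), 0.0);
      for (int s = 0; s < n_stim; ++s) {
        if (step >= stim_onset[s] && step < stim_onset[s] + (long)stim_nsteps[s]) {
          stim[stim_region[s]] += stim_amp[s];
          any_stim = true;
        }
      }
    }
    const double *stp = any_stim ? stim.data() : (const double *)nullptr;
    derivs(x.data(), k1.data(), N, scp, p, stp);
    for (int i = 0; i < 8 * N; ++i) xp[i] = x[i] + dt * k1[i];
    derivs(xp.data(), k2.data(), N, scp, p, stp);
    for (int i = 0; i < 8 * N; ++i) x[i] += 0.5 * dt * (k1[i] + k2[i]);

    if (step + 1 == next_save) {
      for (int i = 0; i < 8 * N; ++i) {
        if (!std::isfinite(x[i])) {
          int var = i / N, reg = i % N;
          stop("non-finite state at time %g (step %ld), region %d, variable %d: "
               "numerical blow-up", (step + 1) * dt, step + 1, reg + 1, var + 1);
        }
      }
      for (int j = 0; j < N; ++j) {
        re_out(j, saved) = x[j];
        if (x[j] < 0 || x[4 * N + j] < 0) ++r_neg;
        if (save_v) { ve_out(j, saved) = x[N + j]; vi_out(j, saved) = x[5 * N + j]; }
      }
      if (save_full)
        for (int i = 0; i < 8 * N; ++i) full_out(i, saved) = x[i];
      ++saved;
      next_save += downsample;
    }
  }

  List out = List::create(_["re"] = re_out,
                          _["final_state"] = NumericVector(x.begin(), x.end()),
                          _["n_negative_rate"] = r_neg);
  if (save_v) { out["ve"] = ve_out; out["vi"] = vi_out; }
  if (save_full) out["full_state"] = full_out;
  return out;
}
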