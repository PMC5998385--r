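// 1D monodomain mMS cable solver with operator splitting:
// forward-Euler reaction substeps + Crank-Nicolson diffusion (Thomas solve,
// sealed/Neumann ends). Reproduces the S1S2 pacing protocol; the drive train
// is simulated once and branched at each s2 stimulus time so a whole
// restitution ladder costs one trunk plus short branches.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct MMS {
  double tau_in, tau_out, tau_open, tau_close, vgate;
};

// Crank-Nicolson tridiagonal system for (I - 0.5 r L) v+ = (I + 0.5 r L) v
// with Neumann (zero-flux) Laplacian L. The matrix is constant, so the
// Thomas forward-elimination coefficients are precomputed.
struct CNDiffusion {
  int n;
  double r;                    // D * dt_pde / dx^2
  std::vector<double> cp;      // precomputed c'_i
  std::vector<double> diag;    // A diagonal
  std::vector<double> off;     // A off-diagonal (constant -0.5 r)

  CNDiffusion(int n_, double r_) : n(n_), r(r_), cp(n_), diag(n_), off(n_, -0.5 * r_) {
    for (int i = 0; i < n; ++i)
      diag[i] = (i == 0 || i == n - 1) ? 1.0 + 0.5 * r : 1.0 + r;
    cp[0] = off[0] / diag[0];
    for (int i = 1; i < n; ++i)
      cp[i] = off[i] / (diag[i] - off[i] * cp[i - 1]);
  }

  void step(std::vector<double>& v, std::vector<double>& rhs, std::vector<double>& dp) const {
    // rhs = (I + 0.5 r L) v
    rhs[0] = v[0] + 0.5 * r * (v[1] - v[0]);
    for (int i = 1; i < n - 1; ++i)
      rhs[i] = v[i] + 0.5 * r * (v[i - 1] - 2.0 * v[i] + v[i + 1]);
    rhs[n - 1] = v[n - 1] + 0.5 * r * (v[n - 2] - v[n - 1]);
    // Thomas solve
    dp[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i)
      dp[i] = (rhs[i] - off[i] * dp[i - 1]) / (diag[i] - off[i] * cp[i - 1]);
    v[n - 1] = dp[n - 1];
    for (int i = n - 2; i >= 0; --i)
      v[i] = dp[i] - cp[i] * v[i + 1];
  }
};

inline double ion(double vm, double h, const MMS& p) {
  return h * vm * (vm - p.vgate) * (1.0 - vm) / p.tau_in - vm / p.tau_out;
}
inline double gate(double vm, double h, const MMS& p) {
  return (vm < p.vgate) ? (1.0 - h) / p.tau_open : -h / p.tau_close;
}

// is any stimulus active at time t? stim_times sorted not required
inline bool stim_active(double t, const std::vector<double>& on, double dur) {
  for (double t0 : on)
    if (t >= t0 && t < t0 + dur) return true;
  return false;
}

struct Recorder {
  std::vector<double> time;
  std::vector<double> samples;  // row-major: per time, one value per sample site
  std::vector<double> vmean;
  const std::vector<int>& idx;
  explicit Recorder(const std::vector<int>& idx_) : idx(idx_) {}
  void record(double t, const std::vector<double>& vm) {
    time.push_back(t);
    double s = 0.0;
    for (double v : vm) s += v;
    vmean.push_back(s / vm.size());
    for (int j : idx) samples.push_back(vm[j]);
  }
};

void advance(std::vector<double>& vm, std::vector<double>& h, double& t,
             double t_to, const MMS& p, const CNDiffusion& cn,
             int n_stim_nodes, double stim_amp, double stim_dur,
             const std::vector<double>& stim_on,
             double dt_ode, double dt_pde, int nsub,
             Recorder* rec,
             std::vector<double>& rhs, std::vector<double>& dp) {
  const int n = (int)vm.size();
  long nsteps = (long)std::llround((t_to - t) / dt_pde);
  for (long s = 0; s < nsteps; ++s) {
    for (int k = 0; k < nsub; ++k) {
      double tk = t + k * dt_ode;
      bool act = stim_active(tk, stim_on, stim_dur);
      for (int i = 0; i < n; ++i) {
        double dv = ion(vm[i], h[i], p);
        if (act && i < n_stim_nodes) dv += stim_amp;
        double dh = gate(vm[i], h[i], p);
        vm[i] += dt_ode * dv;
        h[i] += dt_ode * dh;
      }
    }
    cn.step(vm, rhs, dp);
    t += dt_pde;
    for (int i = 0; i < n; ++i)
      if (!std::isfinite(vm[i]) || std::fabs(vm[i]) > 10.0)
        stop("cable solver instability (|vm| > 10): dt_ode = %f ms, dt_pde = %f ms are too large for these parameters",
             dt_ode, dt_pde);
    if (rec) rec->record(t, vm);
  }
}

List pack(const Recorder& rec, int nsamp) {
  int nt = (int)rec.time.size();
  NumericMatrix vm(nt, nsamp);
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < nsamp; ++j)
      vm(i, j) = rec.samples[(size_t)i * nsamp + j];
  return List::create(_["time"] = NumericVector(rec.time.begin(), rec.time.end()),
                      _["vm"] = vm,
                      _["vm_mean"] = NumericVector(rec.vmean.begin(), rec.vmean.end()));
}

}  // namespace

// [[Rcpp::export]]
List cable_ladder_cpp(NumericVector tau, double vgate, double D,
                      int n_nodes, double dx_cm,
                      double dt_ode_ms, double dt_pde_ms,
                      double stim_len_cm, double stim_amp, double stim_dur_ms,
                      NumericVector drive_times, NumericVector branch_times,
                      double post_ms, IntegerVector sample_idx0) {
  MMS p{tau[0], tau[1], tau[2], tau[3], vgate};
  int nsub = (int)std::llround(dt_pde_ms / dt_ode_ms);
  if (nsub < 1 || std::fabs(nsub * dt_ode_ms - dt_pde_ms) > 1e-9)
    stop("dt_pde must be an integer multiple of dt_ode");
  CNDiffusion cn(n_nodes, D * dt_pde_ms / (dx_cm * dx_cm));
  int n_stim_nodes = std::max(1, (int)std::llround(stim_len_cm / dx_cm));

  std::vector<int> sidx(sample_idx0.begin(), sample_idx0.end());
  std::vector<double> drive(drive_times.begin(), drive_times.end());
  std::vector<double> vm(n_nodes, 0.0), h(n_nodes, 1.0);
  std::vector<double> rhs(n_nodes), dp(n_nodes);

  // branch times must be ascending for sequential checkpointing
  std::vector<double> bt(branch_times.begin(), branch_times.end());
  for (size_t i = 1; i < bt.size(); ++i)
    if (bt[i] <= bt[i - 1]) stop("branch times must be strictly ascending");

  Recorder trunk(sidx);
  double t = 0.0;
  trunk.record(t, vm);

  List branches(bt.size());
  for (size_t k = 0; k < bt.size(); ++k) {
    advance(vm, h, t, bt[k], p, cn, n_stim_nodes, stim_amp, stim_dur_ms,
            drive, dt_ode_ms, dt_pde_ms, nsub, &trunk, rhs, dp);
    // branch: copy state, add the premature stimulus at t, run post_ms
    std::vector<double> vb = vm, hb = h;
    double tb = t;
    std::vector<double> stim_on = drive;
    stim_on.push_back(tb);
    Recorder brec(sidx);
    advance(vb, hb, tb, tb + post_ms, p, cn, n_stim_nodes, stim_amp,
            stim_dur_ms, stim_on, dt_ode_ms, dt_pde_ms, nsub, &brec, rhs, dp);
    branches[k] = pack(brec, (int)sidx.size());
  }
  if (bt.empty()) {
    // no premature beat: just run the drive train plus post window
    double t_end = (drive.empty() ? 0.0 : drive.back()) + post_ms;
    advance(vm, h, t, t_end, p, cn, n_stim_nodes, stim_amp, stim_dur_ms,
            drive, dt_ode_ms, dt_pde_ms, nsub, &trunk, rhs, dp);
  }
  return List::create(_["trunk"] = pack(trunk, (int)sidx.size()),
                      _["branches"] = branches);
}
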