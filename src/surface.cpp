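// Isotropic monodomain on a triangulated surface, P1 finite elements with
// lumped mass. Operator splitting: forward-Euler reaction (per-vertex mMS
// parameters), Crank-Nicolson diffusion solved with Jacobi-preconditioned
// conjugate gradients on the constant SPD system (M/dt + K/2).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct CSR {
  const int* p;     // row pointers, length n+1
  const int* j;     // column indices
  const double* x;  // values
  int n;
  void mult(const std::vector<double>& v, std::vector<double>& out) const {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = p[i]; k < p[i + 1]; ++k) s += x[k] * v[j[k]];
      out[i] = s;
    }
  }
};

// CG solve A z = b where A(v) = (M/dt) v + 0.5 K v; diag = M/dt + 0.5 diag(K)
struct CNSolver {
  CSR K;
  std::vector<double> mdt, diag_inv;
  double half = 0.5;
  int n;
  std::vector<double> r, z, pv, Ap;

  void init(CSR K_, const std::vector<double>& mass, double dt) {
    K = K_; n = K.n;
    mdt.resize(n); diag_inv.resize(n);
    r.resize(n); z.resize(n); pv.resize(n); Ap.resize(n);
    for (int i = 0; i < n; ++i) {
      mdt[i] = mass[i] / dt;
      double kd = 0.0;
      for (int k = K.p[i]; k < K.p[i + 1]; ++k)
        if (K.j[k] == i) kd = K.x[k];
      diag_inv[i] = 1.0 / (mdt[i] + half * kd);
    }
  }
  void applyA(const std::vector<double>& v, std::vector<double>& out) {
    K.mult(v, out);
    for (int i = 0; i < n; ++i) out[i] = mdt[i] * v[i] + half * out[i];
  }
  // rhs = (M/dt) v - 0.5 K v; then solve in place into v (warm start = v)
  void step(std::vector<double>& v, std::vector<double>& rhs) {
    K.mult(v, rhs);
    for (int i = 0; i < n; ++i) rhs[i] = mdt[i] * v[i] - half * rhs[i];
    // CG on A z = rhs, start z = v
    applyA(v, Ap);
    double rn2 = 0.0, bn2 = 0.0;
    for (int i = 0; i < n; ++i) {
      r[i] = rhs[i] - Ap[i];
      bn2 += rhs[i] * rhs[i];
    }
    double tol2 = 1e-16 * (bn2 > 0 ? bn2 : 1.0);
    for (int i = 0; i < n; ++i) { z[i] = r[i] * diag_inv[i]; pv[i] = z[i]; }
    double rz = 0.0;
    for (int i = 0; i < n; ++i) rz += r[i] * z[i];
    for (int it = 0; it < 200; ++it) {
      rn2 = 0.0;
      for (int i = 0; i < n; ++i) rn2 += r[i] * r[i];
      if (rn2 <= tol2) break;
      applyA(pv, Ap);
      double pAp = 0.0;
      for (int i = 0; i < n; ++i) pAp += pv[i] * Ap[i];
      double alpha = rz / pAp;
      for (int i = 0; i < n; ++i) { v[i] += alpha * pv[i]; r[i] -= alpha * Ap[i]; }
      double rz_new = 0.0;
      for (int i = 0; i < n; ++i) { z[i] = r[i] * diag_inv[i]; rz_new += r[i] * z[i]; }
      double beta = rz_new / rz; rz = rz_new;
      for (int i = 0; i < n; ++i) pv[i] = z[i] + beta * pv[i];
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List surface_run_cpp(IntegerVector Kp, IntegerVector Kj, NumericVector Kx,
                     NumericVector mass,
                     NumericVector tau_in, NumericVector tau_out,
                     NumericVector tau_open, NumericVector tau_close,
                     double vgate,
                     IntegerVector stim_idx0, double stim_amp, double stim_dur,
                     NumericVector stim_times,
                     double t_end, double dt_ode, double dt_pde,
                     double lat_window_start, double lat_thresh,
                     IntegerVector record_idx0) {
  const int n = mass.size();
  CSR K{Kp.begin(), Kj.begin(), Kx.begin(), n};
  int nsub = (int)std::llround(dt_pde / dt_ode);
  if (nsub < 1 || std::fabs(nsub * dt_ode - dt_pde) > 1e-9)
    stop("dt_pde must be an integer multiple of dt_ode");

  std::vector<double> massv(mass.begin(), mass.end());
  CNSolver cn; cn.init(K, massv, dt_pde);

  std::vector<double> vm(n, 0.0), h(n, 1.0), rhs(n), prev(n);
  std::vector<char> is_stim(n, 0);
  for (int s : stim_idx0) is_stim[s] = 1;
  std::vector<double> stim_on(stim_times.begin(), stim_times.end());

  std::vector<double> lat(n, NA_REAL);
  long nsteps = (long)std::llround(t_end / dt_pde);
  int nrec = record_idx0.size();
  NumericMatrix traces(nsteps + 1, nrec);
  NumericVector times(nsteps + 1);
  for (int j = 0; j < nrec; ++j) traces(0, j) = 0.0;
  times[0] = 0.0;

  double t = 0.0;
  for (long s = 0; s < nsteps; ++s) {
    prev = vm;  // state at the start of the step, for crossing detection
    for (int k = 0; k < nsub; ++k) {
      double tk = t + k * dt_ode;
      bool act = false;
      for (double t0 : stim_on)
        if (tk >= t0 && tk < t0 + stim_dur) { act = true; break; }
      for (int i = 0; i < n; ++i) {
        double v = vm[i], hh = h[i];
        double dv = hh * v * (v - vgate) * (1.0 - v) / tau_in[i] - v / tau_out[i];
        if (act && is_stim[i]) dv += stim_amp;
        double dh = (v < vgate) ? (1.0 - hh) / tau_open[i] : -hh / tau_close[i];
        vm[i] += dt_ode * dv;
        h[i] += dt_ode * dh;
      }
    }
    cn.step(vm, rhs);
    t += dt_pde;
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(vm[i]) || std::fabs(vm[i]) > 10.0)
        stop("surface solver instability (|vm| > 10) at t = %f ms: dt_ode = %f, dt_pde = %f ms",
             t, dt_ode, dt_pde);
      if (t >= lat_window_start && ISNA(lat[i]) &&
          prev[i] < lat_thresh && vm[i] >= lat_thresh)
        lat[i] = t;
    }
    times[s + 1] = t;
    for (int j = 0; j < nrec; ++j) traces(s + 1, j) = vm[record_idx0[j]];
  }
  return List::create(_["lat"] = NumericVector(lat.begin(), lat.end()),
                      _["time"] = times, _["traces"] = traces);
}
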