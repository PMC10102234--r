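// Explicit-Euler integrators for the delayed PSM model.
//
// The tissue integrator mirrors step_tissue() in R/tissue.R operation for
// operation: per-cell Euler updates from ring-buffer delay histories,
// prescribed dpErk field, and advection as an exact one-index shift every
// dx/u minutes (the new posterior cell copies its anterior neighbour's
// state and full history). The R stepper is the reference; this is the
// production engine.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

// (y/K)^n with fast paths for the small integer exponents the model uses
static inline double hpow(double y, double K, double n) {
  double t = y / K;
  if (n == 2.0) return t * t;
  if (n == 4.0) { double s = t * t; return s * s; }
  if (n == 1.0) return t;
  if (n == 3.0) return t * t * t;
  return std::pow(t, n);
}
static inline double hill_act(double y, double K, double n) {
  double r = hpow(y, K, n);
  return r / (1.0 + r);
}
static inline double hill_rep(double y, double K, double n) {
  return 1.0 / (1.0 + hpow(y, K, n));
}

struct Pars {
  double L, dx, u, dt, t_warmup;
  int N;
  double mu1, mu_sh, mu_sr, mu2, mu3, mu4, mu5;
  double nu1, nu2, nu3, nu_e, q;
  double K1, K2, K3, K4, K5, K6, K_FA, K_FR;
  double n1, n2, n3, n4, n5, n6, nA, nR;
  double tau_h, tau_r, tau_H0, tau_HL, tau_R;
  double x_h, gamma, eta, F0, x_f;
  double x_E, delta, x_e0;
  bool stepwise;
  double her_tx_mult, pfl_mult;
};

static Pars read_pars(const List& p) {
  Pars q;
  q.L = p["L"]; q.dx = p["dx"]; q.u = p["u"]; q.dt = p["dt"];
  q.t_warmup = p["t_warmup"]; q.N = as<int>(p["N"]);
  q.mu1 = p["mu1"]; q.mu_sh = p["mu_sh"]; q.mu_sr = p["mu_sr"];
  q.mu2 = p["mu2"]; q.mu3 = p["mu3"]; q.mu4 = p["mu4"]; q.mu5 = p["mu5"];
  q.nu1 = p["nu1"]; q.nu2 = p["nu2"]; q.nu3 = p["nu3"]; q.nu_e = p["nu_e"];
  q.q = p["q"];
  q.K1 = p["K1"]; q.K2 = p["K2"]; q.K3 = p["K3"]; q.K4 = p["K4"];
  q.K5 = p["K5"]; q.K6 = p["K6"]; q.K_FA = p["K_FA"]; q.K_FR = p["K_FR"];
  q.n1 = p["n1"]; q.n2 = p["n2"]; q.n3 = p["n3"]; q.n4 = p["n4"];
  q.n5 = p["n5"]; q.n6 = p["n6"]; q.nA = p["nA"]; q.nR = p["nR"];
  q.tau_h = p["tau_h"]; q.tau_r = p["tau_r"]; q.tau_H0 = p["tau_H0"];
  q.tau_HL = p["tau_HL"]; q.tau_R = p["tau_R"];
  q.x_h = p["x_h"]; q.gamma = p["gamma"]; q.eta = p["eta"];
  q.F0 = p["F0"]; q.x_f = p["x_f"];
  q.x_E = p["x_E"]; q.delta = p["delta"]; q.x_e0 = p["x_e0"];
  q.stepwise = as<std::string>(p["erk_mode"]) == "stepwise";
  q.her_tx_mult = p["her_tx_mult"]; q.pfl_mult = p["pfl_mult"];
  return q;
}

// shift all columns one index anteriorly; the new posterior cell keeps a
// copy of the old posterior cell (its nearest anterior neighbour after the
// shift)
static inline void shift_left(std::vector<double>& v, int H, int N) {
  // v is H x N column-major
  for (int j = 0; j + 1 < N; ++j)
    std::memcpy(&v[(size_t)j * H], &v[(size_t)(j + 1) * H],
                sizeof(double) * H);
}

// [[Rcpp::export]]
List psm_simulate_cpp(List pars, double t_end, double record_every) {
  Pars p = read_pars(pars);
  const int N = p.N;
  const double dt = p.dt;

  const int kh = (int)std::lround(p.tau_h / dt);
  const int kr = (int)std::lround(p.tau_r / dt);
  const int kR = (int)std::lround(p.tau_R / dt);
  std::vector<int> kH(N);
  std::vector<double> x(N), Fx(N);
  int kmax = std::max(kh, std::max(kr, kR));
  for (int j = 0; j < N; ++j) {
    x[j] = j * p.dx;
    Fx[j] = p.F0 * std::exp(-(p.L - x[j]) / p.x_f);
    double tH = p.tau_H0 + (p.tau_HL - p.tau_H0) * x[j] / p.L;
    kH[j] = (int)std::lround(tH / dt);
    if (kH[j] > kmax) kmax = kH[j];
  }
  const int H = kmax + 1;

  const long warm_steps = (long)std::lround(p.t_warmup / dt);
  const long run_steps = (long)std::lround(t_end / dt);
  const long rec_steps = (long)std::lround(record_every / dt);
  if (rec_steps <= 0) stop("record_every must be a positive multiple of dt");
  const long shift_every = (long)std::lround(p.dx / p.u / dt);
  const long total = warm_steps + run_steps;
  const int nrec = (int)(run_steps / rec_steps) + 1;

  // state
  std::vector<double> m_h(N, 1.0), M_h(N, 1.0), m_r(N, 0.0), M_r(N, 0.0),
      p_h(N, p.nu2 / p.mu4), p_r(N, 0.0), p_t(N), p_e(N);
  double xe = p.stepwise ? p.x_e0 : p.x_E;
  for (int j = 0; j < N; ++j) {
    p_t[j] = (x[j] <= p.x_h) ? 1.0 : 0.0;
    p_e[j] = (x[j] < xe) ? 0.0 : p.nu_e * (1.0 - std::exp(-p.q * (x[j] - xe)));
  }

  // ring buffers, H x N column-major, pre-filled with the initial history
  auto fill = [&](const std::vector<double>& v) {
    std::vector<double> b((size_t)H * N);
    for (int j = 0; j < N; ++j)
      for (int r = 0; r < H; ++r) b[(size_t)j * H + r] = v[j];
    return b;
  };
  std::vector<double> h_ph = fill(p_h), h_pt = fill(p_t), h_pe = fill(p_e),
      h_Mh = fill(M_h), h_Mr = fill(M_r);

  NumericMatrix R_mh(nrec, N), R_Mh(nrec, N), R_mr(nrec, N), R_Mr(nrec, N),
      R_ph(nrec, N), R_pr(nrec, N), R_pt(nrec, N), R_pe(nrec, N);
  NumericVector R_t(nrec), R_xe(nrec);
  long clamped = 0, shifts = 0;
  int irec = 0;

  auto record = [&](long s) {
    for (int j = 0; j < N; ++j) {
      R_mh(irec, j) = m_h[j]; R_Mh(irec, j) = M_h[j];
      R_mr(irec, j) = m_r[j]; R_Mr(irec, j) = M_r[j];
      R_ph(irec, j) = p_h[j]; R_pr(irec, j) = p_r[j];
      R_pt(irec, j) = p_t[j]; R_pe(irec, j) = p_e[j];
    }
    R_t[irec] = (s - warm_steps) * dt;
    R_xe[irec] = xe;
    ++irec;
  };
  if (warm_steps == 0) record(0);

  for (long s = 0; s < total; ++s) {
    const int r_h = (int)(((s - kh) % H + H) % H);
    const int r_r = (int)(((s - kr) % H + H) % H);
    const int r_R = (int)(((s - kR) % H + H) % H);
    for (int j = 0; j < N; ++j) {
      const size_t col = (size_t)j * H;
      const double ph_h = h_ph[col + r_h], pt_h = h_pt[col + r_h];
      const double ph_r = h_ph[col + r_r], pt_r = h_pt[col + r_r];
      const double pe_r = h_pe[col + r_r];
      const int r_H = (int)(((s - kH[j]) % H + H) % H);
      const double Mh_H = h_Mh[col + r_H];
      const double Mr_R = h_Mr[col + r_R];

      const double gate = (x[j] <= p.x_h) ? hill_act(pt_h, p.K2, p.n2) : 1.0;
      const double tx_h = p.her_tx_mult * hill_rep(ph_h, p.K1, p.n1) * gate;
      const double tx_r = p.nu1 * hill_rep(ph_r, p.K3, p.n3) *
                          hill_rep(pe_r, p.K4, p.n4) *
                          hill_act(pt_r, p.K5, p.n5);
      const double P = p.pfl_mult * hill_act(p_t[j], p.K6, p.n6) +
                       p.gamma * hill_rep(Fx[j], p.K_FR, p.nR) *
                           hill_act(Fx[j], p.K_FA, p.nA);

      double nv[7] = {
        m_h[j] + dt * (p.mu1 * (tx_h - p.mu_sh * m_h[j])),
        M_h[j] + dt * (p.mu1 * (p.mu_sh * m_h[j] - M_h[j])),
        p_h[j] + dt * (p.mu3 * (p.nu2 * Mh_H - p.mu4 * p_h[j])),
        m_r[j] + dt * (p.mu1 * (tx_r - p.mu_sr * m_r[j])),
        M_r[j] + dt * (p.mu1 * (p.mu_sr * m_r[j] - p.mu2 * M_r[j])),
        p_r[j] + dt * (p.mu3 * (p.nu3 * Mr_R - p.mu5 * p_r[j])),
        p_t[j] + dt * (p.mu3 * (P - (1.0 + p.eta * p_r[j]) * p_t[j]))
      };
      static const char* vn[7] = {"m_h", "M_h", "p_h", "m_r", "M_r", "p_r", "p_t"};
      for (int v = 0; v < 7; ++v) {
        if (!std::isfinite(nv[v]))
          stop("non-finite state: %s, cell %d, t = %g", vn[v], j + 1,
               (s + 1) * dt - p.t_warmup);
        if (nv[v] < 0.0) {
          if (nv[v] < -1e-9)
            stop("state went negative beyond tolerance: %s, cell %d, t = %g",
                 vn[v], j + 1, (s + 1) * dt - p.t_warmup);
          nv[v] = 0.0;
          ++clamped;
        }
      }
      m_h[j] = nv[0]; M_h[j] = nv[1]; p_h[j] = nv[2];
      m_r[j] = nv[3]; M_r[j] = nv[4]; p_r[j] = nv[5]; p_t[j] = nv[6];
    }
    const long s1 = s + 1;
    if (p.stepwise) {
      xe -= p.u * dt;
      if (xe <= p.x_E - p.delta + 1e-9) xe = p.x_E;
    }
    const int row = (int)(s1 % H);
    for (int j = 0; j < N; ++j) {
      p_e[j] = (x[j] < xe) ? 0.0 : p.nu_e * (1.0 - std::exp(-p.q * (x[j] - xe)));
      const size_t col = (size_t)j * H;
      h_ph[col + row] = p_h[j]; h_pt[col + row] = p_t[j];
      h_pe[col + row] = p_e[j]; h_Mh[col + row] = M_h[j];
      h_Mr[col + row] = M_r[j];
    }
    if (s1 % shift_every == 0) {
      auto sl = [&](std::vector<double>& v) {
        for (int j = 0; j + 1 < N; ++j) v[j] = v[j + 1];
      };
      sl(m_h); sl(M_h); sl(m_r); sl(M_r); sl(p_h); sl(p_r); sl(p_t); sl(p_e);
      shift_left(h_ph, H, N); shift_left(h_pt, H, N); shift_left(h_pe, H, N);
      shift_left(h_Mh, H, N); shift_left(h_Mr, H, N);
      ++shifts;
    }
    if (s1 >= warm_steps && (s1 - warm_steps) % rec_steps == 0 && irec < nrec)
      record(s1);
    if (s % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["times"] = R_t, _["xe"] = R_xe,
    _["m_h"] = R_mh, _["M_h"] = R_Mh, _["m_r"] = R_mr, _["M_r"] = R_Mr,
    _["p_h"] = R_ph, _["p_r"] = R_pr, _["p_t"] = R_pt, _["p_e"] = R_pe,
    _["clamped"] = (double)clamped, _["shifts"] = (double)shifts);
}

// Single-cell her subsystem (nascent/mature mRNA + protein) at a fixed
// Tbx6 gate and fixed translational delay; used for the oscillation scan
// and for period calibration. Returns p_h sampled every record_every.
// [[Rcpp::export]]
NumericVector her_cell_cpp(List pars, double gate, double tau_H,
                           double t_end, double record_every) {
  Pars p = read_pars(pars);
  const double dt = p.dt;
  const int kh = (int)std::lround(p.tau_h / dt);
  const int kHd = (int)std::lround(tau_H / dt);
  const int H = std::max(kh, kHd) + 1;
  const long total = (long)std::lround(t_end / dt);
  const long rec = (long)std::lround(record_every / dt);
  if (rec <= 0) stop("record_every must be a positive multiple of dt");

  double m = 1.0, M = 1.0, ph = p.nu2 / p.mu4;
  std::vector<double> h_ph(H, ph), h_M(H, M);
  const int nrec = (int)(total / rec) + 1;
  NumericVector out(nrec);
  int irec = 0;
  out[irec++] = ph;
  for (long s = 0; s < total; ++s) {
    const double ph_d = h_ph[((s - kh) % H + H) % H];
    const double M_d = h_M[((s - kHd) % H + H) % H];
    const double tx = p.her_tx_mult * hill_rep(ph_d, p.K1, p.n1) * gate;
    double nm = m + dt * (p.mu1 * (tx - p.mu_sh * m));
    double nM = M + dt * (p.mu1 * (p.mu_sh * m - M));
    double np = ph + dt * (p.mu3 * (p.nu2 * M_d - p.mu4 * ph));
    if (nm < 0) nm = 0; if (nM < 0) nM = 0; if (np < 0) np = 0;
    m = nm; M = nM; ph = np;
    const long s1 = s + 1;
    const int row = (int)(s1 % H);
    h_ph[row] = ph; h_M[row] = M;
    if (s1 % rec == 0 && irec < nrec) out[irec++] = ph;
  }
  return out;
}
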