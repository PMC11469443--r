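// Core simulators: exact Gillespie direct method and its differentiable
// (smoothed) counterpart, with forward-mode pathwise sensitivities w.r.t.
// the kinetic parameters propagated alongside the state.
//
// Reaction propensities are restricted to smooth products
//   r_i = theta[p1] * (theta[p2]) * mult_i * (x[sp_i])
// where the second parameter, the external multiplier and the species factor
// are each optional. This covers constant, linear-in-one-species and
// concentration-scaled rate laws.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-style splittable RNG: splitmix64 seeding + xoshiro256++ streams.
// Deterministic across platforms (no std:: distributions involved).
// ---------------------------------------------------------------------------
namespace {

inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1]: never returns 0, so log(u) is always finite
  inline double unif() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
};

// per-trajectory substream derived from a master seed
inline uint64_t stream_seed(double master, int traj) {
  uint64_t base = (uint64_t)((int64_t)master);
  return base ^ (0x9e3779b97f4a7c15ULL * (uint64_t)(traj + 1));
}

struct Net {
  int nR, nS;
  const int *S;        // nR x nS, row-major access via S[i*nS + a]
  std::vector<int> p1, p2, sp, form;
  std::vector<double> mult;
};

Net unpack_net(const IntegerMatrix &Smat, const IntegerVector &form,
               const IntegerVector &p1, const IntegerVector &p2,
               const IntegerVector &sp, const NumericVector &mult,
               std::vector<int> &Sbuf) {
  Net net;
  net.nR = Smat.nrow();
  net.nS = Smat.ncol();
  Sbuf.resize((size_t)net.nR * net.nS);
  for (int i = 0; i < net.nR; ++i)
    for (int a = 0; a < net.nS; ++a) Sbuf[(size_t)i * net.nS + a] = Smat(i, a);
  net.S = Sbuf.data();
  net.form.assign(form.begin(), form.end());
  net.p1.assign(p1.begin(), p1.end());
  net.p2.assign(p2.begin(), p2.end());
  net.sp.assign(sp.begin(), sp.end());
  net.mult.assign(mult.begin(), mult.end());
  return net;
}

// propensities; returns total rate
inline double propensities(const Net &net, const double *x,
                           const double *theta, double *r) {
  double R = 0.0;
  for (int i = 0; i < net.nR; ++i) {
    double v = theta[net.p1[i]] * net.mult[i];
    if (net.p2[i] >= 0) v *= theta[net.p2[i]];
    if (net.form[i] == 1) v *= x[net.sp[i]];
    if (v < 0.0) v = 0.0;  // linear laws can see tiny negative species
    r[i] = v;
    R += v;
  }
  return R;
}

// smooth nonnegativity clamp: softplus with sharpness k (value and slope)
const double CLAMP_K = 1e3;
inline double softplus_clamp(double x, double &slope) {
  double z = CLAMP_K * x;
  if (z > 30.0) {
    slope = 1.0;
    return x;
  }
  if (z < -30.0) {
    slope = std::exp(z);
    return std::exp(z) / CLAMP_K;
  }
  slope = 1.0 / (1.0 + std::exp(-z));
  return std::log1p(std::exp(z)) / CLAMP_K;
}

inline double sigmoid(double z) {
  if (z > 35.0) return 1.0;
  if (z < -35.0) return std::exp(z);
  return 1.0 / (1.0 + std::exp(-z));
}

// two-sided smooth clamp to [0, 1] for promoter-indicator species (a single
// promoter copy's state occupancies are bounded by construction; keeping
// them bounded prevents runaway mass creation from soft selection near
// cumulative-fraction ties)
inline double softplus_clamp01(double x, double &slope) {
  double s1, s2;
  double y = softplus_clamp(x, s1);
  double z = 1.0 - softplus_clamp(1.0 - y, s2);
  slope = s1 * s2;
  return z;
}

}  // namespace

// ---------------------------------------------------------------------------
// Exact Gillespie, batched: final states + time-averaged state at horizon T.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_simulate_exact(IntegerMatrix Smat, IntegerVector form,
                        IntegerVector p1, IntegerVector p2, IntegerVector sp,
                        NumericVector mult, NumericVector theta,
                        NumericVector x0, double T, int n_traj, double seed,
                        double max_events) {
  std::vector<int> Sbuf;
  Net net = unpack_net(Smat, form, p1, p2, sp, mult, Sbuf);
  const int nS = net.nS, nR = net.nR;

  NumericMatrix final_states(n_traj, nS), timeavg(n_traj, nS);
  NumericVector nevents(n_traj);
  LogicalVector absorbed(n_traj), truncated(n_traj);

  std::vector<double> x(nS), r(nR), avg(nS);
  std::vector<double> th(theta.begin(), theta.end());

  for (int A = 0; A < n_traj; ++A) {
    Xoshiro rng(stream_seed(seed, A));
    for (int a = 0; a < nS; ++a) {
      x[a] = x0[a];
      avg[a] = 0.0;
    }
    double t = 0.0, nev = 0.0;
    bool abs_flag = false, trunc_flag = false;
    while (t < T) {
      double R = propensities(net, x.data(), th.data(), r.data());
      if (R <= 0.0) {  // absorbing: hold state to the horizon
        abs_flag = true;
        for (int a = 0; a < nS; ++a) avg[a] += x[a] * (T - t);
        t = T;
        break;
      }
      double u = rng.unif();
      double tau = -std::log(u) / R;
      if (t + tau >= T) {  // state holds through the horizon
        for (int a = 0; a < nS; ++a) avg[a] += x[a] * (T - t);
        t = T;
        break;
      }
      for (int a = 0; a < nS; ++a) avg[a] += x[a] * tau;
      t += tau;
      double uprime = rng.unif();
      double target = uprime * R, csum = 0.0;
      int chosen = nR - 1;
      for (int i = 0; i < nR; ++i) {
        csum += r[i];
        if (csum > target) {
          chosen = i;
          break;
        }
      }
      for (int a = 0; a < nS; ++a) x[a] += net.S[(size_t)chosen * nS + a];
      nev += 1.0;
      if (nev >= max_events) {
        trunc_flag = true;
        for (int a = 0; a < nS; ++a) avg[a] += x[a] * (T - t);
        t = T;
        break;
      }
    }
    for (int a = 0; a < nS; ++a) {
      final_states(A, a) = x[a];
      timeavg(A, a) = avg[a] / T;
    }
    nevents[A] = nev;
    absorbed[A] = abs_flag;
    truncated[A] = trunc_flag;
  }
  return List::create(_["final"] = final_states, _["timeavg"] = timeavg,
                      _["nevents"] = nevents, _["absorbed"] = absorbed,
                      _["truncated"] = truncated);
}

// ---------------------------------------------------------------------------
// Exact Gillespie, single trajectory with the full event record.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_simulate_exact_events(IntegerMatrix Smat, IntegerVector form,
                               IntegerVector p1, IntegerVector p2,
                               IntegerVector sp, NumericVector mult,
                               NumericVector theta, NumericVector x0, double T,
                               double seed, double max_events) {
  std::vector<int> Sbuf;
  Net net = unpack_net(Smat, form, p1, p2, sp, mult, Sbuf);
  const int nS = net.nS, nR = net.nR;

  std::vector<double> x(nS), r(nR);
  std::vector<double> th(theta.begin(), theta.end());
  for (int a = 0; a < nS; ++a) x[a] = x0[a];
  std::vector<double> times;
  std::vector<int> reactions;
  std::vector<double> states;  // row-major, appended per event
  times.push_back(0.0);
  reactions.push_back(NA_INTEGER);
  for (int a = 0; a < nS; ++a) states.push_back(x[a]);

  Xoshiro rng(stream_seed(seed, 0));
  double t = 0.0;
  bool abs_flag = false;
  while (t < T && (double)times.size() < max_events + 1.0) {
    double R = propensities(net, x.data(), th.data(), r.data());
    if (R <= 0.0) {
      abs_flag = true;
      break;
    }
    double u = rng.unif();
    double tau = -std::log(u) / R;
    if (t + tau >= T) break;
    t += tau;
    double uprime = rng.unif();
    double target = uprime * R, csum = 0.0;
    int chosen = nR - 1;
    for (int i = 0; i < nR; ++i) {
      csum += r[i];
      if (csum > target) {
        chosen = i;
        break;
      }
    }
    for (int a = 0; a < nS; ++a) x[a] += net.S[(size_t)chosen * nS + a];
    times.push_back(t);
    reactions.push_back(chosen + 1);
    for (int a = 0; a < nS; ++a) states.push_back(x[a]);
  }
  int nrow = (int)times.size();
  NumericMatrix smat(nrow, nS);
  for (int k = 0; k < nrow; ++k)
    for (int a = 0; a < nS; ++a) smat(k, a) = states[(size_t)k * nS + a];
  return List::create(_["time"] = wrap(times), _["reaction"] = wrap(reactions),
                      _["states"] = smat, _["absorbed"] = abs_flag);
}

// ---------------------------------------------------------------------------
// Differentiable Gillespie, batched, with optional forward sensitivities.
//
// Per step (common random numbers u, u'):
//   tau  = -log(u) / (R + rate_floor)
//   q_i  = cumulative propensity fractions (i = 1..N-1)
//   i'   = 1 + sum_i sigmoid((u' - q_i) / a)
//   x    <- x + sum_j exp(-(i' - j)^2 / b) * S_j, then smooth clamp at 0
// Occupancy accumulates (clamped indicator species / their sum) * tau and is
// finally divided by the total elapsed time.
//
// Besides the raw final state (one soft update past the horizon), a smooth
// snapshot "readout" at time T is returned: the state before the crossing
// dwell linearly time-interpolated toward the post-crossing state,
//   readout = x_prev + s * (x_final - x_prev),  s = (T - t_prev)/tau_cross.
// Unlike the raw final state this readout is a continuous function of the
// parameters even where the trajectory's step count changes, which keeps
// pathwise gradients consistent with finite differences.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_simulate_dga(IntegerMatrix Smat, IntegerVector form, IntegerVector p1,
                      IntegerVector p2, IntegerVector sp, NumericVector mult,
                      NumericVector theta, NumericMatrix x0, double T,
                      double a, double b, double rate_floor, double max_steps,
                      int n_traj, double seed, IntegerVector indicators,
                      bool clamp, bool grad, bool record_noise,
                      int grad_mode, double a_grad, double jac_clip,
                      double grad_window) {
  // grad_mode: 0 = local (explicit selection sensitivities only),
  //            1 = truncated (one order of state feedback),
  //            2 = full (exact chain; explodes over long horizons at sharp
  //                smoothing scales)
  // grad_window: sensitivities accumulate only while t >= T - grad_window
  //   (trailing-window truncated backpropagation; the surrogate treats the
  //   parameters as acting only inside the window, which preserves the
  //   optimizer's fixed point while keeping the chain short enough to stay
  //   numerically stable)
  std::vector<int> Sbuf;
  Net net = unpack_net(Smat, form, p1, p2, sp, mult, Sbuf);
  const int nS = net.nS, nR = net.nR;
  const int P = grad ? (int)theta.size() : 0;
  const int K = indicators.size();
  const double inv_a = 1.0 / a, inv_b = 1.0 / b;
  // derivative-kernel temperature: selection-gradient spikes may use a
  // widened (mass-conserving) kernel of scale a_grad >= a
  const double inv_ag = 1.0 / a_grad;
  const size_t NP = (size_t)nS * std::max(P, 1);

  NumericMatrix final_states(n_traj, nS), readout(n_traj, nS),
      snapshot(n_traj, nS), occupancy(n_traj, std::max(K, 1));
  NumericVector elapsed(n_traj), nsteps(n_traj);
  LogicalVector overrun(n_traj);
  // jacobians stored flat: [A + n_traj*(s + nS*p)]
  NumericVector jac_final(grad ? (R_xlen_t)n_traj * nS * P : 0);
  NumericVector jac_readout(grad ? (R_xlen_t)n_traj * nS * P : 0);
  NumericVector jac_snapshot(grad ? (R_xlen_t)n_traj * nS * P : 0);
  NumericVector jac_occ(grad ? (R_xlen_t)n_traj * std::max(K, 1) * P : 0);
  NumericVector jac_time(grad ? (R_xlen_t)n_traj * P : 0);
  List noise(record_noise ? n_traj : 0);

  std::vector<double> x(nS), r(nR);
  std::vector<double> dr_exp((size_t)nR * std::max(P, 1));
  std::vector<double> dr_tot((size_t)nR * std::max(P, 1));
  std::vector<double> dr_sel0((size_t)nR * std::max(P, 1));
  std::vector<double> dr_sel1((size_t)nR * std::max(P, 1));
  // J0: sensitivities from explicit parameter dependence; J1: one order of
  // state feedback through the selection (zero unless grad_mode == 1)
  std::vector<double> J0(NP), J1(NP);
  std::vector<double> dR_tot(std::max(P, 1)), dtau(std::max(P, 1));
  std::vector<double> dR_sel0(std::max(P, 1)), dR_sel1(std::max(P, 1));
  std::vector<double> csum(nR);
  std::vector<double> dcsum0((size_t)nR * std::max(P, 1));
  std::vector<double> dcsum1((size_t)nR * std::max(P, 1));
  std::vector<double> di0(std::max(P, 1)), di1(std::max(P, 1));
  std::vector<double> occ_num(std::max(K, 1));
  std::vector<double> docc((size_t)std::max(K, 1) * std::max(P, 1));
  std::vector<double> dt_el(std::max(P, 1));
  std::vector<double> x_prev(nS), J_prev(NP);
  std::vector<double> ds_cross(std::max(P, 1));
  std::vector<char> is_ind(nS, 0);
  for (int k = 0; k < K; ++k) is_ind[indicators[k]] = 1;

  for (int A = 0; A < n_traj; ++A) {
    Xoshiro rng(stream_seed(seed, A));
    for (int s = 0; s < nS; ++s) x[s] = x0(A, s);
    std::fill(J0.begin(), J0.end(), 0.0);
    std::fill(J1.begin(), J1.end(), 0.0);
    std::fill(occ_num.begin(), occ_num.end(), 0.0);
    std::fill(docc.begin(), docc.end(), 0.0);
    std::fill(dt_el.begin(), dt_el.end(), 0.0);
    double t = 0.0, steps = 0.0, s_cross = 1.0;
    bool over = false, crossed = false;
    std::vector<double> noise_u, noise_up;

    while (t < T) {
      if (steps >= max_steps) {
        over = true;
        break;
      }
      // outside the gradient window, propagate values only
      const int Pw = (t >= T - grad_window) ? P : 0;
      // propensities and their sensitivities, split by channel:
      //   dr_exp  - explicit parameter dependence at fixed state
      //   dr_tot  - full value derivative (explicit + state via J0 + J1)
      //   dr_sel0 - what the J0 selection channel sees
      //   dr_sel1 - what the J1 selection channel sees (state via J0)
      double R = 0.0;
      for (int p = 0; p < P; ++p) dR_tot[p] = dR_sel0[p] = dR_sel1[p] = 0.0;
      for (int i = 0; i < nR; ++i) {
        double fac = net.mult[i];
        if (net.form[i] == 1) fac *= x[net.sp[i]];
        double th = theta[net.p1[i]];
        double th2 = net.p2[i] >= 0 ? theta[net.p2[i]] : 1.0;
        r[i] = th * th2 * fac;
        R += r[i];
        for (int p = 0; p < Pw; ++p) {
          double dexp = 0.0;
          if (p == net.p1[i]) dexp += th2 * fac;
          if (p == net.p2[i]) dexp += th * fac;
          double dst0 = 0.0, dst1 = 0.0;
          if (net.form[i] == 1) {
            double coef = th * th2 * net.mult[i];
            dst0 = coef * J0[(size_t)net.sp[i] + (size_t)nS * p];
            dst1 = coef * J1[(size_t)net.sp[i] + (size_t)nS * p];
          }
          size_t ip = (size_t)i + (size_t)nR * p;
          dr_exp[ip] = dexp;
          dr_tot[ip] = dexp + dst0 + dst1;
          dR_tot[p] += dr_tot[ip];
          if (grad_mode == 2) {
            dr_sel0[ip] = dexp + dst0;  // J1 stays zero in full mode
          } else {
            dr_sel0[ip] = dexp;
          }
          dR_sel0[p] += dr_sel0[ip];
          if (grad_mode == 1) {
            dr_sel1[ip] = dst0;
            dR_sel1[p] += dst0;
          }
        }
      }
      if (R < rate_floor) {  // absorbing: hold state to the horizon
        double hold = T - t;
        if (K > 0) {
          double ssum = 1e-12;
          for (int k = 0; k < K; ++k) ssum += x[indicators[k]];
          for (int k = 0; k < K; ++k) {
            double v = x[indicators[k]];
            occ_num[k] += v / ssum * hold;
            for (int p = 0; p < P; ++p) {
              size_t kp = (size_t)k + (size_t)K * p;
              double dv = J0[(size_t)indicators[k] + (size_t)nS * p] +
                          J1[(size_t)indicators[k] + (size_t)nS * p];
              double dssum = 0.0;
              for (int kk = 0; kk < K; ++kk)
                dssum += J0[(size_t)indicators[kk] + (size_t)nS * p] +
                         J1[(size_t)indicators[kk] + (size_t)nS * p];
              // d(hold)/dtheta = -d(t)/dtheta
              docc[kp] += hold * (dv * ssum - v * dssum) / (ssum * ssum) -
                          v / ssum * dt_el[p];
            }
          }
        }
        t = T;
        for (int p = 0; p < P; ++p) dt_el[p] = 0.0;  // elapsed pinned at T
        break;
      }
      double Reff = R + rate_floor;
      double u = rng.unif();
      double tau = -std::log(u) / Reff;
      for (int p = 0; p < P; ++p)
        dtau[p] = (p < Pw) ? std::log(u) / (Reff * Reff) * dR_tot[p] : 0.0;

      // occupancy of the *current* state over this dwell time
      if (K > 0) {
        double ssum = 1e-12;
        for (int k = 0; k < K; ++k) ssum += x[indicators[k]];
        for (int k = 0; k < K; ++k) {
          double v = x[indicators[k]];
          occ_num[k] += v / ssum * tau;
          for (int p = 0; p < P; ++p) {
            double dv = J0[(size_t)indicators[k] + (size_t)nS * p] +
                        J1[(size_t)indicators[k] + (size_t)nS * p];
            double dssum = 0.0;
            for (int kk = 0; kk < K; ++kk)
              dssum += J0[(size_t)indicators[kk] + (size_t)nS * p] +
                       J1[(size_t)indicators[kk] + (size_t)nS * p];
            docc[(size_t)k + (size_t)K * p] +=
                tau * (dv * ssum - v * dssum) / (ssum * ssum) +
                v / ssum * dtau[p];
          }
        }
      }
      if (!crossed && t + tau >= T) {  // dwell straddles the horizon
        crossed = true;
        s_cross = (T - t) / tau;
        for (int p = 0; p < P; ++p)
          ds_cross[p] = (-dt_el[p] * tau - (T - t) * dtau[p]) / (tau * tau);
        for (int s = 0; s < nS; ++s) x_prev[s] = x[s];
        for (size_t k = 0; k < NP; ++k) J_prev[k] = J0[k] + J1[k];
      }
      t += tau;
      for (int p = 0; p < P; ++p) dt_el[p] += dtau[p];

      // smooth reaction selection on cumulative fractions
      double u2 = rng.unif();
      if (record_noise) {
        noise_u.push_back(u);
        noise_up.push_back(u2);
      }
      double acc = 0.0;
      for (int i = 0; i < nR; ++i) {
        acc += r[i];
        csum[i] = acc;
      }
      for (int p = 0; p < Pw; ++p) {
        double dacc0 = 0.0, dacc1 = 0.0;
        for (int i = 0; i < nR; ++i) {
          size_t ip = (size_t)i + (size_t)nR * p;
          dacc0 += dr_sel0[ip];
          dcsum0[ip] = dacc0;
          dacc1 += dr_sel1[ip];
          dcsum1[ip] = dacc1;
        }
      }
      double iprime = 1.0;
      for (int p = 0; p < P; ++p) di0[p] = di1[p] = 0.0;
      for (int i = 0; i < nR - 1; ++i) {
        double q = csum[i] / Reff;
        double z = (u2 - q) * inv_a;
        iprime += sigmoid(z);
        if (Pw > 0) {
          double sgg = sigmoid((u2 - q) * inv_ag);
          double sgp = sgg * (1.0 - sgg);
          if (sgp > 1e-14) {
            for (int p = 0; p < Pw; ++p) {
              size_t ip = (size_t)i + (size_t)nR * p;
              double dq0 = (dcsum0[ip] * Reff - csum[i] * dR_sel0[p]) /
                           (Reff * Reff);
              di0[p] += sgp * (-dq0) * inv_ag;
              if (grad_mode == 1) {
                double dq1 = (dcsum1[ip] * Reff - csum[i] * dR_sel1[p]) /
                             (Reff * Reff);
                di1[p] += sgp * (-dq1) * inv_ag;
              }
            }
          }
        }
      }

      // Gaussian stoichiometry weights and state update
      for (int j = 0; j < nR; ++j) {
        double d = iprime - (j + 1);
        double e = -d * d * inv_b;
        if (e < -40.0) continue;
        double w = std::exp(e);
        double dwfac = -2.0 * d * inv_b * w;
        for (int s = 0; s < nS; ++s) {
          int Sj = net.S[(size_t)j * nS + s];
          if (Sj == 0) continue;
          x[s] += w * Sj;
          for (int p = 0; p < Pw; ++p) {
            J0[(size_t)s + (size_t)nS * p] += dwfac * di0[p] * Sj;
            if (grad_mode == 1)
              J1[(size_t)s + (size_t)nS * p] += dwfac * di1[p] * Sj;
          }
        }
      }
      if (clamp) {
        for (int s = 0; s < nS; ++s) {
          double slope;
          double y = is_ind[s] ? softplus_clamp01(x[s], slope)
                               : softplus_clamp(x[s], slope);
          if (y != x[s] || slope != 1.0) {
            x[s] = y;
            for (int p = 0; p < P; ++p) {
              J0[(size_t)s + (size_t)nS * p] *= slope;
              J1[(size_t)s + (size_t)nS * p] *= slope;
            }
          }
        }
      }
      if (P > 0 && jac_clip < R_PosInf) {
        // elasticity clip: bound |dx_s/dlog(theta_p)| by jac_clip*(|x_s|+1),
        // i.e. one log-unit of any rate may not move a species by more than
        // jac_clip times its magnitude (exploding-sensitivity guard)
        for (int s = 0; s < nS; ++s) {
          double cap_base = jac_clip * (std::fabs(x[s]) + 1.0);
          for (int p = 0; p < P; ++p) {
            double cap = cap_base / theta[p];
            double *Js[2] = {&J0[(size_t)s + (size_t)nS * p],
                             &J1[(size_t)s + (size_t)nS * p]};
            for (double *J : Js) {
              if (*J > cap) *J = cap;
              if (*J < -cap) *J = -cap;
            }
          }
        }
      }
      steps += 1.0;
    }

    for (int s = 0; s < nS; ++s) final_states(A, s) = x[s];
    if (crossed) {
      for (int s = 0; s < nS; ++s) {
        readout(A, s) = x_prev[s] + s_cross * (x[s] - x_prev[s]);
        snapshot(A, s) = x_prev[s];
      }
    } else {
      for (int s = 0; s < nS; ++s) {
        readout(A, s) = x[s];
        snapshot(A, s) = x[s];
      }
    }
    elapsed[A] = t;
    nsteps[A] = steps;
    overrun[A] = over;
    for (int k = 0; k < K; ++k) occupancy(A, k) = occ_num[k] / t;
    if (grad) {
      for (int s = 0; s < nS; ++s)
        for (int p = 0; p < P; ++p) {
          double Jtot = J0[(size_t)s + (size_t)nS * p] +
                        J1[(size_t)s + (size_t)nS * p];
          jac_final[A + (R_xlen_t)n_traj * (s + (R_xlen_t)nS * p)] = Jtot;
          double dro;
          if (crossed) {
            double jp = J_prev[(size_t)s + (size_t)nS * p];
            dro = jp + ds_cross[p] * (x[s] - x_prev[s]) +
                  s_cross * (Jtot - jp);
          } else {
            dro = Jtot;
          }
          jac_readout[A + (R_xlen_t)n_traj * (s + (R_xlen_t)nS * p)] = dro;
          jac_snapshot[A + (R_xlen_t)n_traj * (s + (R_xlen_t)nS * p)] =
              crossed ? J_prev[(size_t)s + (size_t)nS * p] : Jtot;
        }
      for (int k = 0; k < K; ++k)
        for (int p = 0; p < P; ++p)
          jac_occ[A + (R_xlen_t)n_traj * (k + (R_xlen_t)K * p)] =
              (docc[(size_t)k + (size_t)K * p] * t - occ_num[k] * dt_el[p]) /
              (t * t);
      for (int p = 0; p < P; ++p)
        jac_time[A + (R_xlen_t)n_traj * p] = dt_el[p];
    }
    if (record_noise) {
      NumericMatrix nm(noise_u.size(), 2);
      for (size_t k = 0; k < noise_u.size(); ++k) {
        nm(k, 0) = noise_u[k];
        nm(k, 1) = noise_up[k];
      }
      noise[A] = nm;
    }
  }

  List out = List::create(
      _["final"] = final_states, _["readout"] = readout,
      _["snapshot"] = snapshot, _["elapsed"] = elapsed,
      _["occupancy"] = occupancy, _["nsteps"] = nsteps,
      _["overrun"] = overrun, _["jac_final"] = jac_final,
      _["jac_readout"] = jac_readout, _["jac_occ"] = jac_occ,
      _["jac_time"] = jac_time, _["noise"] = noise);
  out["jac_snapshot"] = jac_snapshot;
  return out;
}
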