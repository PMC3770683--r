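// Stochastic simulation engines for the Hill-family switch:
//  - Euler-Maruyama for the Ito chemical Langevin equation
//  - Heun (Stratonovich-consistent) integrator driven by an exactly-updated
//    Ornstein-Uhlenbeck process (colored noise)
//  - Gillespie direct-method SSA for the simple birth-death model and the
//    detailed promoter-binding model
//
// RNG: mt19937_64 (sequence fixed by the C++ standard) with explicit 53-bit
// uniforms and a Box-Muller normal, so trajectories are bit-reproducible for
// a given seed regardless of the standard library's distribution internals.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 gen;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : gen(seed) {}
  // uniform on (0, 1), never 0 or 1
  double unif() {
    return ((gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
  double expo() { return -std::log(unif()); }
};

inline double hillg(double x, double a, double beff, int h) {
  double xh = std::pow(x, h);
  return a + beff * xh / (1.0 + xh);
}

// d/dx of the Hill production rate a + beff * x^h / (1 + x^h)
inline double hillg_dx(double x, double beff, int h) {
  double xh = std::pow(x, h);
  double den = 1.0 + xh;
  double xhm1 = (h == 1) ? 1.0 : std::pow(x, h - 1);
  return beff * h * xhm1 / (den * den);
}

inline double ffact(double n, int h) {
  double v = 1.0;
  for (int i = 0; i < h; ++i) v *= (n - i);
  return v > 0.0 ? v : 0.0;
}

} // namespace

// [[Rcpp::export(name = ".cpp_em_hill")]]
NumericVector cpp_em_hill(double a, double beff, int h, double eps,
                          double x0, double dt, double nsteps_d,
                          int thin, double seed) {
  const long long nsteps = (long long) nsteps_d;
  Rng rng((uint64_t) seed);
  const long long nrec = nsteps / thin + 1;
  NumericVector out(nrec);
  double x = x0;
  out[0] = x;
  const double sdt = std::sqrt(dt);
  long long j = 1;
  for (long long k = 1; k <= nsteps; ++k) {
    double g = hillg(x, a, beff, h);
    double B = g + x;
    x = x + (g - x) * dt + eps * std::sqrt(B) * sdt * rng.norm();
    if (x < 0.0) x = -x;  // reflecting boundary at 0
    if (k % thin == 0) out[j++] = x;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_heun_ou_hill")]]
NumericVector cpp_heun_ou_hill(double a, double beff, int h, double eps,
                               double tau, double x0, double dt,
                               double nsteps_d, int thin, double seed) {
  const long long nsteps = (long long) nsteps_d;
  Rng rng((uint64_t) seed);
  const long long nrec = nsteps / thin + 1;
  NumericVector out(nrec);
  const double sig = eps / std::sqrt(2.0 * tau);   // stationary sd of OU
  const double rho = std::exp(-dt / tau);
  const double sres = sig * std::sqrt(1.0 - rho * rho);
  double x = x0;
  double z = sig * rng.norm();                     // stationary start
  out[0] = x;
  long long j = 1;
  // Stratonovich-form drift: the Ito equation dx = f dt + eps sqrt(B) dW is
  // equivalent to the Stratonovich one with drift f - (eps^2/4) B_x, which
  // is what the OU drive must multiply for the tau -> 0 (Wong-Zakai) limit
  // to recover the white-noise system.
  const double corr = 0.25 * eps * eps;
  for (long long k = 1; k <= nsteps; ++k) {
    // Heun predictor-corrector; OU value held constant during the step
    double g0 = hillg(x, a, beff, h);
    double Bx0 = hillg_dx(x, beff, h) + 1.0;
    double d0 = (g0 - x) - corr * Bx0 + std::sqrt(g0 + x) * z;
    double xp = x + d0 * dt;
    if (xp < 0.0) xp = -xp;
    double g1 = hillg(xp, a, beff, h);
    double Bx1 = hillg_dx(xp, beff, h) + 1.0;
    double d1 = (g1 - xp) - corr * Bx1 + std::sqrt(g1 + xp) * z;
    x = x + 0.5 * dt * (d0 + d1);
    if (x < 0.0) x = -x;
    // exact OU update
    z = rho * z + sres * rng.norm();
    if (k % thin == 0) out[j++] = x;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_ou_path")]]
NumericVector cpp_ou_path(double tau, double eps, double dt,
                          double nsteps_d, double seed) {
  const long long nsteps = (long long) nsteps_d;
  Rng rng((uint64_t) seed);
  NumericVector out(nsteps + 1);
  const double sig = eps / std::sqrt(2.0 * tau);
  const double rho = std::exp(-dt / tau);
  const double sres = sig * std::sqrt(1.0 - rho * rho);
  double z = sig * rng.norm();
  out[0] = z;
  for (long long k = 1; k <= nsteps; ++k) {
    z = rho * z + sres * rng.norm();
    out[k] = z;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_ssa_hill")]]
List cpp_ssa_hill(double a, double beff, int h, double Omega,
                  double n0, double t_end, double seed, double record_dt) {
  Rng rng((uint64_t) seed);
  double n = n0, t = 0.0;
  std::vector<double> times, states;
  double rec_t = 0.0;
  const bool grid = record_dt > 0.0;
  if (grid) {
    size_t cap = (size_t)(t_end / record_dt) + 2;
    times.reserve(cap); states.reserve(cap);
  } else {
    times.reserve(1 << 16); states.reserve(1 << 16);
    times.push_back(0.0); states.push_back(n);
  }
  long long n_events = 0;
  while (t < t_end) {
    double wplus = Omega * hillg(n / Omega, a, beff, h);
    double wminus = n;
    double a0 = wplus + wminus;
    double t_next = (a0 > 0.0) ? t + rng.expo() / a0 : t_end + 1.0;
    if (grid) {
      while (rec_t < t_next && rec_t <= t_end) {
        times.push_back(rec_t); states.push_back(n);
        rec_t += record_dt;
      }
    }
    if (t_next > t_end) break;
    t = t_next;
    if (rng.unif() * a0 < wplus) n += 1.0; else n -= 1.0;
    ++n_events;
    if (!grid) { times.push_back(t); states.push_back(n); }
  }
  return List::create(_["times"] = wrap(times), _["states"] = wrap(states),
                      _["n_events"] = (double) n_events);
}

// [[Rcpp::export(name = ".cpp_ssa_detailed")]]
List cpp_ssa_detailed(double a, double b, int h, double Omega,
                      double keq, double koff, int dT,
                      double n0, int d1_0, double t_end, double seed,
                      double record_dt) {
  Rng rng((uint64_t) seed);
  double n = n0, t = 0.0;
  int d1 = d1_0;
  const double kon = keq * koff / std::pow(Omega, h);
  std::vector<double> times, states, occ;
  double rec_t = 0.0;
  const bool grid = record_dt > 0.0;
  if (grid) {
    size_t cap = (size_t)(t_end / record_dt) + 2;
    times.reserve(cap); states.reserve(cap); occ.reserve(cap);
  } else {
    times.push_back(0.0); states.push_back(n); occ.push_back(d1);
  }
  long long n_events = 0;
  while (t < t_end) {
    int d0 = dT - d1;
    double a_prod = Omega * (a * d0 + (a + b) * d1);
    double a_deg  = n;
    double a_bind = d0 > 0 ? kon * d0 * ffact(n, h) : 0.0;
    double a_unb  = koff * d1;
    double a0 = a_prod + a_deg + a_bind + a_unb;
    double t_next = (a0 > 0.0) ? t + rng.expo() / a0 : t_end + 1.0;
    if (grid) {
      while (rec_t < t_next && rec_t <= t_end) {
        times.push_back(rec_t); states.push_back(n); occ.push_back(d1);
        rec_t += record_dt;
      }
    }
    if (t_next > t_end) break;
    t = t_next;
    double u = rng.unif() * a0;
    if (u < a_prod) {
      n += 1.0;
    } else if (u < a_prod + a_deg) {
      n -= 1.0;
    } else if (u < a_prod + a_deg + a_bind) {
      n -= h; d1 += 1;   // h monomers sequestered by the binding event
    } else {
      n += h; d1 -= 1;
    }
    ++n_events;
    if (!grid) { times.push_back(t); states.push_back(n); occ.push_back(d1); }
  }
  return List::create(_["times"] = wrap(times), _["states"] = wrap(states),
                      _["d1"] = wrap(occ), _["n_events"] = (double) n_events);
}

// Detailed model with production and degradation switched off and the
// protein count clamped: isolates the binding/unbinding two-state kinetics
// of the promoter, whose time-averaged occupancy must equal
// keq p^h / (1 + keq p^h) at equilibrium (p = n / Omega).
// [[Rcpp::export(name = ".cpp_ssa_binding_only")]]
List cpp_ssa_binding_only(int h, double Omega, double keq, double koff,
                          int dT, double n_clamped, double t_end,
                          double seed) {
  Rng rng((uint64_t) seed);
  const double kon = keq * koff / std::pow(Omega, h);
  double t = 0.0, t_occ = 0.0;
  int d1 = 0;
  long long n_events = 0;
  while (t < t_end) {
    int d0 = dT - d1;
    double a_bind = d0 > 0 ? kon * d0 * ffact(n_clamped, h) : 0.0;
    double a_unb  = koff * d1;
    double a0 = a_bind + a_unb;
    double t_next = (a0 > 0.0) ? t + rng.expo() / a0 : t_end + 1.0;
    double seg_end = t_next < t_end ? t_next : t_end;
    t_occ += (seg_end - t) * d1;
    if (t_next > t_end) break;
    t = t_next;
    if (rng.unif() * a0 < a_bind) d1 += 1; else d1 -= 1;
    ++n_events;
  }
  return List::create(_["occupancy"] = t_occ / (t_end * dT),
                      _["n_events"] = (double) n_events);
}
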