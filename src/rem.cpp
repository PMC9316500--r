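// Metropolis Monte Carlo replica-exchange kernel for the surrogate
// torsional system.  Potential decomposition at ladder point (s, lambda):
//   U = V_s(y) + s * V_S(phi) + lambda * V_sS(phi, y)
//   V_S  = (Kb/2)(1 - cos 2*phi) + (a/2)(1 - cos phi)
//   V_sS = -(deps/2)(1 - cos phi) + (g/2) * sum(y^2)
//   V_s  = (ks/2) * sum(y^2)
// Configurations are swapped between neighbouring slots (Hamiltonians stay
// put); walker ids travel with the configurations.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

// xoshiro256++ with splitmix64 seeding: fast, high-quality, and
// deterministic across platforms (unlike std:: distributions).
struct FastRng {
  uint64_t s[4];
  double spare;
  bool has_spare;
  explicit FastRng(uint64_t seed) : has_spare(false) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {  // splitmix64
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * 0x1.0p-53;
  }
  inline double norm() {  // Marsaglia polar method with cached spare
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; has_spare = true;
    return u * f;
  }
};

static inline double wrap_phi(double phi) {
  // wrap into (-pi, pi]; avoids fmod (versioned symbol on recent glibc)
  double r = phi - TWO_PI * std::floor((phi + M_PI) / TWO_PI);
  if (r <= -M_PI) r += TWO_PI;
  return r;
}

struct SlotState {
  double phi;
  std::vector<double> y;
  double VS;    // solute intramolecular energy
  double cphi;  // phi-dependent part of V_sS
  double Sy;    // sum of y_i^2
};

// [[Rcpp::export(name = ".rem_run_cpp")]]
List rem_run_cpp(double Kb, double a, double deps, int Ns, double ks,
                 double g, double beta,
                 NumericVector s_vec, NumericVector lam_vec,
                 NumericVector dphi_vec, double sigma_y,
                 double n_sweeps_d, int swap_interval, int sample_interval,
                 int burn_in, NumericVector phi_init, double seed_d) {
  const int K = s_vec.size();
  const long long n_sweeps = (long long)n_sweeps_d;
  FastRng rng((uint64_t)seed_d);

  std::vector<SlotState> st(K);
  std::vector<int> walker(K);  // walker id at each slot (0-based)
  for (int k = 0; k < K; ++k) {
    st[k].phi = phi_init[k];
    st[k].y.assign(Ns, 0.0);
    double c2 = std::cos(2.0 * st[k].phi), c1 = std::cos(st[k].phi);
    st[k].VS = 0.5 * Kb * (1.0 - c2) + 0.5 * a * (1.0 - c1);
    st[k].cphi = -0.5 * deps * (1.0 - c1);
    st[k].Sy = 0.0;
    walker[k] = k;
  }

  const long long n_samp = (n_sweeps > burn_in)
      ? (n_sweeps - burn_in) / sample_interval : 0;
  const long long n_rounds = (swap_interval > 0) ? n_sweeps / swap_interval : 0;

  NumericMatrix phi_out(n_samp, K), vs_out(n_samp, K),
                vS_out(n_samp, K), vsS_out(n_samp, K);
  NumericVector samp_sweep(n_samp);
  IntegerMatrix walker_slot(n_rounds, K);  // column w: slot of walker w
  NumericVector round_sweep(n_rounds);
  NumericVector attempts(std::max(K - 1, 0)), accepts(std::max(K - 1, 0));
  NumericVector phi_att(K), phi_acc(K), y_att(K), y_acc(K);

  long long isamp = 0, iround = 0;
  for (long long sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int k = 0; k < K; ++k) {
      const double s = s_vec[k], lam = lam_vec[k];
      // torsional move: wrapped uniform proposal
      double phin = wrap_phi(st[k].phi + (2.0 * rng.unif() - 1.0) * dphi_vec[k]);
      double c2 = std::cos(2.0 * phin), c1 = std::cos(phin);
      double VSn = 0.5 * Kb * (1.0 - c2) + 0.5 * a * (1.0 - c1);
      double cn = -0.5 * deps * (1.0 - c1);
      double du = beta * (s * (VSn - st[k].VS) + lam * (cn - st[k].cphi));
      phi_att[k] += 1.0;
      if (du <= 0.0 || rng.unif() < std::exp(-du)) {
        st[k].phi = phin; st[k].VS = VSn; st[k].cphi = cn;
        phi_acc[k] += 1.0;
      }
      // solvent moves: independent Gaussian random-walk proposals
      const double keff = 0.5 * beta * (ks + lam * g);
      for (int i = 0; i < Ns; ++i) {
        double yo = st[k].y[i];
        double yn = yo + sigma_y * rng.norm();
        double duy = keff * (yn * yn - yo * yo);
        y_att[k] += 1.0;
        if (duy <= 0.0 || rng.unif() < std::exp(-duy)) {
          st[k].Sy += yn * yn - yo * yo;
          st[k].y[i] = yn;
          y_acc[k] += 1.0;
        }
      }
    }
    // neighbour swaps on alternating even/odd edge sets
    if (swap_interval > 0 && sweep % swap_interval == 0 && iround < n_rounds) {
      int parity = (int)((iround + 1) % 2);  // round 1: odd edges (0-based 0,2,..)
      for (int e = (parity == 1 ? 0 : 1); e < K - 1; e += 2) {
        double vsS_lo = st[e].cphi + 0.5 * g * st[e].Sy;
        double vsS_hi = st[e + 1].cphi + 0.5 * g * st[e + 1].Sy;
        double delta = beta * ((s_vec[e] - s_vec[e + 1]) * (st[e + 1].VS - st[e].VS)
                     + (lam_vec[e] - lam_vec[e + 1]) * (vsS_hi - vsS_lo));
        attempts[e] += 1.0;
        if (delta <= 0.0 || rng.unif() < std::exp(-delta)) {
          std::swap(st[e], st[e + 1]);
          std::swap(walker[e], walker[e + 1]);
          accepts[e] += 1.0;
        }
      }
      for (int k = 0; k < K; ++k) walker_slot(iround, walker[k]) = k + 1;
      round_sweep[iround] = (double)sweep;
      ++iround;
    }
    if (sweep > burn_in && (sweep - burn_in) % sample_interval == 0
        && isamp < n_samp) {
      for (int k = 0; k < K; ++k) {
        phi_out(isamp, k) = st[k].phi;
        vs_out(isamp, k) = 0.5 * ks * st[k].Sy;
        vS_out(isamp, k) = st[k].VS;
        vsS_out(isamp, k) = st[k].cphi + 0.5 * g * st[k].Sy;
      }
      samp_sweep[isamp] = (double)sweep;
      ++isamp;
    }
  }

  return List::create(
      _["phi"] = phi_out, _["v_s"] = vs_out, _["v_S"] = vS_out,
      _["v_sS"] = vsS_out, _["sample_sweep"] = samp_sweep,
      _["attempts"] = attempts, _["accepts"] = accepts,
      _["walker_slot"] = walker_slot, _["round_sweep"] = round_sweep,
      _["phi_move_rate"] = phi_acc / pmax(phi_att, 1.0),
      _["y_move_rate"] = y_acc / pmax(y_att, 1.0));
}
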