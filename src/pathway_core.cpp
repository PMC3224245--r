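// Euler / Euler-Maruyama core for the chemotaxis pathway.
//
// States: aC  total receptor activity of the cell (sums all complexes),
//         M   methylation level of a representative complex,
//         nAp, nYp, nBp phosphorylated copy numbers,
//         X   motor CW bias (continuous Langevin) or CW state (0/1 telegraph).
// Noise is additive with intensities evaluated at the adapted state, so the
// stochastic paths linearise exactly onto the analytic spectra. Shared
// phosphotransfer noises use one Gaussian draw injected with opposite signs
// into the donor and acceptor equations.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding: fast, reproducible across platforms.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_cached = false;
  double cached = 0.0;
  double norm() {  // polar Box-Muller
    if (have_cached) { have_cached = false; return cached; }
    double u, v, r2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(r2) / r2);
    cached = v * f;
    have_cached = true;
    return u * f;
  }
};

struct Mwc {
  double N, eps0, nu_a, Ka_off, Ka_on, nu_s, Ks_off, Ks_on;
  double ligand_term(double c) const {
    return N * (nu_a * (std::log1p(c / Ka_off) - std::log1p(c / Ka_on)) +
                nu_s * (std::log1p(c / Ks_off) - std::log1p(c / Ks_on)));
  }
  // per-complex activity in [0, N] given cached ligand term
  double activity(double lig, double M) const {
    double F = N * eps0 - 0.5 * M + lig;
    if (F > 700.0) return 0.0;
    if (F < -700.0) return N;
    return N / (1.0 + std::exp(F));
  }
};

double stimulus_dc(int type, double t, double p1, double p2, double p3) {
  switch (type) {
    case 1: {  // triangular impulse: peak p1, duration p2, onset p3
      double u = t - p3;
      if (u <= 0.0 || u >= p2) return 0.0;
      return p1 * (1.0 - std::fabs(2.0 * u / p2 - 1.0));
    }
    case 2:  // step of height p1 at t = p2
      return (t >= p2) ? p1 : 0.0;
    case 3:  // sine: amplitude p1, angular frequency p2, onset p3
      return (t >= p3) ? p1 * std::sin(p2 * (t - p3)) : 0.0;
    default:
      return 0.0;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix pathway_euler_core(NumericVector init, List pars, List stim,
                                 double dt, double nsteps_d, int sample_every,
                                 bool noise, double seed, int replicate,
                                 bool discrete_motor, int model_code,
                                 int record_mode) {
  const long nsteps = (long)nsteps_d;
  const double N      = as<double>(pars["N"]);
  const double N_C    = as<double>(pars["N_C"]);
  const double N_tot  = as<double>(pars["N_tot"]);
  const double conv   = as<double>(pars["conv"]);
  const double gR     = as<double>(pars["gamma_R"]);
  const double gB     = as<double>(pars["gamma_B"]);
  const double gBs    = as<double>(pars["gamma_B_simpl"]);
  const double k_A    = as<double>(pars["k_A"]);
  const double kyv    = as<double>(pars["kyv"]);
  const double kbv    = as<double>(pars["kbv"]);
  const double k_my   = as<double>(pars["k_minus_y"]);
  const double k_mb   = as<double>(pars["k_minus_b"]);
  const double NAtot  = as<double>(pars["NA_tot"]);
  const double NYtot  = as<double>(pars["NY_tot"]);
  const double NBtot  = as<double>(pars["NB_tot"]);
  const double k12    = as<double>(pars["k12"]);
  const double c0     = as<double>(pars["c0"]);
  const double sigc   = as<double>(pars["sigma_c"]);  // per-step ligand sd, mM
  // motor (0 = linearized, 1 = mwc)
  const int motor_mode = as<int>(pars["motor_mode"]);
  const double kps  = as<double>(pars["k_plus_star"]);
  const double kms  = as<double>(pars["k_minus_star"]);
  const double dkp  = as<double>(pars["dkplus_dYp"]);
  const double dkm  = as<double>(pars["dkminus_dYp"]);
  const double Yp0  = as<double>(pars["Yp_anchor"]);
  const double mu    = as<double>(pars["mu"]);
  const double Kccw  = as<double>(pars["K_CCW"]);
  const double Kcw   = as<double>(pars["K_CW"]);
  const double kp0   = as<double>(pars["k_plus_0"]);
  const double km0   = as<double>(pars["k_minus_0"]);
  const double mcoop = as<double>(pars["m_coop"]);
  // simplified-model motor coupling to total activity
  const double dkp_dA = as<double>(pars["dkplus_dAc"]);
  const double dkm_dA = as<double>(pars["dkminus_dAc"]);
  const double aC_star = as<double>(pars["aC_star"]);

  Mwc mwc{as<double>(pars["N"]), as<double>(pars["eps0"]),
          as<double>(pars["nu_a"]), as<double>(pars["Ka_off"]),
          as<double>(pars["Ka_on"]), as<double>(pars["nu_s"]),
          as<double>(pars["Ks_off"]), as<double>(pars["Ks_on"])};

  // Receptor switching relaxes at k12 >> 1/dt-compatible scales; the
  // Euler-Maruyama step on such a stiff Ornstein-Uhlenbeck state inflates
  // its variance by ~k12*dt/2, so this one state uses the exact OU update
  // (exponential decay towards the MWC target plus its exact stationary
  // increment). All other states use plain Euler-Maruyama.
  const double Qa_tot = as<double>(pars["Qa_tot"]);
  const double decay_a = std::exp(-k12 * dt);
  const double sA_exact =
      std::sqrt(Qa_tot * (1.0 - decay_a * decay_a) / (2.0 * k12));
  // noise amplitudes sqrt(Q dt), zero when noise is off
  const double sA  = noise && Qa_tot > 0.0 ? sA_exact : 0.0;
  const double sM  = noise ? std::sqrt(as<double>(pars["QM_eff"]) * dt) : 0.0;
  const double sAp = noise ? std::sqrt(as<double>(pars["QAp"]) * dt) : 0.0;
  const double sAY = noise ? std::sqrt(as<double>(pars["QAYp"]) * dt) : 0.0;
  const double sAB = noise ? std::sqrt(as<double>(pars["QABp"]) * dt) : 0.0;
  const double sY  = noise ? std::sqrt(as<double>(pars["QmYp"]) * dt) : 0.0;
  const double sB  = noise ? std::sqrt(as<double>(pars["QmBp"]) * dt) : 0.0;
  const double sX  = noise ? std::sqrt(as<double>(pars["QX"]) * dt) : 0.0;
  const bool switching_noise = noise && sA > 0.0;
  const bool ligand_noise = noise && sigc > 0.0;

  const int stim_type = as<int>(stim["type"]);
  const double p1 = as<double>(stim["p1"]);
  const double p2 = as<double>(stim["p2"]);
  const double p3 = as<double>(stim["p3"]);

  const bool simplified = (model_code == 1);

  Xoshiro rng(((uint64_t)(seed)) * 0x2545F4914F6CDD1DULL +
              (uint64_t)(replicate + 1) * 0x9E3779B97F4A7C15ULL);

  double aC = init[0], M = init[1], nAp = init[2], nYp = init[3],
         nBp = init[4], X = init[5];
  // a telegraph motor starts in a definite rotational state drawn from
  // the stationary bias
  if (discrete_motor) X = (rng.unif() < X) ? 1.0 : 0.0;

  // record_mode 0: instantaneous samples every sample_every steps;
  // record_mode 1: block means over sample_every steps (boxcar
  // anti-aliasing for spectral estimation)
  const bool block_mean = (record_mode == 1);
  const long nsamp = block_mean ? nsteps / sample_every
                                : nsteps / sample_every + 1;
  NumericMatrix out(nsamp, 7);
  colnames(out) = CharacterVector::create("t", "c", "A_c", "N_Ap", "N_Yp",
                                          "N_Bp", "X");
  long row = 0;
  double acc[6] = {0, 0, 0, 0, 0, 0};
  long acc_n = 0;
  double c_prev = NA_REAL, lig = 0.0;

  for (long i = 0; i <= nsteps; ++i) {
    const double t = i * dt;
    double c = c0 + stimulus_dc(stim_type, t, p1, p2, p3);
    const double c_mean = c;
    if (ligand_noise) c += sigc * rng.norm();
    if (c < 0.0) c = 0.0;
    if (c != c_prev) { lig = mwc.ligand_term(c); c_prev = c; }

    const double Amwc = mwc.activity(lig, M);
    if (switching_noise) {
      const double target = N_C * Amwc;
      aC = target + (aC - target) * decay_a + sA * rng.norm();
    } else {
      aC = N_C * Amwc;
    }

    if (block_mean) {
      if (i > 0) {
        acc[0] += c_mean; acc[1] += aC; acc[2] += nAp; acc[3] += nYp;
        acc[4] += nBp; acc[5] += X;
        if (++acc_n == sample_every) {
          out(row, 0) = t - 0.5 * (sample_every - 1) * dt;
          for (int j = 0; j < 6; ++j) {
            out(row, j + 1) = acc[j] / sample_every;
            acc[j] = 0.0;
          }
          acc_n = 0;
          ++row;
        }
      }
    } else if (i % sample_every == 0 && row < nsamp) {
      out(row, 0) = t; out(row, 1) = c_mean; out(row, 2) = aC;
      out(row, 3) = nAp; out(row, 4) = nYp; out(row, 5) = nBp;
      out(row, 6) = X;
      ++row;
    }
    if (i == nsteps) break;

    const double Aj = aC / N_C;
    double kp, km;
    if (simplified) {
      M += dt * (gR * (N - Aj) - gBs * Aj * Aj * Aj) +
           (noise ? sM * rng.norm() : 0.0);
      kp = kps + dkp_dA * (aC - aC_star);
      km = kms + dkm_dA * (aC - aC_star);
    } else {
      const double Bp_uM = conv * nBp;
      const double dM = gR * (N - Aj) - gB * Bp_uM * Bp_uM * Aj;
      const double dAp = k_A * (aC / N_tot) * (NAtot - nAp) -
                         kyv * (NYtot - nYp) * nAp -
                         kbv * (NBtot - nBp) * nAp;
      const double dYp = kyv * (NYtot - nYp) * nAp - k_my * nYp;
      const double dBp = kbv * (NBtot - nBp) * nAp - k_mb * nBp;
      if (noise) {
        const double zAY = rng.norm(), zAB = rng.norm();
        M   += dt * dM  + sM * rng.norm();
        nAp += dt * dAp + sAp * rng.norm() + sAY * zAY + sAB * zAB;
        nYp += dt * dYp - sAY * zAY + sY * rng.norm();
        nBp += dt * dBp - sAB * zAB + sB * rng.norm();
      } else {
        M += dt * dM; nAp += dt * dAp; nYp += dt * dYp; nBp += dt * dBp;
        if (nAp < 0.0 || nAp > NAtot || nYp < 0.0 || nYp > NYtot ||
            nBp < 0.0 || nBp > NBtot)
          stop("phosphorylation state left [0, total] bounds; reduce dt");
      }
      const double Yp_uM = conv * (nYp > 0.0 ? nYp : 0.0);
      if (motor_mode == 1) {
        const double num = 1.0 + mu * Yp_uM / Kccw;
        kp = kp0 * std::pow(num / (1.0 + Yp_uM / Kccw), mcoop);
        km = km0 * std::pow(num / (1.0 + Yp_uM / Kcw), mcoop);
      } else {
        kp = kps + dkp * (Yp_uM - Yp0);
        km = kms + dkm * (Yp_uM - Yp0);
      }
    }
    if (kp < 0.0) kp = 0.0;
    if (km < 0.0) km = 0.0;

    if (discrete_motor) {
      const double u = rng.unif();
      if (X < 0.5) { if (u < kp * dt) X = 1.0; }
      else         { if (u < km * dt) X = 0.0; }
    } else {
      X += dt * (kp * (1.0 - X) - km * X) + (noise ? sX * rng.norm() : 0.0);
      if (!noise && (X < -1e-9 || X > 1.0 + 1e-9))
        stop("motor bias left [0, 1]; reduce dt");
    }
  }
  return out;
}
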