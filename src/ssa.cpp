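#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Counter-free PRNG (xoshiro256++ seeded through splitmix64). The simulator
// does not touch R's RNG: each cell gets its own stream derived from the root
// seed, so a population is reproducible and independent of simulation order.
namespace {

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(seed);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform on (0,1), never exactly 0 or 1
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

struct Kinetics {
  double k_on, k_off, k_tx, d_m, k_p, d_p;
  int ploidy;       // allele copies per class; total units = 2 * ploidy
  bool nmd;         // class 1 (second allele) transcripts decay immediately
};

Kinetics kinetics_from_list(const List& par) {
  Kinetics k;
  k.k_on  = as<double>(par["k_on"]);
  k.k_off = as<double>(par["k_off"]);
  k.k_tx  = as<double>(par["k_tx"]);
  k.d_m   = as<double>(par["d_m"]);
  k.k_p   = as<double>(par["k_p"]);
  k.d_p   = as<double>(par["d_p"]);
  k.ploidy = as<int>(par["ploidy"]);
  k.nmd   = as<bool>(par["nmd"]);
  return k;
}

// State of one cell: per allele unit (units 0..ploidy-1 are allele class 0,
// units ploidy..2*ploidy-1 are class 1).
struct Cell {
  std::vector<int> g;   // promoter 0 = OFF, 1 = ON
  std::vector<int> m;   // mRNA molecules
  std::vector<int> p;   // protein molecules
};

void init_cell(Cell& c, const Kinetics& k, Xoshiro& rng) {
  int n = 2 * k.ploidy;
  c.g.assign(n, 0);
  c.m.assign(n, 0);
  c.p.assign(n, 0);
  double denom = k.k_on + k.k_off;
  double p_on = denom > 0 ? k.k_on / denom : 0.0;
  for (int i = 0; i < n; ++i) c.g[i] = (rng.unif() < p_on) ? 1 : 0;
}

// Exact (Gillespie direct-method) advance of one cell to time t_target.
// Reaction set per allele unit: OFF->ON, ON->OFF, transcription (while ON),
// mRNA decay, translation, protein decay.
void advance(Cell& c, const Kinetics& k, double t0, double t_target,
             Xoshiro& rng) {
  const int n = 2 * k.ploidy;
  double t = t0;
  std::vector<double> a(6 * n);
  for (;;) {
    double a0 = 0.0;
    for (int i = 0; i < n; ++i) {
      double* ai = &a[6 * i];
      ai[0] = k.k_on * (1 - c.g[i]);
      ai[1] = k.k_off * c.g[i];
      ai[2] = k.k_tx * c.g[i];
      ai[3] = k.d_m * c.m[i];
      ai[4] = k.k_p * c.m[i];
      ai[5] = k.d_p * c.p[i];
      a0 += ai[0] + ai[1] + ai[2] + ai[3] + ai[4] + ai[5];
    }
    if (a0 <= 0.0) return;  // absorbing (e.g. all rates zero)
    t += -std::log(rng.unif()) / a0;
    if (t >= t_target) return;
    double target = rng.unif() * a0, cum = 0.0;
    int i = 0, r = 0;
    bool found = false;
    for (i = 0; i < n && !found; ++i) {
      for (r = 0; r < 6; ++r) {
        cum += a[6 * i + r];
        if (cum >= target) { found = true; break; }
      }
    }
    if (found) --i; else { i = n - 1; r = 5; }
    switch (r) {
      case 0: c.g[i] = 1; break;
      case 1: c.g[i] = 0; break;
      case 2:
        // NMD mode: second-allele transcripts are degraded immediately
        if (!(k.nmd && i >= k.ploidy)) c.m[i] += 1;
        break;
      case 3: c.m[i] -= 1; break;
      case 4: c.p[i] += 1; break;
      case 5: c.p[i] -= 1; break;
    }
  }
}

uint64_t child_seed(uint64_t root, uint64_t index) {
  uint64_t x = root ^ (0x9E3779B97F4A7C15ULL * (index + 1));
  return Xoshiro::splitmix(x);
}

}  // namespace

// One steady-state snapshot per cell: columns g1,g2,m1,m2,p1,p2 (per-class
// sums). `seed` is the root seed; cell i uses a stream derived from (seed, i).
// [[Rcpp::export]]
NumericMatrix ssa_population_cpp(List par, int n_cells, double t_end,
                                 double seed) {
  Kinetics k = kinetics_from_list(par);
  NumericMatrix out(n_cells, 6);
  for (int cell = 0; cell < n_cells; ++cell) {
    Xoshiro rng(child_seed(static_cast<uint64_t>(seed),
                           static_cast<uint64_t>(cell)));
    Cell c;
    init_cell(c, k, rng);
    advance(c, k, 0.0, t_end, rng);
    double g1 = 0, g2 = 0, m1 = 0, m2 = 0, p1 = 0, p2 = 0;
    for (int i = 0; i < k.ploidy; ++i) {
      g1 += c.g[i]; m1 += c.m[i]; p1 += c.p[i];
    }
    for (int i = k.ploidy; i < 2 * k.ploidy; ++i) {
      g2 += c.g[i]; m2 += c.m[i]; p2 += c.p[i];
    }
    out(cell, 0) = g1; out(cell, 1) = g2;
    out(cell, 2) = m1; out(cell, 3) = m2;
    out(cell, 4) = p1; out(cell, 5) = p2;
    if (cell % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  colnames(out) = CharacterVector::create("g1", "g2", "m1", "m2", "p1", "p2");
  return out;
}

// Trajectory of a single cell recorded at the (sorted, non-negative) sample
// times. Columns time,g1,g2,m1,m2,p1,p2.
// [[Rcpp::export]]
NumericMatrix ssa_trajectory_cpp(List par, NumericVector times, double seed) {
  Kinetics k = kinetics_from_list(par);
  Xoshiro rng(child_seed(static_cast<uint64_t>(seed), 0));
  Cell c;
  init_cell(c, k, rng);
  int nt = times.size();
  NumericMatrix out(nt, 7);
  double t = 0.0;
  for (int j = 0; j < nt; ++j) {
    advance(c, k, t, times[j], rng);
    t = times[j];
    double g1 = 0, g2 = 0, m1 = 0, m2 = 0, p1 = 0, p2 = 0;
    for (int i = 0; i < k.ploidy; ++i) {
      g1 += c.g[i]; m1 += c.m[i]; p1 += c.p[i];
    }
    for (int i = k.ploidy; i < 2 * k.ploidy; ++i) {
      g2 += c.g[i]; m2 += c.m[i]; p2 += c.p[i];
    }
    out(j, 0) = times[j];
    out(j, 1) = g1; out(j, 2) = g2;
    out(j, 3) = m1; out(j, 4) = m2;
    out(j, 5) = p1; out(j, 6) = p2;
  }
  colnames(out) = CharacterVector::create("time", "g1", "g2", "m1", "m2",
                                          "p1", "p2");
  return out;
}
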