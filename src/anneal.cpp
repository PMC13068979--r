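// Metropolis engines: simulated annealing with an exponential cooling
// schedule, parallel tempering with neighbour temperature swaps, and
// gray-code exhaustive enumeration.  All engines share one model view that
// supports both quadratic (QUBO) and higher-order (HUBO) objectives in the
// Boolean 0/1 domain; offsets are handled on the R side.
//
// Reproducibility: a dedicated 64-bit generator is seeded per repeat /
// instance from the master seed, and uniform doubles are derived from the
// raw 64-bit stream, so results are identical across platforms.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>

using namespace Rcpp;

static inline double u01(std::mt19937_64 &g) {
  return (g() >> 11) * (1.0 / 9007199254740992.0);
}

static inline uint64_t mix_seed(uint64_t seed, uint64_t stream) {
  uint64_t z = seed * 0x9E3779B97F4A7C15ULL + stream * 0xBF58476D1CE4E5B9ULL + 1ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Model {
  bool quad;
  int n;
  std::vector<double> h, w, tcoef;
  std::vector<int> aptr, aidx, tptr, tvars, vptr, vterm;

  static Model from_r(List m) {
    Model mod;
    mod.quad = as<bool>(m["quad"]);
    mod.n = as<int>(m["n"]);
    if (mod.quad) {
      mod.h = as<std::vector<double> >(m["h"]);
      mod.aptr = as<std::vector<int> >(m["aptr"]);
      mod.aidx = as<std::vector<int> >(m["aidx"]);
      mod.w = as<std::vector<double> >(m["w"]);
    } else {
      mod.tptr = as<std::vector<int> >(m["tptr"]);
      mod.tvars = as<std::vector<int> >(m["tvars"]);
      mod.tcoef = as<std::vector<double> >(m["tcoef"]);
      mod.vptr = as<std::vector<int> >(m["vptr"]);
      mod.vterm = as<std::vector<int> >(m["vterm"]);
    }
    return mod;
  }
};

struct Walker {
  const Model *m;
  std::vector<char> b;
  std::vector<double> f;  // local fields (quadratic only)
  double E;

  void init_random(std::mt19937_64 &g) {
    b.assign(m->n, 0);
    for (int i = 0; i < m->n; ++i) b[i] = (g() & 1) ? 1 : 0;
    recompute();
  }

  void recompute() {
    E = 0.0;
    if (m->quad) {
      f.assign(m->n, 0.0);
      for (int i = 0; i < m->n; ++i) {
        f[i] = m->h[i];
        for (int p = m->aptr[i]; p < m->aptr[i + 1]; ++p)
          if (b[m->aidx[p]]) f[i] += m->w[p];
      }
      for (int i = 0; i < m->n; ++i)
        if (b[i]) E += m->h[i] + 0.5 * (f[i] - m->h[i]);
    } else {
      int nt = (int)m->tptr.size() - 1;
      for (int t = 0; t < nt; ++t) {
        bool on = true;
        for (int p = m->tptr[t]; p < m->tptr[t + 1]; ++p)
          if (!b[m->tvars[p]]) { on = false; break; }
        if (on) E += m->tcoef[t];
      }
    }
  }

  double delta(int i) const {
    if (m->quad) return (b[i] ? -1.0 : 1.0) * f[i];
    double s = 0.0;
    for (int q = m->vptr[i]; q < m->vptr[i + 1]; ++q) {
      int t = m->vterm[q];
      bool on = true;
      for (int p = m->tptr[t]; p < m->tptr[t + 1]; ++p) {
        int v = m->tvars[p];
        if (v != i && !b[v]) { on = false; break; }
      }
      if (on) s += m->tcoef[t];
    }
    return (b[i] ? -1.0 : 1.0) * s;
  }

  void flip(int i, double de) {
    b[i] ^= 1;
    E += de;
    if (m->quad) {
      double s = b[i] ? 1.0 : -1.0;
      for (int p = m->aptr[i]; p < m->aptr[i + 1]; ++p)
        f[m->aidx[p]] += s * m->w[p];
    }
  }
};

static void sweep(Walker &w, const std::vector<int> &order, double T,
                  std::mt19937_64 &g, double &bestE, std::vector<char> &bestB) {
  for (size_t k = 0; k < order.size(); ++k) {
    int i = order[k];
    double de = w.delta(i);
    if (de <= 0.0 || u01(g) < std::exp(-de / T)) {
      w.flip(i, de);
      if (w.E < bestE - 1e-12) { bestE = w.E; bestB = w.b; }
    }
  }
}

// [[Rcpp::export]]
List cpp_sa(List model, IntegerVector order, int sweeps, double t0, double zeta,
            double tmin, int repeats, double seed) {
  Model m = Model::from_r(model);
  std::vector<int> ord = as<std::vector<int> >(order);
  NumericVector energies(repeats);
  IntegerMatrix states(repeats, m.n);
  for (int r = 0; r < repeats; ++r) {
    std::mt19937_64 g(mix_seed((uint64_t)seed, (uint64_t)r));
    Walker w; w.m = &m;
    w.init_random(g);
    double bestE = w.E;
    std::vector<char> bestB = w.b;
    double T = t0;
    for (int s = 0; s < sweeps; ++s) {
      sweep(w, ord, T, g, bestE, bestB);
      T *= zeta;
      if (T < tmin) T = tmin;
    }
    energies[r] = bestE;
    for (int i = 0; i < m.n; ++i) states(r, i) = bestB[i];
  }
  return List::create(_["energies"] = energies, _["states"] = states);
}

// [[Rcpp::export]]
List cpp_pt(List model, IntegerVector order, NumericVector temps, int sweeps,
            double seed, int record_from) {
  Model m = Model::from_r(model);
  std::vector<int> ord = as<std::vector<int> >(order);
  int M = temps.size();
  std::vector<Walker> reps(M);
  std::mt19937_64 g(mix_seed((uint64_t)seed, 0xA11CEULL));
  double bestE = R_PosInf;
  std::vector<char> bestB;
  for (int k = 0; k < M; ++k) {
    reps[k].m = &m;
    reps[k].init_random(g);
    if (reps[k].E < bestE) { bestE = reps[k].E; bestB = reps[k].b; }
  }
  int nrec = (record_from >= 0 && record_from < sweeps) ? (sweeps - record_from) : 0;
  IntegerMatrix trace(nrec, m.n);
  NumericVector swap_attempts(std::max(M - 1, 0)), swap_accepts(std::max(M - 1, 0));
  int row = 0;
  for (int s = 0; s < sweeps; ++s) {
    for (int k = 0; k < M; ++k)
      sweep(reps[k], ord, temps[k], g, bestE, bestB);
    // alternate even/odd neighbour pairs each sweep
    for (int k = (s % 2); k + 1 < M; k += 2) {
      double expo = (reps[k].E - reps[k + 1].E) * (1.0 / temps[k] - 1.0 / temps[k + 1]);
      swap_attempts[k] += 1;
      if (expo >= 0.0 || u01(g) < std::exp(expo)) {
        std::swap(reps[k], reps[k + 1]);
        swap_accepts[k] += 1;
      }
    }
    if (nrec > 0 && s >= record_from) {
      for (int i = 0; i < m.n; ++i) trace(row, i) = reps[0].b[i];
      ++row;
    }
  }
  NumericVector repE(M);
  for (int k = 0; k < M; ++k) repE[k] = reps[k].E;
  IntegerVector best(m.n);
  for (int i = 0; i < m.n; ++i) best[i] = bestB[i];
  return List::create(
    _["best_energy"] = bestE, _["best_state"] = best, _["trace"] = trace,
    _["replica_energies"] = repE,
    _["swap_attempts"] = swap_attempts, _["swap_accepts"] = swap_accepts);
}

// Exhaustive minimisation by gray-code enumeration (exact oracle).
// [[Rcpp::export]]
List cpp_exact(List model, int keep) {
  Model m = Model::from_r(model);
  if (m.n > 30) stop("too many variables for exhaustive enumeration");
  Walker w; w.m = &m;
  w.b.assign(m.n, 0);
  w.recompute();
  double minE = w.E;
  std::vector<std::vector<char> > argmins;
  long long argmin_count = 1;
  argmins.push_back(w.b);
  uint64_t total = 1ULL << m.n;
  for (uint64_t k = 1; k < total; ++k) {
    int i = 0;
    uint64_t t = k;
    while (!(t & 1)) { t >>= 1; ++i; }
    double de = w.delta(i);
    w.flip(i, de);
    if (w.E < minE - 1e-9) {
      w.recompute();  // guard against drift at candidate minima
      if (w.E < minE - 1e-9) {
        minE = w.E;
        argmin_count = 1;
        argmins.clear();
        argmins.push_back(w.b);
        continue;
      }
    }
    if (std::fabs(w.E - minE) <= 1e-9) {
      ++argmin_count;
      if ((int)argmins.size() < keep) argmins.push_back(w.b);
    }
  }
  IntegerMatrix states(argmins.size(), m.n);
  for (size_t r = 0; r < argmins.size(); ++r)
    for (int i = 0; i < m.n; ++i) states(r, i) = argmins[r][i];
  return List::create(_["energy"] = minE, _["states"] = states,
                      _["argmin_count"] = (double)argmin_count);
}
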