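// Exhaustive self-avoiding-walk enumeration on the simple-cubic and the
// tetrahedral (diamond) lattice.  These routines define the lattice-space
// ground truth against which the binary encodings are verified.
//
// Conventions (shared with the R side):
//  - beads are 0-based here, 1-based in R;
//  - cubic steps are the 6 unit vectors, ordered +x,-x,+y,-y,+z,-z;
//  - diamond steps use quarter-cell integer units: bead k (0-based) steps by
//    +v_a if k is even and -v_a if k is odd, with
//    v = {(1,1,1),(1,-1,-1),(-1,1,-1),(-1,-1,1)};
//  - a contact is a pair |i-j| >= 3 on adjacent sites (bonded pairs and
//    overlapping beads never count).

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cstdint>
#include <cmath>
#include <functional>

using namespace Rcpp;

static const int CUBIC_DIRS[6][3] = {
  {1, 0, 0}, {-1, 0, 0}, {0, 1, 0}, {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
static const int DIAMOND_DIRS[4][3] = {
  {1, 1, 1}, {1, -1, -1}, {-1, 1, -1}, {-1, -1, 1}};

static inline uint64_t pack(int x, int y, int z) {
  const uint64_t B = 1 << 20;
  return ((uint64_t)(x + B) << 42) | ((uint64_t)(y + B) << 21) | (uint64_t)(z + B);
}

// adjacency of the sites occupied by bead i (0-based) and bead j on the
// infinite lattice; for the diamond lattice the step sign is fixed by the
// sublattice of bead i (even beads sit on sublattice A).
static inline bool beads_adjacent(const int *u, const int *v, bool cubic, int i) {
  int dx = v[0] - u[0], dy = v[1] - u[1], dz = v[2] - u[2];
  if (cubic) return std::abs(dx) + std::abs(dy) + std::abs(dz) == 1;
  if (std::abs(dx) != 1 || std::abs(dy) != 1 || std::abs(dz) != 1) return false;
  int sign = (i % 2 == 0) ? 1 : -1;
  return dx * dy * dz == sign;
}

struct SawScan {
  int n;                     // beads
  bool cubic;
  bool reduce;               // fix the first step (symmetry reduction)
  bool collect_all;          // keep every walk (enumerate_saws)
  int keep;                  // max argmin folds kept
  const double *eps;         // n x n pair energies (column-major), may be NULL
  std::vector<int> pos;      // 3 * n
  std::unordered_set<uint64_t> occ;
  double cur_e;
  int cur_contacts;
  long long n_walks, n_contact_walks;
  double min_e;
  long long argmin_count;
  std::vector<std::vector<int> > argmin_folds;
  std::vector<std::vector<int> > all_folds;

  int ndirs() const { return cubic ? 6 : 4; }

  void step_vec(int k, int a, int *d) const {
    if (cubic) {
      d[0] = CUBIC_DIRS[a][0]; d[1] = CUBIC_DIRS[a][1]; d[2] = CUBIC_DIRS[a][2];
    } else {
      int s = (k % 2 == 0) ? 1 : -1;
      d[0] = s * DIAMOND_DIRS[a][0]; d[1] = s * DIAMOND_DIRS[a][1]; d[2] = s * DIAMOND_DIRS[a][2];
    }
  }

  void leaf() {
    ++n_walks;
    if (cur_contacts > 0) ++n_contact_walks;
    if (collect_all) {
      all_folds.push_back(std::vector<int>(pos.begin(), pos.begin() + 3 * n));
      return;
    }
    if (cur_e < min_e - 1e-9) {
      min_e = cur_e;
      argmin_count = 1;
      argmin_folds.clear();
      argmin_folds.push_back(std::vector<int>(pos.begin(), pos.begin() + 3 * n));
    } else if (cur_e < min_e + 1e-9) {
      ++argmin_count;
      if ((int)argmin_folds.size() < keep)
        argmin_folds.push_back(std::vector<int>(pos.begin(), pos.begin() + 3 * n));
    }
  }

  void dfs(int k) {  // place bead k (0..n-1); bead 0 pre-placed
    if (k == n) { leaf(); return; }
    int d[3];
    int nd = (reduce && k == 1) ? 1 : ndirs();
    for (int a = 0; a < nd; ++a) {
      step_vec(k - 1, a, d);
      int x = pos[3 * (k - 1)] + d[0];
      int y = pos[3 * (k - 1) + 1] + d[1];
      int z = pos[3 * (k - 1) + 2] + d[2];
      uint64_t key = pack(x, y, z);
      if (occ.count(key)) continue;
      pos[3 * k] = x; pos[3 * k + 1] = y; pos[3 * k + 2] = z;
      double de = 0.0;
      int dc = 0;
      for (int j = 0; j + 3 <= k; ++j) {
        if (beads_adjacent(&pos[3 * j], &pos[3 * k], cubic, j)) {
          ++dc;
          if (eps) de += eps[j + (size_t)n * k];
        }
      }
      occ.insert(key);
      cur_e += de; cur_contacts += dc;
      dfs(k + 1);
      cur_e -= de; cur_contacts -= dc;
      occ.erase(key);
    }
  }

  void run() {
    pos.assign(3 * n, 0);
    occ.clear();
    occ.insert(pack(0, 0, 0));
    cur_e = 0.0; cur_contacts = 0;
    n_walks = n_contact_walks = 0;
    min_e = R_PosInf; argmin_count = 0;
    if (n == 1) { leaf(); return; }
    dfs(1);
  }
};

static List folds_to_list(const std::vector<std::vector<int> > &folds, int n) {
  List out(folds.size());
  for (size_t i = 0; i < folds.size(); ++i) {
    IntegerMatrix m(n, 3);
    for (int k = 0; k < n; ++k)
      for (int c = 0; c < 3; ++c) m(k, c) = folds[i][3 * k + c];
    out[i] = m;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_saw_scan(int n, std::string kind, bool reduce, Nullable<NumericMatrix> pair_eps,
                  bool collect_all, int keep) {
  SawScan s;
  s.n = n;
  s.cubic = (kind == "cartesian");
  s.reduce = reduce;
  s.collect_all = collect_all;
  s.keep = keep;
  NumericMatrix em;
  s.eps = NULL;
  if (pair_eps.isNotNull()) {
    em = pair_eps.get();
    if (em.nrow() != n || em.ncol() != n) stop("pair_eps must be n x n");
    s.eps = em.begin();
  }
  s.run();
  return List::create(
    _["n_walks"] = (double)s.n_walks,
    _["n_contact_walks"] = (double)s.n_contact_walks,
    _["min_energy"] = s.min_e,
    _["argmin_count"] = (double)s.argmin_count,
    _["folds"] = folds_to_list(s.collect_all ? s.all_folds : s.argmin_folds, n));
}

// Exhaustive enumeration of chain placements on a finite lattice, with the
// coordinate-model bead-parity convention: bead 0 occupies a parity-0 site.
// This is the feasible space of the coordinate-based encodings.
// [[Rcpp::export]]
List cpp_lattice_fold_scan(List adj, IntegerVector parity, int n_beads,
                           NumericMatrix pair_eps, int keep) {
  int ns = adj.size();
  std::vector<std::vector<int> > nb(ns);
  std::vector<char> amat((size_t)ns * ns, 0);
  for (int i = 0; i < ns; ++i) {
    IntegerVector v = adj[i];
    for (int j = 0; j < v.size(); ++j) {
      nb[i].push_back(v[j] - 1);
      amat[(size_t)i * ns + (v[j] - 1)] = 1;
    }
  }
  std::vector<int> path(n_beads);
  std::vector<char> used(ns, 0);
  double min_e = R_PosInf;
  long long argmin_count = 0, n_folds = 0;
  std::vector<std::vector<int> > argmin_folds;
  std::vector<double> estack(n_beads, 0.0);

  // iterative DFS with explicit recursion via lambda
  std::function<void(int, double)> dfs = [&](int k, double e) {
    if (k == n_beads) {
      ++n_folds;
      if (e < min_e - 1e-9) {
        min_e = e; argmin_count = 1; argmin_folds.clear();
        argmin_folds.push_back(path);
      } else if (e < min_e + 1e-9) {
        ++argmin_count;
        if ((int)argmin_folds.size() < keep) argmin_folds.push_back(path);
      }
      return;
    }
    for (size_t t = 0; t < nb[path[k - 1]].size(); ++t) {
      int s = nb[path[k - 1]][t];
      if (used[s]) continue;
      double de = 0.0;
      for (int j = 0; j + 3 <= k; ++j)
        if (amat[(size_t)path[j] * ns + s]) de += pair_eps(j, k);
      path[k] = s; used[s] = 1;
      dfs(k + 1, e + de);
      used[s] = 0;
    }
  };

  for (int s0 = 0; s0 < ns; ++s0) {
    if (parity[s0] != 0) continue;
    path[0] = s0; used[s0] = 1;
    dfs(1, 0.0);
    used[s0] = 0;
  }
  List folds(argmin_folds.size());
  for (size_t i = 0; i < argmin_folds.size(); ++i) {
    IntegerVector p(n_beads);
    for (int k = 0; k < n_beads; ++k) p[k] = argmin_folds[i][k] + 1;
    folds[i] = p;
  }
  return List::create(
    _["n_folds"] = (double)n_folds,
    _["min_energy"] = min_e,
    _["argmin_count"] = (double)argmin_count,
    _["folds"] = folds);
}
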