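#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Generalized Louvain on a symmetric gain ("modularity") matrix B.
// The quality of a partition is sum_{i,j same community} B_ij (diagonal
// included; it is constant across partitions, so it never affects moves).
// Greedy two-phase optimization: local node moves in a seeded random sweep
// order, then aggregation of communities into super-nodes, repeated until no
// move improves the quality. Deterministic given the seed.

namespace {

struct XorShift {
  uint32_t state;
  explicit XorShift(uint32_t seed) {
    state = seed ? seed : 0x9E3779B9u;
    // scramble a few rounds so nearby seeds diverge
    for (int k = 0; k < 8; ++k) next();
  }
  uint32_t next() {
    uint32_t x = state;
    x ^= x << 13; x ^= x >> 17; x ^= x << 5;
    return state = x;
  }
  // uniform integer in [0, n)
  uint32_t below(uint32_t n) { return next() % n; }
};

void shuffle_order(std::vector<int>& v, XorShift& rng) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)rng.below((uint32_t)(i + 1));
    std::swap(v[i], v[j]);
  }
}

// One level of local moving; B is n x n (dense, symmetric), comm is the
// community of each node (in 0..n-1). Returns true if any move was made.
bool local_move(const std::vector<double>& B, int n, std::vector<int>& comm,
                XorShift& rng) {
  std::vector<int> order(n), cand(n);
  for (int i = 0; i < n; ++i) { order[i] = i; cand[i] = i; }
  bool any_move = false;
  bool moved = true;
  const double eps = 1e-12;
  std::vector<double> link(n);  // link[c] = sum_{j in c, j != i} B_ij
  while (moved) {
    moved = false;
    shuffle_order(order, rng);
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      std::fill(link.begin(), link.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        if (j != i) link[comm[j]] += B[(size_t)i * n + j];
      }
      int ci = comm[i];
      double best_gain = eps;
      int best_c = ci;
      // candidates scanned in random order so exact ties between equally
      // good target communities are sampled uniformly across runs instead
      // of resolving to a fixed index
      shuffle_order(cand, rng);
      for (int ck = 0; ck < n; ++ck) {
        int c = cand[ck];
        if (c == ci) continue;
        double gain = 2.0 * (link[c] - link[ci]);
        if (gain > best_gain) { best_gain = gain; best_c = c; }
      }
      if (best_c != ci) {
        comm[i] = best_c;
        moved = true;
        any_move = true;
      }
    }
  }
  return any_move;
}

// Relabel communities to consecutive 0..k-1 in order of first appearance.
int compress_labels(std::vector<int>& comm) {
  std::vector<int> map(comm.size(), -1);
  int k = 0;
  for (size_t i = 0; i < comm.size(); ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = k++;
    comm[i] = map[comm[i]];
  }
  return k;
}

std::vector<int> louvain_run(const std::vector<double>& B0, int n0,
                             XorShift& rng) {
  std::vector<double> B = B0;
  int n = n0;
  std::vector<int> node_comm(n0);       // community of each original node
  for (int i = 0; i < n0; ++i) node_comm[i] = i;
  std::vector<int> comm(n);
  while (true) {
    for (int i = 0; i < n; ++i) comm[i] = i;
    bool improved = local_move(B, n, comm, rng);
    int k = compress_labels(comm);
    if (!improved || k == n) break;
    // map original nodes through this level
    for (int i = 0; i < n0; ++i) node_comm[i] = comm[node_comm[i]];
    // aggregate B into k x k
    std::vector<double> Bn((size_t)k * k, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        Bn[(size_t)comm[i] * k + comm[j]] += B[(size_t)i * n + j];
    B.swap(Bn);
    n = k;
  }
  compress_labels(node_comm);
  return node_comm;
}

std::vector<double> to_vec(const NumericMatrix& B) {
  int n = B.nrow();
  std::vector<double> v((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      v[(size_t)i * n + j] = B(i, j);
  return v;
}

}  // namespace

// [[Rcpp::export(name = ".louvain_once_cpp")]]
IntegerVector louvain_once_cpp(NumericMatrix B, int seed) {
  int n = B.nrow();
  if (B.ncol() != n) stop("gain matrix must be square");
  XorShift rng((uint32_t)seed);
  std::vector<double> Bv = to_vec(B);
  std::vector<int> comm = louvain_run(Bv, n, rng);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = comm[i] + 1;
  return out;
}

// [[Rcpp::export(name = ".louvain_runs_cpp")]]
IntegerMatrix louvain_runs_cpp(NumericMatrix B, int n_runs, int seed) {
  int n = B.nrow();
  if (B.ncol() != n) stop("gain matrix must be square");
  std::vector<double> Bv = to_vec(B);
  IntegerMatrix out(n_runs, n);
  for (int r = 0; r < n_runs; ++r) {
    XorShift rng((uint32_t)(seed + 1013904223 * (r + 1)));
    std::vector<int> comm = louvain_run(Bv, n, rng);
    for (int i = 0; i < n; ++i) out(r, i) = comm[i] + 1;
  }
  return out;
}

// Co-assignment counts over n_runs Louvain runs (used by versatility and
// consensus procedures); entry (i, j) of `counts` counts runs where i and j
// share a community (diagonal = n_runs); `k` holds each run's module count.
// [[Rcpp::export(name = ".louvain_coassign_cpp")]]
List louvain_coassign_cpp(NumericMatrix B, int n_runs, int seed) {
  int n = B.nrow();
  if (B.ncol() != n) stop("gain matrix must be square");
  std::vector<double> Bv = to_vec(B);
  NumericMatrix counts(n, n);
  IntegerVector ks(n_runs);
  for (int r = 0; r < n_runs; ++r) {
    XorShift rng((uint32_t)(seed + 1013904223 * (r + 1)));
    std::vector<int> comm = louvain_run(Bv, n, rng);
    int k = 0;
    for (int i = 0; i < n; ++i) k = std::max(k, comm[i] + 1);
    ks[r] = k;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (comm[i] == comm[j]) counts(i, j) += 1.0;
  }
  return List::create(_["counts"] = counts, _["k"] = ks);
}

// Minimum-cost perfect assignment on a square cost matrix (Hungarian
// algorithm with potentials, O(n^3)). Returns, for each row, the 1-based
// column assigned to it. Used to align arbitrary module labels across
// Louvain runs by maximal overlap (pass negated overlap counts as cost).
// [[Rcpp::export(name = ".assignment_cpp")]]
IntegerVector assignment_cpp(NumericMatrix cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = 1e100;
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = 0;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j) if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
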