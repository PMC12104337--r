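#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <numeric>

using namespace Rcpp;

// Weighted-modularity Louvain on a dense similarity graph.
//
// Conventions: the input matrix holds edge weights w_ij (i != j); the
// diagonal is ignored at the input level (self-similarity carries no
// information about community structure). During aggregation the internal
// weight of a merged community is kept as a self term counted twice
// (sum over ordered pairs), so node strength k_i = self_i + sum_j w_ij and
// 2m = sum_i k_i stay invariant across levels.

namespace {

struct Level {
  int n;
  std::vector<double> w;     // n x n off-diagonal weights, column-major
  std::vector<double> self;  // double-counted internal weight per node
};

inline double &W(Level &L, int i, int j) { return L.w[i + (size_t)L.n * j]; }
inline double Wc(const Level &L, int i, int j) {
  return L.w[i + (size_t)L.n * j];
}

// One pass of greedy local moves; returns true if any node moved.
bool local_moves(Level &L, std::vector<int> &comm, double gamma, double two_m,
                 std::mt19937 &rng) {
  const int n = L.n;
  std::vector<double> k(n), tot;
  for (int i = 0; i < n; ++i) {
    double s = L.self[i];
    for (int j = 0; j < n; ++j)
      if (j != i) s += Wc(L, i, j);
    k[i] = s;
  }
  int ncomm = *std::max_element(comm.begin(), comm.end()) + 1;
  tot.assign(ncomm, 0.0);
  std::vector<int> csize(ncomm, 0);
  for (int i = 0; i < n; ++i) {
    tot[comm[i]] += k[i];
    csize[comm[i]] += 1;
  }

  std::vector<int> order(n);
  std::iota(order.begin(), order.end(), 0);
  bool any_move = false;
  bool improved = true;
  int pass = 0;
  std::vector<double> links(ncomm);
  std::vector<int> touched;
  touched.reserve(n);
  while (improved && pass < 128) {
    improved = false;
    ++pass;
    std::shuffle(order.begin(), order.end(), rng);
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      int c_old = comm[i];
      // weights from i to each community (excluding i itself)
      touched.clear();
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double wij = Wc(L, i, j);
        if (wij == 0.0) continue;
        int c = comm[j];
        if (links[c] == 0.0) touched.push_back(c);
        links[c] += wij;
      }
      tot[c_old] -= k[i];
      csize[c_old] -= 1;
      if (links[c_old] == 0.0) touched.push_back(c_old);
      double best_gain = links[c_old] - gamma * k[i] * tot[c_old] / two_m;
      int best_c = c_old;
      // moving out into an empty community has gain 0; some id is always
      // free because the n-1 remaining nodes cannot fill all ncomm slots
      if (0.0 > best_gain + 1e-12) {
        for (int c = 0; c < ncomm; ++c)
          if (csize[c] == 0) {
            best_gain = 0.0;
            best_c = c;
            break;
          }
      }
      for (int t = 0; t < (int)touched.size(); ++t) {
        int c = touched[t];
        if (c == c_old) continue;
        double gain = links[c] - gamma * k[i] * tot[c] / two_m;
        // strict improvement; exact ties keep the earlier community,
        // which is deterministic given the shuffled visit order
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_c = c;
        }
      }
      comm[i] = best_c;
      tot[best_c] += k[i];
      csize[best_c] += 1;
      if (best_c != c_old) {
        improved = true;
        any_move = true;
      }
      for (int t = 0; t < (int)touched.size(); ++t) links[touched[t]] = 0.0;
    }
  }
  return any_move;
}

// Renumber communities to 0..K-1 in order of first appearance.
int renumber(std::vector<int> &comm) {
  std::vector<int> map(comm.size(), -1);
  int next = 0;
  for (size_t i = 0; i < comm.size(); ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = next++;
    comm[i] = map[comm[i]];
  }
  return next;
}

Level aggregate(const Level &L, const std::vector<int> &comm, int ncomm) {
  Level A;
  A.n = ncomm;
  A.w.assign((size_t)ncomm * ncomm, 0.0);
  A.self.assign(ncomm, 0.0);
  for (int i = 0; i < L.n; ++i) {
    A.self[comm[i]] += L.self[i];
    for (int j = 0; j < L.n; ++j) {
      if (j == i) continue;
      double wij = Wc(L, i, j);
      if (wij == 0.0) continue;
      if (comm[i] == comm[j])
        A.self[comm[i]] += wij;  // ordered pairs: double counted
      else
        A.w[comm[i] + (size_t)ncomm * comm[j]] += wij;
    }
  }
  return A;
}

}  // namespace

// [[Rcpp::export(name = ".louvain_cpp")]]
List louvain_cpp(NumericMatrix weights, double gamma, int seed) {
  const int n = weights.nrow();
  if (weights.ncol() != n) stop("weight matrix must be square");
  Level L;
  L.n = n;
  L.w.assign((size_t)n * n, 0.0);
  L.self.assign(n, 0.0);
  double two_m = 0.0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (i != j) {
        double v = weights(i, j);
        L.w[i + (size_t)n * j] = v;
        two_m += v;
      }
  if (two_m <= 0) stop("total edge weight must be positive");

  std::mt19937 rng((unsigned)seed);
  std::vector<int> final_comm(n);
  std::iota(final_comm.begin(), final_comm.end(), 0);

  Level cur = L;
  std::vector<int> node2final(n);
  std::iota(node2final.begin(), node2final.end(), 0);  // original -> cur node
  while (true) {
    std::vector<int> comm(cur.n);
    std::iota(comm.begin(), comm.end(), 0);
    bool moved = local_moves(cur, comm, gamma, two_m, rng);
    int ncomm = renumber(comm);
    for (int i = 0; i < n; ++i) node2final[i] = comm[node2final[i]];
    if (!moved || ncomm == cur.n) break;
    cur = aggregate(cur, comm, ncomm);
  }

  // modularity of the returned labels on the original graph,
  // Q = (1/2m) sum_ij [w_ij - gamma k_i k_j / 2m] delta(c_i, c_j), i != j
  std::vector<double> k(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (j != i) k[i] += Wc(L, i, j);
  int ncomm = *std::max_element(node2final.begin(), node2final.end()) + 1;
  std::vector<double> win(ncomm, 0.0), wtot(ncomm, 0.0);
  for (int i = 0; i < n; ++i) {
    wtot[node2final[i]] += k[i];
    for (int j = 0; j < n; ++j)
      if (j != i && node2final[i] == node2final[j]) win[node2final[i]] += Wc(L, i, j);
  }
  double Q = 0.0;
  for (int c = 0; c < ncomm; ++c)
    Q += win[c] / two_m - gamma * (wtot[c] / two_m) * (wtot[c] / two_m);

  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) labels[i] = node2final[i] + 1;
  return List::create(_["labels"] = labels, _["modularity"] = Q,
                      _["n_communities"] = ncomm);
}
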