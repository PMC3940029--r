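// Agglomerative clustering engine: seed/grow, merge and reassignment phases,
// all gated by a minimum mean intra-cluster similarity T.
//
// Conventions: element indices are 0-based internally, 1-based at the R
// boundary. Cluster ids in assignment vectors are renumbered 1..k in order
// of first appearance before returning to R. Every similarity-matrix read
// goes through sim() so that lookup counts can be reported (the engine's
// cost model is O(k n^2) similarity lookups).

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

inline double sim(const NumericMatrix& S, int i, int j, long long& ops) {
  ++ops;
  return S(i, j);
}

inline double n_pairs(double m) { return m * (m - 1.0) / 2.0; }

// Admission comparisons use a hair of relative slack so that thresholds
// read off recorded means are not defeated by last-ulp summation noise
// (e.g. a constant matrix whose recorded means differ from the constant by
// one representation step).
inline double admit_level(double threshold) {
  return threshold - 1e-12 * std::max(1.0, std::fabs(threshold));
}

// Renumber cluster ids to 1..k in order of first appearance (element order).
IntegerVector canonical_assignment(const std::vector<int>& g) {
  const int n = (int)g.size();
  std::vector<int> remap(n, 0);
  IntegerVector out(n);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int c = g[i];
    if (remap[c] == 0) remap[c] = ++next;
    out[i] = remap[c];
  }
  return out;
}

// Grow a single cluster from the (sorted, 0-based) unassigned set.
std::vector<int> seed_and_grow_impl(const NumericMatrix& S,
                                    const std::vector<int>& un, double T,
                                    long long& ops) {
  const int u = (int)un.size();
  if (u == 1) return std::vector<int>(1, un[0]);

  const double t_eff = admit_level(T);
  // Seed: unassigned pair of maximal similarity; ties -> lowest (i, j).
  int bi = -1, bj = -1;
  double best = R_NegInf;
  for (int a = 0; a < u; ++a)
    for (int b = a + 1; b < u; ++b) {
      double s = sim(S, un[a], un[b], ops);
      if (s > best) { best = s; bi = a; bj = b; }
    }
  if (best < t_eff) return std::vector<int>(1, un[0]);  // un sorted: lowest index

  std::vector<char> used(u, 0);
  used[bi] = 1; used[bj] = 1;
  std::vector<int> mem;
  mem.push_back(un[bi]); mem.push_back(un[bj]);

  // cs[a] = sum of similarities from candidate a to current members.
  std::vector<double> cs(u, 0.0);
  for (int a = 0; a < u; ++a)
    if (!used[a]) cs[a] = sim(S, un[a], un[bi], ops) + sim(S, un[a], un[bj], ops);

  double pair_sum = best;
  double npairs = 1.0;
  int m = 2, remaining = u - 2;

  while (remaining > 0) {
    int ba = -1;
    double bcs = R_NegInf;
    for (int a = 0; a < u; ++a)
      if (!used[a] && cs[a] > bcs) { bcs = cs[a]; ba = a; }  // ties -> lowest index
    double new_mean = (pair_sum + bcs) / (npairs + m);
    if (!(new_mean >= t_eff)) break;
    used[ba] = 1;
    mem.push_back(un[ba]);
    pair_sum += bcs;
    npairs += m;
    ++m;
    --remaining;
    for (int a = 0; a < u; ++a)
      if (!used[a]) cs[a] += sim(S, un[a], un[ba], ops);
  }
  std::sort(mem.begin(), mem.end());
  return mem;
}

// Partition all elements by repeated seed-and-grow. Fills g with 0-based ids.
void grow_all_impl(const NumericMatrix& S, double T, std::vector<int>& g,
                   long long& ops) {
  const int n = S.nrow();
  g.assign(n, -1);
  int next_id = 0, assigned = 0;
  std::vector<int> un;
  while (assigned < n) {
    un.clear();
    for (int i = 0; i < n; ++i)
      if (g[i] < 0) un.push_back(i);
    std::vector<int> mem = seed_and_grow_impl(S, un, T, ops);
    for (size_t i = 0; i < mem.size(); ++i) g[mem[i]] = next_id;
    assigned += (int)mem.size();
    ++next_id;
  }
}

// Greedy merging: repeatedly join the cluster pair whose union has the
// highest mean intra-cluster similarity while that mean stays >= T.
int merge_pass_impl(const NumericMatrix& S, std::vector<int>& g, double T,
                    long long& ops) {
  const int n = S.nrow();
  int k = 0;
  for (int i = 0; i < n; ++i) k = std::max(k, g[i] + 1);
  if (k < 2) return 0;

  std::vector<double> psum(k, 0.0), msize(k, 0.0);
  std::vector<double> cross((size_t)k * k, 0.0);
  for (int i = 0; i < n; ++i) msize[g[i]] += 1.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = sim(S, i, j, ops);
      if (g[i] == g[j]) psum[g[i]] += s;
      else {
        int a = std::min(g[i], g[j]), b = std::max(g[i], g[j]);
        cross[(size_t)a * k + b] += s;
      }
    }

  const double t_eff = admit_level(T);
  std::vector<char> alive(k, 1);
  int merges = 0;
  for (;;) {
    int ba = -1, bb = -1;
    double best = R_NegInf;
    for (int a = 0; a < k; ++a) {
      if (!alive[a]) continue;
      for (int b = a + 1; b < k; ++b) {
        if (!alive[b]) continue;
        double um = (psum[a] + psum[b] + cross[(size_t)a * k + b]) /
                    n_pairs(msize[a] + msize[b]);
        if (um > best) { best = um; ba = a; bb = b; }  // ties -> lowest (a, b)
      }
    }
    if (ba < 0 || !(best >= t_eff)) break;
    psum[ba] += psum[bb] + cross[(size_t)ba * k + bb];
    msize[ba] += msize[bb];
    for (int c = 0; c < k; ++c) {
      if (!alive[c] || c == ba || c == bb) continue;
      double cb = (c < bb) ? cross[(size_t)c * k + bb] : cross[(size_t)bb * k + c];
      if (c < ba) cross[(size_t)c * k + ba] += cb;
      else cross[(size_t)ba * k + c] += cb;
    }
    alive[bb] = 0;
    for (int i = 0; i < n; ++i)
      if (g[i] == bb) g[i] = ba;
    ++merges;
  }
  return merges;
}

// Local refinement: each element, in index order, moves to the cluster with
// which it has the highest mean similarity (incumbent wins ties), provided
// both affected clusters still satisfy mean >= T after the move.
void reassign_pass_impl(const NumericMatrix& S, std::vector<int>& g, double T,
                        int max_passes, long long& ops, int& passes,
                        bool& converged) {
  const int n = S.nrow();
  int k = 0;
  for (int i = 0; i < n; ++i) k = std::max(k, g[i] + 1);
  const double t_eff = admit_level(T);
  passes = 0;
  converged = true;
  if (k < 2) return;

  // ms[e + n*c] = sum of similarities from element e to members of cluster c
  // (includes S(e,e) when c is e's own cluster).
  std::vector<double> ms((size_t)n * k, 0.0);
  std::vector<double> psum(k, 0.0);
  std::vector<int> msize(k, 0);
  for (int i = 0; i < n; ++i) msize[g[i]] += 1;
  for (int j = 0; j < n; ++j) {
    const int c = g[j];
    for (int i = 0; i < n; ++i) ms[(size_t)i + (size_t)n * c] += sim(S, i, j, ops);
  }
  for (int c = 0; c < k; ++c) {
    double tot = 0.0;
    for (int e = 0; e < n; ++e)
      if (g[e] == c) tot += ms[(size_t)e + (size_t)n * c] - S(e, e);
    psum[c] = tot / 2.0;
  }

  converged = false;
  while (passes < max_passes) {
    int moves = 0;
    for (int e = 0; e < n; ++e) {
      const int curr = g[e];
      const double self = S(e, e);
      double own = (msize[curr] >= 2)
                       ? (ms[(size_t)e + (size_t)n * curr] - self) / (msize[curr] - 1)
                       : R_NegInf;
      int bestc = -1;
      double bestv = R_NegInf;
      for (int c = 0; c < k; ++c) {
        if (c == curr || msize[c] == 0) continue;
        double v = ms[(size_t)e + (size_t)n * c] / msize[c];
        if (v > bestv) { bestv = v; bestc = c; }  // ties -> lowest cluster id
      }
      if (bestc < 0 || !(bestv > own)) continue;  // incumbent wins ties

      double tgt_mean = (psum[bestc] + ms[(size_t)e + (size_t)n * bestc]) /
                        (n_pairs((double)msize[bestc]) + msize[bestc]);
      bool ok = tgt_mean >= t_eff;
      if (ok && msize[curr] >= 3) {
        double rem = psum[curr] - (ms[(size_t)e + (size_t)n * curr] - self);
        ok = rem / n_pairs((double)msize[curr] - 1.0) >= t_eff;
      }
      if (!ok) continue;

      psum[curr] -= ms[(size_t)e + (size_t)n * curr] - self;
      psum[bestc] += ms[(size_t)e + (size_t)n * bestc];
      msize[curr] -= 1;
      msize[bestc] += 1;
      for (int f = 0; f < n; ++f) {
        double s = sim(S, f, e, ops);
        ms[(size_t)f + (size_t)n * curr] -= s;
        ms[(size_t)f + (size_t)n * bestc] += s;
      }
      g[e] = bestc;
      ++moves;
    }
    ++passes;
    if (moves == 0) { converged = true; break; }
  }
}

std::vector<int> r_to_zero_based(const IntegerVector& assignment) {
  std::vector<int> g(assignment.size());
  for (int i = 0; i < assignment.size(); ++i) g[i] = assignment[i] - 1;
  return g;
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_seed_and_grow(NumericMatrix S, IntegerVector unassigned,
                                double threshold) {
  long long ops = 0;
  std::vector<int> un(unassigned.size());
  for (int i = 0; i < unassigned.size(); ++i) un[i] = unassigned[i] - 1;
  std::sort(un.begin(), un.end());
  std::vector<int> mem = seed_and_grow_impl(S, un, threshold, ops);
  IntegerVector out(mem.size());
  for (size_t i = 0; i < mem.size(); ++i) out[i] = mem[i] + 1;
  return out;
}

// [[Rcpp::export]]
List cpp_grow_all(NumericMatrix S, double threshold) {
  long long ops = 0;
  std::vector<int> g;
  grow_all_impl(S, threshold, g, ops);
  return List::create(_["assignment"] = canonical_assignment(g),
                      _["lookups"] = (double)ops);
}

// [[Rcpp::export]]
List cpp_merge_pass(NumericMatrix S, IntegerVector assignment, double threshold) {
  long long ops = 0;
  std::vector<int> g = r_to_zero_based(assignment);
  int merges = merge_pass_impl(S, g, threshold, ops);
  return List::create(_["assignment"] = canonical_assignment(g),
                      _["n_merges"] = merges,
                      _["lookups"] = (double)ops);
}

// [[Rcpp::export]]
List cpp_reassign_pass(NumericMatrix S, IntegerVector assignment,
                       double threshold, int max_passes) {
  long long ops = 0;
  int passes = 0;
  bool converged = true;
  std::vector<int> g = r_to_zero_based(assignment);
  reassign_pass_impl(S, g, threshold, max_passes, ops, passes, converged);
  return List::create(_["assignment"] = canonical_assignment(g),
                      _["passes"] = passes,
                      _["converged"] = converged,
                      _["lookups"] = (double)ops);
}

// [[Rcpp::export]]
List cpp_cluster_at_threshold(NumericMatrix S, double threshold, int max_passes) {
  long long ops = 0;
  std::vector<int> g;
  grow_all_impl(S, threshold, g, ops);
  int merges = merge_pass_impl(S, g, threshold, ops);
  int passes = 0;
  bool converged = true;
  reassign_pass_impl(S, g, threshold, max_passes, ops, passes, converged);
  return List::create(_["assignment"] = canonical_assignment(g),
                      _["n_merges"] = merges,
                      _["passes"] = passes,
                      _["converged"] = converged,
                      _["lookups"] = (double)ops);
}

// Per-cluster mean intra-cluster similarity; NA for singleton clusters.
// Cost is sum over clusters of m_c^2, not n^2.
// [[Rcpp::export]]
NumericVector cpp_cluster_means(NumericMatrix S, IntegerVector assignment) {
  const int n = S.nrow();
  int k = 0;
  for (int i = 0; i < n; ++i) k = std::max(k, (int)assignment[i]);
  std::vector<std::vector<int> > members(k);
  for (int i = 0; i < n; ++i) members[assignment[i] - 1].push_back(i);
  NumericVector out(k);
  for (int c = 0; c < k; ++c) {
    const std::vector<int>& mem = members[c];
    const int m = (int)mem.size();
    if (m < 2) { out[c] = NA_REAL; continue; }
    double tot = 0.0;
    for (int a = 0; a < m; ++a)
      for (int b = a + 1; b < m; ++b) tot += S(mem[a], mem[b]);
    out[c] = tot / n_pairs((double)m);
  }
  return out;
}
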