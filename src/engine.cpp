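#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// ---- signed-permutation ranking ------------------------------------------
//
// A signed permutation of n elements is indexed as
//   rank = lehmer(|perm|) * 2^n + signBits,
// signBits bit i set iff element i is negative.  Used by the exhaustive
// breadth-first reversal-distance oracle.

static inline long rank_core(const int* r, int n) {
  long f[9];
  f[0] = 1;
  for (int i = 1; i <= n; ++i) f[i] = f[i - 1] * i;
  int a[8];
  long sign_bits = 0;
  for (int i = 0; i < n; ++i) {
    int v = r[i];
    a[i] = (v > 0 ? v : -v) - 1;
    if (v < 0) sign_bits |= (1L << i);
  }
  long lr = 0;
  for (int i = 0; i < n; ++i) {
    int c = 0;
    for (int j = i + 1; j < n; ++j)
      if (a[j] < a[i]) ++c;
    lr += c * f[n - 1 - i];
  }
  return lr * (1L << n) + sign_bits;
}

static inline void unrank_core(long idx, int n, int* r) {
  long f[9];
  f[0] = 1;
  for (int i = 1; i <= n; ++i) f[i] = f[i - 1] * i;
  long sign_bits = idx & ((1L << n) - 1);
  long lr = idx >> n;
  bool used[8] = {false, false, false, false, false, false, false, false};
  for (int i = 0; i < n; ++i) {
    long q = lr / f[n - 1 - i];
    lr %= f[n - 1 - i];
    int cnt = -1, v = -1;
    for (int x = 0; x < n; ++x) {
      if (!used[x]) {
        ++cnt;
        if (cnt == q) { v = x; break; }
      }
    }
    used[v] = true;
    r[i] = v + 1;
    if (sign_bits & (1L << i)) r[i] = -r[i];
  }
}

// [[Rcpp::export]]
double perm_rank(IntegerVector perm) {
  int n = perm.size();
  if (n < 1 || n > 8) stop("perm_rank supports n in 1..8");
  int r[8];
  for (int i = 0; i < n; ++i) r[i] = perm[i];
  return (double)rank_core(r, n);
}

// Breadth-first search over the full reversal graph of signed permutations
// of size n; returns the distance of every permutation (indexed by rank)
// from the identity.
// [[Rcpp::export]]
IntegerVector bfs_distance_table(int n) {
  if (n < 1 || n > 8) stop("oracle limit: n must be in 1..8");
  long f = 1;
  for (int i = 1; i <= n; ++i) f *= i;
  long size = f * (1L << n);
  std::vector<uint8_t> dist(size, 255);
  std::vector<int> cur, nxt;
  int id[8];
  for (int i = 0; i < n; ++i) id[i] = i + 1;
  long r0 = rank_core(id, n);
  dist[r0] = 0;
  cur.push_back((int)r0);
  uint8_t d = 0;
  int p[8], q[8];
  while (!cur.empty()) {
    nxt.clear();
    ++d;
    for (size_t s = 0; s < cur.size(); ++s) {
      unrank_core(cur[s], n, p);
      for (int a = 0; a < n; ++a) {
        for (int b = a; b < n; ++b) {
          for (int i = 0; i < n; ++i) q[i] = p[i];
          for (int i = a, j = b; i <= j; ++i, --j) {
            int ti = p[i], tj = p[j];
            q[i] = -tj;
            q[j] = -ti;
          }
          long rk = rank_core(q, n);
          if (dist[rk] == 255) {
            dist[rk] = d;
            nxt.push_back((int)rk);
          }
        }
      }
    }
    cur.swap(nxt);
  }
  IntegerVector out(size);
  for (long i = 0; i < size; ++i) out[i] = dist[i];
  return out;
}

// ---- Sankoff small-parsimony scan ----------------------------------------
//
// Scores many tree topologies under per-arm state spaces with arbitrary
// integer transition costs (shortest valid-flip paths between arrangement
// states).  Trees are ape edge matrices in postorder; tips 1..ntips,
// internal nodes ntips+1 .. 2*ntips-1 with the traversal root at ntips+1.
//
// leafCosts: one numeric S x ntips matrix per arm (Inf = state not allowed
// at that tip); costMats: one S x S matrix per arm.

// [[Rcpp::export]]
NumericVector sankoff_scan(List edgeList, int ntips, List leafCosts,
                           List costMats) {
  int narm = leafCosts.size();
  if (costMats.size() != narm) stop("leafCosts and costMats must be parallel");
  int ntree = edgeList.size();
  NumericVector scores(ntree);

  std::vector<NumericMatrix> lc, cm;
  for (int k = 0; k < narm; ++k) {
    lc.push_back(as<NumericMatrix>(leafCosts[k]));
    cm.push_back(as<NumericMatrix>(costMats[k]));
    if (lc[k].ncol() != ntips) stop("leaf cost matrix does not match ntips");
  }

  for (int t = 0; t < ntree; ++t) {
    IntegerMatrix e = edgeList[t];
    int ne = e.nrow();
    int nnode = 0;
    for (int i = 0; i < ne; ++i) {
      if (e(i, 0) > nnode) nnode = e(i, 0);
      if (e(i, 1) > nnode) nnode = e(i, 1);
    }
    double total = 0.0;
    for (int k = 0; k < narm; ++k) {
      int S = cm[k].nrow();
      std::vector<double> C((size_t)nnode * S, 0.0);
      for (int tip = 0; tip < ntips; ++tip)
        for (int s = 0; s < S; ++s)
          C[(size_t)tip * S + s] = lc[k](s, tip);
      for (int i = 0; i < ne; ++i) {
        int par = e(i, 0) - 1, ch = e(i, 1) - 1;
        for (int s = 0; s < S; ++s) {
          double mn = R_PosInf;
          for (int u = 0; u < S; ++u) {
            double v = C[(size_t)ch * S + u] + cm[k](u, s);
            if (v < mn) mn = v;
          }
          C[(size_t)par * S + s] += mn;
        }
      }
      int root = ntips; // 0-based index of node ntips+1
      double best = R_PosInf;
      for (int s = 0; s < S; ++s)
        if (C[(size_t)root * S + s] < best) best = C[(size_t)root * S + s];
      total += best;
    }
    scores[t] = total;
  }
  return scores;
}
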