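#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving pairwise rewiring of a mixed directed/undirected edge
// list sharing one occupancy space (at most one edge per unordered node
// pair). Directed swaps (a->b, c->d) -> (a->d, c->b) preserve in- and
// out-degree sequences; undirected double-edge swaps preserve the degree
// sequence. The budget counts ATTEMPTS; attempts that would create a
// self-loop or land on an occupied pair are rejected and not retried, which
// guarantees termination on swap-poor graphs (a star is a fixed point).
// Uses R's RNG so results are reproducible under set.seed().

static inline long long ukey(int a, int b, int n) {
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return (long long)(lo - 1) * n + (hi - 1);
}

// [[Rcpp::export]]
IntegerMatrix rewire_edgelist(IntegerMatrix edges, LogicalVector directed,
                              int q, int n) {
  int m = edges.nrow();
  IntegerMatrix out = clone(edges);
  std::unordered_set<long long> occ;
  std::vector<int> didx, uidx;
  for (int e = 0; e < m; ++e) {
    occ.insert(ukey(out(e, 0), out(e, 1), n));
    if (directed[e]) didx.push_back(e); else uidx.push_back(e);
  }

  int nd = didx.size(), nu = uidx.size();
  long long att_d = (long long)q * nd, att_u = (long long)q * nu;

  if (nd >= 2) {
    for (long long t = 0; t < att_d; ++t) {
      int i1 = didx[(int)(unif_rand() * nd)];
      int i2 = didx[(int)(unif_rand() * nd)];
      if (i1 == i2) continue;
      int a = out(i1, 0), b = out(i1, 1);
      int c = out(i2, 0), d = out(i2, 1);
      // proposed: a->d, c->b
      if (a == d || c == b) continue;
      long long k1 = ukey(a, d, n), k2 = ukey(c, b, n);
      if (k1 == k2 || occ.count(k1) || occ.count(k2)) continue;
      occ.erase(ukey(a, b, n));
      occ.erase(ukey(c, d, n));
      occ.insert(k1);
      occ.insert(k2);
      out(i1, 1) = d;
      out(i2, 1) = b;
    }
  }

  if (nu >= 2) {
    for (long long t = 0; t < att_u; ++t) {
      int i1 = uidx[(int)(unif_rand() * nu)];
      int i2 = uidx[(int)(unif_rand() * nu)];
      if (i1 == i2) continue;
      int a = out(i1, 0), b = out(i1, 1);
      int c = out(i2, 0), d = out(i2, 1);
      // two pairings preserve degrees: {a,d},{c,b} or {a,c},{b,d}
      int w, x, y, z;
      if (unif_rand() < 0.5) { w = a; x = d; y = c; z = b; }
      else                   { w = a; x = c; y = b; z = d; }
      if (w == x || y == z) continue;
      long long k1 = ukey(w, x, n), k2 = ukey(y, z, n);
      if (k1 == k2 || occ.count(k1) || occ.count(k2)) continue;
      occ.erase(ukey(a, b, n));
      occ.erase(ukey(c, d, n));
      occ.insert(k1);
      occ.insert(k2);
      out(i1, 0) = w; out(i1, 1) = x;
      out(i2, 0) = y; out(i2, 1) = z;
    }
  }

  return out;
}
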