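#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Ward.D2 agglomerative clustering via the Lance-Williams recurrence on
// squared distances:
//   d(k, i+j)^2 = ((n_i+n_k) d_ik^2 + (n_j+n_k) d_jk^2 - n_k d_ij^2)
//                 / (n_i + n_j + n_k)
// Heights are reported unsquared. Ties are broken by the lexicographically
// lowest (min id, max id) pair of current cluster ids, where leaves carry
// ids 1..n and the cluster created at merge step s carries id n + s.
//
// Nearest-neighbour caching keeps the typical cost near O(n^2); the cache
// is rebuilt for any cluster whose cached neighbour was invalidated by a
// merge, so the tie rule above is honoured exactly.

static inline size_t idx(int i, int j, int n) {
  return (size_t)i * (size_t)n + (size_t)j;
}

// [[Rcpp::export(name = ".ward_linkage_cpp")]]
List ward_linkage_cpp(NumericMatrix D) {
  const int n = D.nrow();
  if (n != D.ncol()) stop("distance matrix must be square");
  if (n < 2) stop("need at least two observations");

  std::vector<double> d2((size_t)n * (size_t)n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double v = D(i, j);
      if (v < 0) stop("distance matrix has a negative entry");
      d2[idx(i, j, n)] = v * v;
    }
  }

  std::vector<char> active(n, 1);
  std::vector<int>  cid(n);        // slot -> current cluster id (1-based)
  std::vector<double> sz(n, 1.0);  // slot -> cluster size
  std::vector<int>  step_of(2 * n, 0); // cluster id -> merge step (leaves 0)
  for (int i = 0; i < n; ++i) cid[i] = i + 1;

  // nearest-neighbour cache per active slot
  std::vector<int>    nn(n, -1);
  std::vector<double> nnd(n, R_PosInf);

  // prefer (v, a, b) over the current best (bv, ba, bb)?
  auto better_pair = [](double v, int a, int b,
                        double bv, int ba, int bb) {
    if (v < bv) return true;
    if (v > bv) return false;
    if (a < ba) return true;
    if (a > ba) return false;
    return b < bb;
  };

  auto rescan = [&](int i) {
    double bv = R_PosInf; int bj = -1, ba = 0, bb = 0;
    for (int j = 0; j < n; ++j) {
      if (!active[j] || j == i) continue;
      double v = d2[idx(i, j, n)];
      int a = std::min(cid[i], cid[j]), b = std::max(cid[i], cid[j]);
      if (bj < 0 || better_pair(v, a, b, bv, ba, bb)) {
        bv = v; bj = j; ba = a; bb = b;
      }
    }
    nn[i] = bj; nnd[i] = bv;
  };

  for (int i = 0; i < n; ++i) rescan(i);

  IntegerMatrix merge(n - 1, 2);
  NumericVector height(n - 1);
  IntegerVector new_size(n - 1);

  for (int step = 1; step <= n - 1; ++step) {
    // global best over cached neighbours
    int bi = -1; double bv = R_PosInf; int ba = 0, bb = 0;
    for (int i = 0; i < n; ++i) {
      if (!active[i] || nn[i] < 0) continue;
      int j = nn[i];
      int a = std::min(cid[i], cid[j]), b = std::max(cid[i], cid[j]);
      if (bi < 0 || better_pair(nnd[i], a, b, bv, ba, bb)) {
        bi = i; bv = nnd[i]; ba = a; bb = b;
      }
    }
    int bj = nn[bi];
    if (bj < bi) std::swap(bi, bj);   // keep slot order stable

    int ci = cid[bi], cj = cid[bj];
    int mi = ci <= n ? -ci : step_of[ci];
    int mj = cj <= n ? -cj : step_of[cj];
    if (mi > mj) std::swap(mi, mj);   // leaves (negative) first, then by step
    merge(step - 1, 0) = mi;
    merge(step - 1, 1) = mj;
    height[step - 1] = std::sqrt(bv);
    double ns = sz[bi] + sz[bj];
    new_size[step - 1] = (int)ns;

    // Lance-Williams update into slot bi
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == bi || k == bj) continue;
      double dik = d2[idx(bi, k, n)];
      double djk = d2[idx(bj, k, n)];
      double nk = sz[k];
      double v = ((sz[bi] + nk) * dik + (sz[bj] + nk) * djk - nk * bv) /
                 (sz[bi] + sz[bj] + nk);
      d2[idx(bi, k, n)] = v;
      d2[idx(k, bi, n)] = v;
    }

    active[bj] = 0;
    sz[bi] = ns;
    cid[bi] = n + step;
    step_of[n + step] = step;

    if (step == n - 1) break;
    rescan(bi);
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == bi) continue;
      if (nn[k] == bi || nn[k] == bj) {
        rescan(k);
      } else {
        // the merged cluster may now be k's nearest neighbour
        double v = d2[idx(k, bi, n)];
        int a = std::min(cid[k], cid[bi]), b = std::max(cid[k], cid[bi]);
        int j = nn[k];
        int oa = std::min(cid[k], cid[j]), ob = std::max(cid[k], cid[j]);
        if (better_pair(v, a, b, nnd[k], oa, ob)) {
          nn[k] = bi; nnd[k] = v;
        }
      }
    }
  }

  return List::create(_["merge"] = merge,
                      _["height"] = height,
                      _["size"] = new_size);
}
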