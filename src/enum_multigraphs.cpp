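// Exhaustive, isomorph-free enumeration of connected cubic multigraphs
// (loops and parallel edges allowed; a loop contributes 2 to the degree).
// Labelled multiplicity matrices are enumerated by backtracking over the
// vertex pairs in lexicographic order with degree pruning; representatives
// are kept via a colour-refinement invariant plus exact backtracking
// isomorphism within invariant buckets.  Colour refinement uses
// permutation-invariant integer hashing: hash collisions can only weaken
// the colour constraint, never break correctness, because membership in a
// class is always confirmed by exact isomorphism.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>

using namespace Rcpp;

typedef std::vector<int> Mult;            // n*n row-major multiplicity matrix
typedef unsigned long long u64;

static bool connected(const Mult& m, int n) {
  std::vector<int> stack(1, 0), seen(n, 0);
  seen[0] = 1;
  int count = 1;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    for (int w = 0; w < n; ++w) {
      if (w != v && m[v * n + w] > 0 && !seen[w]) {
        seen[w] = 1; ++count; stack.push_back(w);
      }
    }
  }
  return count == n;
}

static inline u64 mix(u64 h, u64 x) {
  h ^= x + 0x9e3779b97f4a7c15ULL + (h << 6) + (h >> 2);
  return h;
}

// three rounds of colour refinement, hashed; isomorphic graphs always get
// identical colour multisets
static std::vector<u64> wl_colours(const Mult& m, int n) {
  std::vector<u64> col(n), nxt(n);
  for (int v = 0; v < n; ++v) col[v] = 1469598103934665603ULL + (u64)m[v * n + v];
  for (int round = 0; round < 3; ++round) {
    for (int v = 0; v < n; ++v) {
      std::vector<u64> nb;
      for (int w = 0; w < n; ++w) {
        if (w != v && m[v * n + w] > 0) {
          nb.push_back(col[w] * 31ULL + (u64)m[v * n + w]);
        }
      }
      std::sort(nb.begin(), nb.end());
      u64 h = mix(0x12345678u, col[v]);
      for (size_t i = 0; i < nb.size(); ++i) h = mix(h, nb[i]);
      nxt[v] = h;
    }
    col = nxt;
  }
  return col;
}

static bool iso_recurse(const Mult& a, const Mult& b, int n,
                        const std::vector<u64>& ca, const std::vector<u64>& cb,
                        std::vector<int>& map, std::vector<int>& used, int v) {
  if (v == n) return true;
  for (int w = 0; w < n; ++w) {
    if (used[w] || ca[v] != cb[w]) continue;
    if (a[v * n + v] != b[w * n + w]) continue;
    bool ok = true;
    for (int u = 0; u < v; ++u) {
      if (a[v * n + u] != b[w * n + map[u]]) { ok = false; break; }
    }
    if (!ok) continue;
    map[v] = w; used[w] = 1;
    if (iso_recurse(a, b, n, ca, cb, map, used, v + 1)) return true;
    used[w] = 0;
  }
  return false;
}

static bool isomorphic_multigraphs(const Mult& a, const std::vector<u64>& ca,
                                   const Mult& b, const std::vector<u64>& cb,
                                   int n) {
  std::vector<int> map(n, -1), used(n, 0);
  return iso_recurse(a, b, n, ca, cb, map, used, 0);
}

struct Enumerator {
  int n;
  std::vector<std::pair<int, int> > pairs; // (i, j) with i <= j, lex order
  Mult mult;
  std::vector<int> deg;
  std::vector<Mult> reps;
  std::vector<std::vector<u64> > rep_cols;
  std::map<std::vector<u64>, std::vector<int> > buckets;

  Enumerator(int n_) : n(n_), mult(n_ * n_, 0), deg(n_, 0) {
    for (int i = 0; i < n; ++i) {
      for (int j = i; j < n; ++j) pairs.push_back(std::make_pair(i, j));
    }
  }

  void record() {
    if (!connected(mult, n)) return;
    std::vector<u64> col = wl_colours(mult, n);
    std::vector<u64> key = col;
    std::sort(key.begin(), key.end());
    std::vector<int>& bucket = buckets[key];
    for (size_t i = 0; i < bucket.size(); ++i) {
      int r = bucket[i];
      if (isomorphic_multigraphs(mult, col, reps[r], rep_cols[r], n)) return;
    }
    bucket.push_back((int)reps.size());
    reps.push_back(mult);
    rep_cols.push_back(col);
  }

  void search(size_t p) {
    if (p == pairs.size()) {
      record();
      return;
    }
    int i = pairs[p].first, j = pairs[p].second;
    int maxm;
    if (i == j) {
      maxm = (3 - deg[i]) / 2;          // a loop costs 2 degree units
    } else {
      maxm = std::min(3 - deg[i], 3 - deg[j]);
    }
    for (int m = 0; m <= maxm; ++m) {
      if (i == j) {
        mult[i * n + i] = m;
        deg[i] += 2 * m;
      } else {
        mult[i * n + j] = mult[j * n + i] = m;
        deg[i] += m; deg[j] += m;
      }
      // once all pairs involving i are decided, deg[i] must be exactly 3
      bool last_for_i = (j == n - 1);
      if (!last_for_i || deg[i] == 3) search(p + 1);
      if (i == j) {
        deg[i] -= 2 * m;
        mult[i * n + i] = 0;
      } else {
        deg[i] -= m; deg[j] -= m;
        mult[i * n + j] = mult[j * n + i] = 0;
      }
    }
  }
};

// [[Rcpp::export]]
List enum_cubic_multigraphs_cpp(int n) {
  if (n < 1 || n % 2 != 0) stop("n must be a positive even integer");
  Enumerator en(n);
  en.search(0);
  List out(en.reps.size());
  for (size_t k = 0; k < en.reps.size(); ++k) {
    IntegerMatrix m(n, n);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) m(i, j) = en.reps[k][i * n + j];
    }
    out[k] = m;
  }
  return out;
}
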