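#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Minimum-energy nested secondary structure under a simplified stacked-pair
// model: a base pair stacked directly inside an adjacent outer pair
// contributes its own pair energy (GC/CG -3.0, AU/UA -2.0, GU/UG -1.0
// kcal/mol); isolated (unstacked) pairs contribute nothing; hairpin loops
// shorter than 3 nt are forbidden; no pseudoknots, no dangling ends.
//
// Bases are encoded 0=A, 1=C, 2=G, 3=U.

static const double INF = std::numeric_limits<double>::infinity();
static const int MINLOOP = 3;

static inline double pair_energy(int a, int b) {
  // returns 0 if a:b is not an allowed pair
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return -3.0; // G:C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return -2.0; // A:U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return -1.0; // G:U
  return 0.0;
}

struct FoldDP {
  int n;
  const std::vector<int>& s;
  std::vector<double> W, V, U;
  std::vector<int> pairvec;

  FoldDP(const std::vector<int>& seq)
    : n((int)seq.size()), s(seq),
      W(n * n, 0.0), V(n * n, INF), U(n * n, 0.0),
      pairvec(n, -1) {}

  inline int idx(int i, int j) const { return i * n + j; }

  inline bool can_pair(int i, int j) const {
    return j - i - 1 >= MINLOOP && pair_energy(s[i], s[j]) < 0.0;
  }

  void run() {
    for (int span = MINLOOP + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // U(i,j): best structure on [i,j] with i NOT paired to j
        double u = W[idx(i + 1, j)];                 // i unpaired
        for (int k = i + MINLOOP + 1; k < j; ++k) {  // i paired to k < j
          if (V[idx(i, k)] == INF) continue;
          double cand = V[idx(i, k)] + (k + 1 <= j ? W[idx(k + 1, j)] : 0.0);
          if (cand < u) u = cand;
        }
        U[idx(i, j)] = u;
        // V(i,j): best structure given i:j paired
        if (can_pair(i, j)) {
          double v = U[idx(i + 1, j - 1)];
          if (can_pair(i + 1, j - 1) && V[idx(i + 1, j - 1)] != INF) {
            double stacked = V[idx(i + 1, j - 1)] + pair_energy(s[i + 1], s[j - 1]);
            if (stacked < v) v = stacked;
          }
          V[idx(i, j)] = v;
        }
        // W(i,j)
        double w = u;
        if (V[idx(i, j)] < w) w = V[idx(i, j)];
        W[idx(i, j)] = w;
      }
    }
  }

  void traceW(int i, int j) {
    if (j - i < MINLOOP + 1) return;
    if (V[idx(i, j)] != INF && V[idx(i, j)] <= U[idx(i, j)]) traceV(i, j);
    else traceU(i, j);
  }

  void traceU(int i, int j) {
    if (j - i < MINLOOP + 1) return;
    double u = U[idx(i, j)];
    if (u == W[idx(i + 1, j)]) { traceW(i + 1, j); return; }
    for (int k = i + MINLOOP + 1; k < j; ++k) {
      if (V[idx(i, k)] == INF) continue;
      double rest = (k + 1 <= j ? W[idx(k + 1, j)] : 0.0);
      if (u == V[idx(i, k)] + rest) {
        traceV(i, k);
        if (k + 1 <= j) traceW(k + 1, j);
        return;
      }
    }
    traceW(i + 1, j); // numerical fallback, should not be reached
  }

  void traceV(int i, int j) {
    pairvec[i] = j;
    pairvec[j] = i;
    double v = V[idx(i, j)];
    if (can_pair(i + 1, j - 1) && V[idx(i + 1, j - 1)] != INF &&
        v == V[idx(i + 1, j - 1)] + pair_energy(s[i + 1], s[j - 1])) {
      traceV(i + 1, j - 1);
    } else {
      traceU(i + 1, j - 1);
    }
  }
};

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector seq_codes) {
  int n = seq_codes.size();
  if (n == 0) {
    return List::create(_["structure"] = std::string(""), _["mfe"] = 0.0,
                        _["pairs"] = IntegerVector(0));
  }
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = seq_codes[i];
  FoldDP dp(s);
  if (n > MINLOOP + 1) {
    dp.run();
    dp.traceW(0, n - 1);
  }
  double mfe = (n > MINLOOP + 1) ? dp.W[dp.idx(0, n - 1)] : 0.0;
  std::string db(n, '.');
  IntegerVector pairs(n, 0);
  for (int i = 0; i < n; ++i) {
    if (dp.pairvec[i] >= 0) {
      pairs[i] = dp.pairvec[i] + 1;
      db[i] = (dp.pairvec[i] > i) ? '(' : ')';
    }
  }
  return List::create(_["structure"] = db, _["mfe"] = mfe, _["pairs"] = pairs);
}
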