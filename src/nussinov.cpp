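#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Base codes: 0=A, 1=C, 2=G, 3=U/T, -1=other (never pairs).
// Watson-Crick plus G:U wobble.
static inline bool can_pair(int a, int b) {
  if (a < 0 || b < 0) return false;
  return (a + b == 3) ||               // A:U (0+3), G:C (1+2)
         (a == 2 && b == 3) || (a == 3 && b == 2); // G:U
}

// Maximum base-pairing DP (minimum loop length 3, i.e. a pair (i,j)
// requires j - i >= 4). Returns the maximum number of pairs.
static int max_pairs(const int *s, int n) {
  if (n < 5) return 0;
  std::vector<int> dp((size_t)n * n, 0);
  for (int len = 5; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = dp[(size_t)i * n + (j - 1)]; // j unpaired
      for (int k = i; k <= j - 4; ++k) {      // j pairs with k
        if (!can_pair(s[k], s[j])) continue;
        int v = 1 + (k > i ? dp[(size_t)i * n + (k - 1)] : 0) +
                dp[(size_t)(k + 1) * n + (j - 1)];
        if (v > best) best = v;
      }
      dp[(size_t)i * n + j] = best;
    }
  }
  return dp[(size_t)0 * n + (n - 1)];
}

// [[Rcpp::export(name = ".cpp_max_pairs")]]
int cpp_max_pairs(IntegerVector codes) {
  if (codes.size() == 0) return 0;
  return max_pairs(&codes[0], codes.size());
}

// Per-position rolling-window score: value at position i (1-based) is
// -1 * max_pairs over the `window` nt ending at i - offset; NA where the
// window is incomplete.
// [[Rcpp::export(name = ".cpp_window_dg")]]
NumericVector cpp_window_dg(IntegerVector codes, int window, int offset) {
  int n = codes.size();
  NumericVector out(n, NA_REAL);
  if (n == 0) return out;
  for (int i = window + offset; i <= n; ++i) {
    int lo = i - offset - window; // 0-based start of window
    out[i - 1] = -1.0 * max_pairs(&codes[lo], window);
  }
  return out;
}
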