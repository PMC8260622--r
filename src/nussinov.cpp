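#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Watson-Crick plus G-U wobble, on the DNA alphabet (T stands for U).
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// Maximum number of nested base pairs with a minimum hairpin loop of
// `min_loop` unpaired nucleotides (positions i, j may pair only if
// j - i > min_loop). Standard O(n^3) interval dynamic program; the
// table is kept in both row-major (M) and column-major (MT) layout so
// both inner-loop reads are contiguous.
// [[Rcpp::export]]
int nussinov_max_pairs(std::string seq, int min_loop = 3) {
  int n = (int) seq.size();
  if (n < min_loop + 2) return 0;
  std::vector<int> M((size_t) n * n, 0);   // M[i*n + j]
  std::vector<int> MT((size_t) n * n, 0);  // MT[j*n + i]
  const char *s = seq.c_str();
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[(size_t) i * n + (j - 1)];  // j unpaired
      const int *rowi = &M[(size_t) i * n];
      const int *colj1 = &MT[(size_t) (j - 1) * n];
      char cj = s[j];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (can_pair(s[k], cj)) {
          int v = 1;
          if (k > i) v += rowi[k - 1];
          if (k + 1 <= j - 1) v += colj1[k + 1];
          if (v > best) best = v;
        }
      }
      M[(size_t) i * n + j] = best;
      MT[(size_t) j * n + i] = best;
    }
  }
  return M[n - 1];
}
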