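#include <Rcpp.h>
using namespace Rcpp;

// Pairwise site counts over an integer-encoded sequence matrix
// (rows = sequences, columns = alignment positions; A=1, C=2, G=3, T=4,
// anything else 0 = skipped at that pair, i.e. pairwise deletion).
// Purines (A=1, G=3) are odd, pyrimidines (C=2, T=4) even, so two
// differing valid bases are a transition iff they have equal parity.
// [[Rcpp::export(name = ".pair_counts_all")]]
List pair_counts_all(const IntegerMatrix& enc) {
  const int n = enc.nrow(), L = enc.ncol();
  IntegerMatrix valid(n, n), ts(n, n), tv(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int v = 0, s = 0, w = 0;
      for (int k = 0; k < L; ++k) {
        const int a = enc(i, k), b = enc(j, k);
        if (a == 0 || b == 0) continue;
        ++v;
        if (a != b) {
          if (((a ^ b) & 1) == 0) ++s; else ++w;
        }
      }
      valid(i, j) = valid(j, i) = v;
      ts(i, j) = ts(j, i) = s;
      tv(i, j) = tv(j, i) = w;
    }
  }
  return List::create(_["valid"] = valid,
                      _["transitions"] = ts,
                      _["transversions"] = tv);
}
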