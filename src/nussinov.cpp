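#include <Rcpp.h>
#include <vector>
#include <string>

// Minimum total pair energy over nested secondary structures with a
// minimum hairpin loop, by Nussinov-style dynamic programming.
// Pair energies: G-C -3, A-U -2, G-U -1 kcal/mol.

static inline double pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return 0.0;
}

// [[Rcpp::export(name = ".nussinov_mfe")]]
double nussinov_mfe(std::string seq, int min_loop) {
  const int n = seq.size();
  if (n < min_loop + 2) return 0.0;
  std::vector<double> E((size_t)n * n, 0.0);
  // E[i*n + j] over 0-based i <= j
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double best = E[(size_t)i * n + (j - 1)];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        double e = pair_energy(seq[k], seq[j]);
        if (e < 0) {
          double left = (k > i) ? E[(size_t)i * n + (k - 1)] : 0.0;
          double v = left + E[(size_t)(k + 1) * n + (j - 1)] + e;
          if (v < best) best = v;
        }
      }
      E[(size_t)i * n + j] = best;
    }
  }
  return E[0 + (size_t)(n - 1)];
}
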