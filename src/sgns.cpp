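#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// One skip-gram/negative-sampling epoch over a pre-shuffled list of pair
// occurrences. Each pair is a 2-token sentence: both directions (center a,
// context b) and (center b, context a) are trained. syn0 (input vectors, the
// exported embedding) and syn1 (output vectors) are updated in place; the
// caller owns both matrices and must not alias them elsewhere.
//
// All randomness comes from R's RNG (unif_rand), so a single set.seed() in
// the calling R code makes the whole run reproducible. The learning rate
// decays linearly from alpha_start to alpha_end across the epoch's updates.
//
// neg_table is a 0-based unigram^0.75 sampling table; a drawn negative equal
// to the positive context is skipped (word2vec convention).
// [[Rcpp::export]]
void sgns_epoch(NumericMatrix syn0, NumericMatrix syn1,
                IntegerVector pair_a, IntegerVector pair_b,
                IntegerVector neg_table,
                double alpha_start, double alpha_end, int n_neg) {
  const int n = pair_a.size();
  const int k = syn0.ncol();
  const int table_size = neg_table.size();
  if (n == 0) return;
  RNGScope scope;
  std::vector<double> grad(k);
  const double steps = 2.0 * n;
  double step = 0.0;
  for (int t = 0; t < n; ++t) {
    for (int dir = 0; dir < 2; ++dir) {
      const int center = dir == 0 ? pair_a[t] : pair_b[t];
      const int context = dir == 0 ? pair_b[t] : pair_a[t];
      const double alpha =
          alpha_start + (alpha_end - alpha_start) * (step / steps);
      step += 1.0;
      std::fill(grad.begin(), grad.end(), 0.0);
      for (int s = 0; s <= n_neg; ++s) {
        int target;
        double label;
        if (s == 0) {
          target = context;
          label = 1.0;
        } else {
          int r = (int)(unif_rand() * table_size);
          if (r >= table_size) r = table_size - 1;
          target = neg_table[r];
          if (target == context) continue;
          label = 0.0;
        }
        double dot = 0.0;
        for (int c = 0; c < k; ++c) dot += syn0(center, c) * syn1(target, c);
        const double pred = 1.0 / (1.0 + std::exp(-dot));
        const double g = (label - pred) * alpha;
        for (int c = 0; c < k; ++c) {
          grad[c] += g * syn1(target, c);
          syn1(target, c) += g * syn0(center, c);
        }
      }
      for (int c = 0; c < k; ++c) syn0(center, c) += grad[c];
    }
  }
}
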