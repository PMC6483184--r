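#include <Rcpp.h>
using namespace Rcpp;

// Draw a variant index (0-based) from row i of the usage matrix using R's RNG.
static inline int sample_variant(const NumericMatrix &P, const int i,
                                 const int n) {
  double u = unif_rand(), c = 0.0;
  for (int k = 0; k < n; ++k) {
    c += P(i, k);
    if (u < c) return k;
  }
  return n - 1;
}

// Learning update toward a heard variant: p_k' = p_k + (1 - p_k) l for the
// heard variant, p_k' = p_k (1 - l) for all others.  Conserves the unit sum
// algebraically.
static inline void learn(NumericMatrix &P, const int i, const int heard,
                         const double l, const int n) {
  for (int k = 0; k < n; ++k) P(i, k) *= (1.0 - l);
  P(i, heard) += l;
}

//' Run rounds of pairwise interactions on a usage matrix
//'
//' Each round pairs agents by a uniformly random perfect matching (one agent
//' idles when N is odd); within a pair both utterances are sampled from the
//' pre-round distributions before either agent updates.  Uses R's RNG
//' stream, so results are reproducible under set.seed().
//'
//' @param probs numeric matrix, one row per agent, rows summing to one.
//' @param l learning weight between 0 and 1.
//' @param rounds number of interaction rounds.
//' @noRd
// [[Rcpp::export]]
NumericMatrix interaction_rounds_cpp(const NumericMatrix &probs,
                                     const double l, const int rounds) {
  NumericMatrix P = clone(probs);
  const int N = P.nrow(), n = P.ncol();
  if (rounds <= 0) return P;
  if (N < 2) stop("an interaction round needs at least two agents");
  std::vector<int> idx(N);
  for (int t = 0; t < rounds; ++t) {
    for (int i = 0; i < N; ++i) idx[i] = i;
    // Fisher-Yates shuffle on R's RNG: consecutive positions form the pairs,
    // which induces a uniform random perfect matching.
    for (int i = N - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      std::swap(idx[i], idx[j]);
    }
    const int npair = N / 2;
    for (int p = 0; p < npair; ++p) {
      const int a = idx[2 * p], b = idx[2 * p + 1];
      // Both utterances precede either update; agents interact once per
      // round, so all sampling sees pre-round state.
      const int ua = sample_variant(P, a, n);
      const int ub = sample_variant(P, b, n);
      learn(P, a, ub, l, n);
      learn(P, b, ua, l, n);
    }
  }
  return P;
}
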