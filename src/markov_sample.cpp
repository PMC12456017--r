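#include <Rcpp.h>
using namespace Rcpp;

// Sample a first-order Markov chain over the 4-letter DNA alphabet.
// Uniform deviates are generated on the R side so that set.seed()
// governs the output; this routine is purely deterministic given u.
//
// init_cum:  cumulative initial-state probabilities (length 4, last == 1)
// trans_cum: 4x4 row-wise cumulative transition probabilities
// u:         runif(n) deviates, one per emitted base
//
// Returns 1-based state codes (1=A, 2=C, 3=G, 4=T).

// [[Rcpp::export]]
IntegerVector sample_markov_chain(NumericVector init_cum,
                                  NumericMatrix trans_cum,
                                  NumericVector u) {
  const int n = u.size();
  IntegerVector out(n);
  if (n == 0) return out;

  int state = 3;
  for (int j = 0; j < 4; ++j) {
    if (u[0] <= init_cum[j]) { state = j; break; }
  }
  out[0] = state + 1;

  for (int i = 1; i < n; ++i) {
    const double ui = u[i];
    int s = 3;
    for (int j = 0; j < 4; ++j) {
      if (ui <= trans_cum(state, j)) { s = j; break; }
    }
    state = s;
    out[i] = state + 1;
  }
  return out;
}
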