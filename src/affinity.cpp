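#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// TRAP-style occupancy scan. Sequences are integer-encoded (A=1, C=2, G=3,
// T=4, anything else 0 = ambiguous). `lodds` is the width x 4 matrix of
// log(p_motif / p_background) ALREADY divided by lambda; `lodds_rc` its
// reverse complement. Each window on each strand contributes
//   p_w = R * K_w / (1 + R * K_w),  K_w = exp(scaled log-odds),
// evaluated in logistic form for numerical stability. Windows overlapping
// an ambiguous base contribute 0.

// [[Rcpp::export]]
NumericVector trap_scores_cpp(List seqs, NumericMatrix lodds,
                              NumericMatrix lodds_rc, double logR) {
  const int w = lodds.nrow();
  // position-major layout: wf[5*j + b] for base code b in 1..4; code 0
  // (ambiguous) carries -inf so the whole window is suppressed.
  std::vector<double> wf(5 * w), wr(5 * w);
  const double neg_inf = -std::numeric_limits<double>::infinity();
  for (int j = 0; j < w; ++j) {
    wf[5 * j] = wr[5 * j] = neg_inf;
    for (int b = 0; b < 4; ++b) {
      wf[5 * j + b + 1] = lodds(j, b);
      wr[5 * j + b + 1] = lodds_rc(j, b);
    }
  }
  const int n_seq = seqs.size();
  NumericVector out(n_seq);
  for (int k = 0; k < n_seq; ++k) {
    IntegerVector code = seqs[k];
    const int n = code.size();
    const int *c = INTEGER(code);
    double total = 0.0;
    for (int i = 0; i + w <= n; ++i) {
      double sf = 0.0, sr = 0.0;
      const int *ci = c + i;
      for (int j = 0; j < w; ++j) {
        sf += wf[5 * j + ci[j]];
        sr += wr[5 * j + ci[j]];
      }
      if (sf > neg_inf) {  // no ambiguous base in the window
        const double tf = logR + sf;
        const double tr = logR + sr;
        total += 1.0 / (1.0 + std::exp(-tf));
        total += 1.0 / (1.0 + std::exp(-tr));
      }
    }
    out[k] = total;
  }
  return out;
}
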