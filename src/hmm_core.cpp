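#include <Rcpp.h>
using namespace Rcpp;

// Two-state forward algorithm with per-step transition probabilities.
//
// logb:  T x 2 matrix of log emission densities (state 1, state 2)
// p12, p21: length-T vectors of off-diagonal transition probabilities;
//           entry t is used for the step t-1 -> t (entry of the first step
//           of a segment is ignored)
// seg_start: 1-based indices of the first observation of each segment
// seg_end:   1-based indices of the last observation of each segment
// init1: stationary probability of state 1 at each segment's first covariates
//        (length = number of segments)
//
// Returns the total log-likelihood, summed over independent segments.
// Scaling: work with alpha normalized to sum 1, accumulate log of the sums.
// [[Rcpp::export]]
double forward_loglik_cpp(NumericMatrix logb, NumericVector p12,
                          NumericVector p21, IntegerVector seg_start,
                          IntegerVector seg_end, NumericVector init1) {
  const int nseg = seg_start.size();
  double total = 0.0;
  for (int s = 0; s < nseg; ++s) {
    int t0 = seg_start[s] - 1, t1 = seg_end[s] - 1;
    // first step: initial distribution times emission
    double m = std::max(logb(t0, 0), logb(t0, 1));
    if (!R_finite(m)) m = 0.0;
    double a1 = init1[s] * std::exp(logb(t0, 0) - m);
    double a2 = (1.0 - init1[s]) * std::exp(logb(t0, 1) - m);
    double c = a1 + a2;
    if (c <= 0.0 || !R_finite(c)) return R_NegInf;
    total += std::log(c) + m;
    a1 /= c; a2 /= c;
    for (int t = t0 + 1; t <= t1; ++t) {
      double q12 = p12[t], q21 = p21[t];
      double b1 = a1 * (1.0 - q12) + a2 * q21;
      double b2 = a1 * q12 + a2 * (1.0 - q21);
      m = std::max(logb(t, 0), logb(t, 1));
      if (!R_finite(m)) m = 0.0;
      a1 = b1 * std::exp(logb(t, 0) - m);
      a2 = b2 * std::exp(logb(t, 1) - m);
      c = a1 + a2;
      if (c <= 0.0 || !R_finite(c)) return R_NegInf;
      total += std::log(c) + m;
      a1 /= c; a2 /= c;
    }
  }
  return total;
}

// Viterbi decoding under the same conventions. Ties broken toward state 1.
// Returns a length-T integer vector of states in {1, 2}.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix logb, NumericVector p12,
                          NumericVector p21, IntegerVector seg_start,
                          IntegerVector seg_end, NumericVector init1) {
  const int T = logb.nrow(), nseg = seg_start.size();
  IntegerVector path(T);
  for (int s = 0; s < nseg; ++s) {
    int t0 = seg_start[s] - 1, t1 = seg_end[s] - 1, n = t1 - t0 + 1;
    std::vector<double> d1(n), d2(n);
    std::vector<int> bp1(n), bp2(n);
    d1[0] = std::log(init1[s]) + logb(t0, 0);
    d2[0] = std::log(1.0 - init1[s]) + logb(t0, 1);
    for (int k = 1; k < n; ++k) {
      int t = t0 + k;
      double l11 = std::log(1.0 - p12[t]), l12 = std::log(p12[t]);
      double l21 = std::log(p21[t]), l22 = std::log(1.0 - p21[t]);
      double from1 = d1[k - 1] + l11, from2 = d2[k - 1] + l21;
      if (from1 >= from2) { d1[k] = from1; bp1[k] = 1; }
      else { d1[k] = from2; bp1[k] = 2; }
      d1[k] += logb(t, 0);
      from1 = d1[k - 1] + l12; from2 = d2[k - 1] + l22;
      if (from1 >= from2) { d2[k] = from1; bp2[k] = 1; }
      else { d2[k] = from2; bp2[k] = 2; }
      d2[k] += logb(t, 1);
    }
    int st = (d1[n - 1] >= d2[n - 1]) ? 1 : 2;
    path[t1] = st;
    for (int k = n - 1; k >= 1; --k) {
      st = (st == 1) ? bp1[k] : bp2[k];
      path[t0 + k - 1] = st;
    }
  }
  return path;
}
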