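#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Raw cross-correlogram machinery shared by the NCC and NCCH measures.
//
// For each ordered pair (i, j) and delay tau >= 0 the coincidence count is
//   coin(tau) = #\{ t : j[t] = 1 and i[t + tau] = 1, 0 <= t <= D-1-tau \},
// i.e. source spikes followed by a target spike tau bins later.  The
// window counts needed for mean-correction of the NCC on the overlap
// window are n_i(tau) = #\{ s in S_i : s >= tau \} and
// n_j(tau) = #\{ s in S_j : s <= D-1-tau \}.

// [[Rcpp::export]]
List cc_counts_cpp(List spikes, int D, IntegerVector delays,
                   IntegerMatrix pairs) {
  const int nn = spikes.size(), np = pairs.nrow(), nd = delays.size();
  int dmax = 0, dmin = 0;
  for (int q = 0; q < nd; ++q) {
    if (delays[q] < 0) stop("delays must be >= 0");
    dmax = std::max(dmax, delays[q]);
    dmin = std::min(dmin, delays[q]);
  }
  std::vector<std::vector<int>> sp(nn);
  for (int n = 0; n < nn; ++n) {
    IntegerVector v = spikes[n];
    sp[n] = std::vector<int>(v.begin(), v.end());
  }

  // per-neuron window counts at each delay
  NumericMatrix n_from(nn, nd), n_to(nn, nd);
  for (int n = 0; n < nn; ++n) {
    const std::vector<int> &s = sp[n];
    for (int q = 0; q < nd; ++q) {
      int tau = delays[q];
      n_from(n, q) = s.end() -
        std::lower_bound(s.begin(), s.end(), tau);          // spikes >= tau
      n_to(n, q) = std::upper_bound(s.begin(), s.end(), D - 1 - tau) -
        s.begin();                                          // spikes <= D-1-tau
    }
  }

  NumericMatrix coin(np, nd);
  std::vector<double> hist(dmax + 1);
  for (int p = 0; p < np; ++p) {
    const std::vector<int> &si = sp[pairs(p, 0) - 1];
    const std::vector<int> &sj = sp[pairs(p, 1) - 1];
    std::fill(hist.begin(), hist.end(), 0.0);
    // for each target spike s, source spikes in [s - dmax, s]
    size_t lo = 0;
    for (int s : si) {
      while (lo < sj.size() && sj[lo] < s - dmax) ++lo;
      for (size_t q = lo; q < sj.size() && sj[q] <= s; ++q)
        hist[s - sj[q]] += 1.0;
    }
    for (int q = 0; q < nd; ++q) coin(p, q) = hist[delays[q]];
    if (p % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["coin"] = coin, _["n_from"] = n_from,
                      _["n_to"] = n_to);
}
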