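#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <climits>
#include <algorithm>

using namespace Rcpp;

// Sparse pattern counting for transfer entropy on binary spike series.
//
// For a target series i, source series j, history length k, message length
// l and delay d, the word at time t is
//   ( i[t+1] ; i[t], ..., i[t-k+1] ; j[t+1-d], ..., j[t+2-d-l] )
// (0-based bins).  Valid t are those where every referenced bin exists:
//   t in [max(k-1, d+l-2), D-2],  n_valid = D - max(k, d+l-1).
// Only time points whose word contains at least one spike are visited; the
// count of the all-zero word is inferred as n_valid minus the sum of the
// other counts.  Non-zero positions are exactly the union of the intervals
// [s-1, s+k-1] over spikes s of i and [s+d-1, s+d+l-2] over spikes s of j,
// so the cost scales with the number of spikes, not with the number of
// bins.
//
// Two implementations are provided.  count_patterns_cpp() walks the two
// sorted spike lists once per (k, l, d), reading word bits out of sliding
// windows -- simple, and the reference for the batch path.  The batch
// te_profiles_cpp() factors the word into its delay-independent target and
// source parts: per neuron it precomputes the stream of non-zero
// "target words" (next state + k-bin history anchored at t) and "source
// words" (l-bin message anchored at p), plus per-delay marginal counts of
// each; a single two-pointer join of the two streams then tallies the
// jointly non-zero words for every delay at once, and the marginals supply
// the counts of words where only one side is non-zero.

namespace {

// plug-in transfer entropy (bits) from a flat count table
// tab[(inext << k | iw) << l | jw]
double te_from_table(const double *tab, long nvalid, int k, int l) {
  const int nih = 1 << k, nji = 1 << l;
  double c_ii[64], c_i[32], c_ij[1024];  // stack buffers for k, l <= 5
  std::fill(c_ii, c_ii + 2 * nih, 0.0);
  std::fill(c_i, c_i + nih, 0.0);
  std::fill(c_ij, c_ij + nih * nji, 0.0);
  for (int inext = 0; inext < 2; ++inext)
    for (int iw = 0; iw < nih; ++iw) {
      const double *row = &tab[((size_t)(inext << k | iw)) << l];
      double s = 0;
      for (int jw = 0; jw < nji; ++jw) {
        s += row[jw];
        c_ij[(size_t)iw * nji + jw] += row[jw];
      }
      c_ii[inext * nih + iw] = s;
      c_i[iw] += s;
    }
  double te = 0.0;
  for (int inext = 0; inext < 2; ++inext)
    for (int iw = 0; iw < nih; ++iw) {
      const double *row = &tab[((size_t)(inext << k | iw)) << l];
      for (int jw = 0; jw < nji; ++jw) {
        const double c = row[jw];
        if (c <= 0) continue;
        te += c * std::log2((c * c_i[iw]) /
                            (c_ij[(size_t)iw * nji + jw] *
                             c_ii[inext * nih + iw]));
      }
    }
  return te / (double)nvalid;
}

// reference single-(k,l,d) counter: sliding windows over the spike lists
long count_single(const std::vector<int> &si, const std::vector<int> &sj,
                  int D, int k, int l, int d, std::vector<double> &cnt) {
  const int tmin = std::max(k - 1, d + l - 2);
  const int tmax = D - 2;
  const long nvalid = (long)tmax - tmin + 1;
  if (nvalid <= 0)
    stop("no valid time positions: series too short for (k, l, d)");
  std::fill(cnt.begin(), cnt.end(), 0.0);

  const int ni = (int)si.size(), nj = (int)sj.size();
  int ia = 0, ib = 0;  // candidate generation pointers
  int wi = 0, wj = 0;  // sliding-window start pointers
  long seen = 0;
  long t = (long)tmin - 1;
  for (;;) {
    // next non-zero position after t from either spike stream
    while (ia < ni && (long)si[ia] + k - 1 <= t) ++ia;
    long candA = LONG_MAX;
    if (ia < ni) candA = std::max((long)si[ia] - 1, t + 1);
    while (ib < nj && (long)sj[ib] + d + l - 2 <= t) ++ib;
    long candB = LONG_MAX;
    if (ib < nj) candB = std::max((long)sj[ib] + d - 1, t + 1);
    t = std::min(candA, candB);
    if (t > tmax) break;

    // word bits from the windows [t-k+1, t+1] of i and [t+2-d-l, t+1-d]
    // of j
    while (wi < ni && si[wi] < t - k + 1) ++wi;
    while (wj < nj && sj[wj] < t + 2 - d - l) ++wj;
    int w = 0;
    for (int q = wi; q < ni && si[q] <= t + 1; ++q) {
      if (si[q] == t + 1) w |= 1 << (k + l);
      else w |= 1 << (l + (int)(k - 1 - (t - si[q])));
    }
    for (int q = wj; q < nj && sj[q] <= t + 1 - d; ++q)
      w |= 1 << (int)(l - 1 - (t + 1 - d - sj[q]));
    cnt[w] += 1.0;
    ++seen;
  }
  cnt[0] += nvalid - seen;
  return nvalid;
}

struct Stream {
  std::vector<int> t;  // sorted anchor positions
  std::vector<int> w;  // non-zero word at each anchor
};

// anchors t in [k-1, hi] where the window [t-k+1, t+1] holds >= 1 spike;
// word = (next-state bit << k) | history bits (MSB = bin t)
void build_target_stream(const std::vector<int> &sp, int k, int hi,
                         Stream &st) {
  st.t.clear();
  st.w.clear();
  const int n = (int)sp.size();
  int ia = 0, wi = 0;
  long t = (long)k - 2;
  for (;;) {
    while (ia < n && (long)sp[ia] + k - 1 <= t) ++ia;
    if (ia >= n) break;
    t = std::max((long)sp[ia] - 1, t + 1);
    if (t > hi) break;
    while (wi < n && sp[wi] < t - k + 1) ++wi;
    int w = 0;
    for (int q = wi; q < n && sp[q] <= t + 1; ++q) {
      if (sp[q] == t + 1) w |= 1 << k;
      else w |= 1 << (int)(k - 1 - (t - sp[q]));
    }
    st.t.push_back((int)t);
    st.w.push_back(w);
  }
}

// anchors p in [l-1, hi] where the window [p-l+1, p] holds >= 1 spike;
// word = message bits (MSB = bin p)
void build_source_stream(const std::vector<int> &sp, int l, int hi,
                         Stream &st) {
  st.t.clear();
  st.w.clear();
  const int n = (int)sp.size();
  int ib = 0, wj = 0;
  long p = (long)l - 2;
  for (;;) {
    while (ib < n && (long)sp[ib] + l - 1 <= p) ++ib;
    if (ib >= n) break;
    p = std::max((long)sp[ib], p + 1);
    if (p > hi) break;
    while (wj < n && sp[wj] < p - l + 1) ++wj;
    int w = 0;
    for (int q = wj; q < n && sp[q] <= p; ++q)
      w |= 1 << (int)(l - 1 - (p - sp[q]));
    st.t.push_back((int)p);
    st.w.push_back(w);
  }
}

// counts of stream entries with word w and anchor in [lo, hi], for each
// delay; entries of each word are anchor-sorted via a counting-sort CSR
struct StreamIndex {
  int nw;
  std::vector<int> ptr;      // word -> [ptr[w], ptr[w+1]) into anchors
  std::vector<int> anchors;  // anchor positions grouped by word, sorted

  void build(const Stream &st, int nw_) {
    nw = nw_;
    ptr.assign(nw + 1, 0);
    for (int w : st.w) ++ptr[w + 1];
    for (int w = 0; w < nw; ++w) ptr[w + 1] += ptr[w];
    anchors.resize(st.t.size());
    std::vector<int> fill(ptr.begin(), ptr.end() - 1);
    for (size_t q = 0; q < st.t.size(); ++q)
      anchors[fill[st.w[q]]++] = st.t[q];
  }

  double count_range(int w, int lo, int hi) const {
    const int *b = anchors.data() + ptr[w], *e = anchors.data() + ptr[w + 1];
    return (double)(std::upper_bound(b, e, hi) - std::lower_bound(b, e, lo));
  }
};

}  // namespace

// [[Rcpp::export]]
List count_patterns_cpp(IntegerVector si, IntegerVector sj, int D,
                        int k, int l, int d) {
  if (k < 1 || k > 5 || l < 1 || l > 5)
    stop("history/message lengths k and l must lie in 1..5");
  std::vector<int> vi(si.begin(), si.end()), vj(sj.begin(), sj.end());
  std::vector<double> cnt((size_t)1 << (k + l + 1));
  long nvalid = count_single(vi, vj, D, k, l, d, cnt);
  return List::create(_["counts"] = NumericVector(cnt.begin(), cnt.end()),
                      _["n_valid"] = (double)nvalid);
}

// Profiles for many ordered pairs: TE (bits) at each delay.
// spikes: list of 0-based sorted bin indices; pairs: 2-column 1-based
// (target i, source j) matrix.
// [[Rcpp::export]]
NumericMatrix te_profiles_cpp(List spikes, int D, int k, int l,
                              IntegerVector delays, IntegerMatrix pairs) {
  const int nn = spikes.size(), np = pairs.nrow(), nd = delays.size();
  if (k < 1 || k > 5 || l < 1 || l > 5)
    stop("history/message lengths k and l must lie in 1..5");
  int dmin = INT_MAX, dmax = 0;
  for (int q = 0; q < nd; ++q) {
    if (delays[q] < 1) stop("delays must be >= 1");
    dmin = std::min(dmin, delays[q]);
    dmax = std::max(dmax, delays[q]);
  }
  const int ndr = dmax - dmin + 1;  // contiguous computed delay range
  if ((long)D - std::max(k, dmax + l - 1) <= 0)
    stop("no valid time positions: series too short for (k, l, d)");
  const int npat = 1 << (k + l + 1);
  const int n_tw = 1 << (k + 1), n_sw = 1 << l;

  std::vector<std::vector<int>> sp(nn);
  for (int n = 0; n < nn; ++n) {
    IntegerVector v(spikes[n]);
    sp[n] = std::vector<int>(v.begin(), v.end());
  }

  // which neurons appear as target / source
  std::vector<char> used_t(nn, 0), used_s(nn, 0);
  for (int p = 0; p < np; ++p) {
    used_t[pairs(p, 0) - 1] = 1;
    used_s[pairs(p, 1) - 1] = 1;
  }

  // per-neuron streams and per-delay marginal word counts
  std::vector<Stream> tstr(nn), sstr(nn);
  // marg_t[n][(d-dmin)*n_tw + w], marg_s[n][(d-dmin)*n_sw + w]
  std::vector<std::vector<double>> marg_t(nn), marg_s(nn);
  std::vector<long> nvalid(ndr);
  for (int d = dmin; d <= dmax; ++d)
    nvalid[d - dmin] = (long)D - std::max(k, d + l - 1);
  {
    StreamIndex idx;
    for (int n = 0; n < nn; ++n) {
      if (used_t[n]) {
        build_target_stream(sp[n], k, D - 2, tstr[n]);
        idx.build(tstr[n], n_tw);
        marg_t[n].assign((size_t)ndr * n_tw, 0.0);
        for (int d = dmin; d <= dmax; ++d) {
          const int tmin = std::max(k - 1, d + l - 2);
          for (int w = 1; w < n_tw; ++w)
            marg_t[n][(size_t)(d - dmin) * n_tw + w] =
                idx.count_range(w, tmin, D - 2);
        }
      }
      if (used_s[n]) {
        build_source_stream(sp[n], l, D - 1 - dmin, sstr[n]);
        idx.build(sstr[n], n_sw);
        marg_s[n].assign((size_t)ndr * n_sw, 0.0);
        for (int d = dmin; d <= dmax; ++d) {
          const int pmin = std::max(k - d, l - 1);
          for (int w = 1; w < n_sw; ++w)
            marg_s[n][(size_t)(d - dmin) * n_sw + w] =
                idx.count_range(w, pmin, D - 1 - d);
        }
      }
    }
  }

  NumericMatrix out(np, nd);
  std::vector<double> cnt((size_t)ndr * npat);
  for (int p = 0; p < np; ++p) {
    const int ti = pairs(p, 0) - 1, sj = pairs(p, 1) - 1;
    const Stream &A = tstr[ti], &B = sstr[sj];
    std::fill(cnt.begin(), cnt.end(), 0.0);

    // join: tally jointly non-zero words for every delay in one pass;
    // a target anchor t pairs with source anchors p = t + 1 - d
    const int nb = (int)B.t.size();
    int jlo = 0;
    for (size_t qa = 0; qa < A.t.size(); ++qa) {
      const long t = A.t[qa];
      const int base_w = A.w[qa] << l;
      while (jlo < nb && B.t[jlo] < t + 1 - dmax) ++jlo;
      for (int qb = jlo; qb < nb && B.t[qb] <= t + 1 - dmin; ++qb) {
        const int d = (int)(t + 1 - B.t[qb]);
        cnt[(size_t)(d - dmin) * npat + (base_w | B.w[qb])] += 1.0;
      }
    }

    for (int q = 0; q < nd; ++q) {
      const int dr = delays[q] - dmin;
      double *tab = &cnt[(size_t)dr * npat];
      const double *mt = &marg_t[ti][(size_t)dr * n_tw];
      const double *ms = &marg_s[sj][(size_t)dr * n_sw];
      // words with a silent source side: marginal minus joint row sums
      double nonzero = 0.0;
      for (int w = 1; w < n_tw; ++w) {
        double row = 0.0;
        for (int v = 1; v < n_sw; ++v) row += tab[(w << l) | v];
        tab[w << l] = mt[w] - row;
        nonzero += mt[w];
      }
      // words with a silent target side
      for (int v = 1; v < n_sw; ++v) {
        double col = 0.0;
        for (int w = 1; w < n_tw; ++w) col += tab[(w << l) | v];
        tab[v] = ms[v] - col;
        nonzero += tab[v];
      }
      tab[0] = nvalid[dr] - nonzero;
      out(p, q) = te_from_table(tab, nvalid[dr], k, l);
    }
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
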