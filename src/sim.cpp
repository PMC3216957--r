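#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Izhikevich cortical network with conduction delays and additive STDP.
//
// Dynamics per 1-ms step (voltage in mV, time in ms):
//   spike when v >= 30, then v <- c, u <- u + d
//   v integrated in two 0.5-ms Euler half-steps of
//     v' = 0.04 v^2 + 5 v + 140 - u + I
//   u integrated once per ms:  u' = a (b v - u)
//
// STDP: each neuron carries an exponentially decaying trace (set to 0.1 at
// firing, multiplied by 0.95 each ms, ~20 ms time constant).  When a neuron
// fires, every excitatory synapse onto it is potentiated by the presynaptic
// trace evaluated at the arrival time of the last presynaptic spike; when a
// spike arrives at a target, the synapse is depressed by 1.2 x the target's
// current trace.  Weight derivatives are folded into the weights once per
// second: s <- clip(0.01 + s + sd, 0, s_max), sd <- 0.9 sd.  Only synapses
// from excitatory neurons are plastic.
//
// Thalamic drive, per ms: scheme 0 delivers a 20-mV input to one uniformly
// chosen neuron (rate 1 Hz/neuron for N = 1000); scheme 1 delivers an
// independent Bernoulli(p) input of the same weight to every neuron.
//
// Synapses of each neuron must be ordered by non-decreasing delay.

// [[Rcpp::export]]
List sim_network_cpp(IntegerMatrix post,     // N x M, 1-based target ids
                     IntegerMatrix delay,    // N x M, integer ms >= 1
                     NumericMatrix weight,   // N x M, signed mV
                     LogicalVector is_exc,   // length N
                     NumericVector a, NumericVector b,
                     NumericVector c, NumericVector d,
                     int stdp_ms, int total_ms, int record_ms,
                     double s_max, double thal_w,
                     int thal_scheme, double thal_p,
                     double seed) {
  const int N = post.nrow(), M = post.ncol();
  // synapse tables as flat arrays, synapse-major per neuron: index n*M + m
  std::vector<int> tgt(static_cast<size_t>(N) * M);
  std::vector<int> dly(static_cast<size_t>(N) * M);
  std::vector<double> s(static_cast<size_t>(N) * M);
  int D = 1;
  for (int n = 0; n < N; ++n) {
    int prev = 0;
    for (int m = 0; m < M; ++m) {
      const int dl = delay(n, m);
      if (dl < 1) stop("delays must be >= 1 ms");
      if (dl < prev) stop("synapses must be sorted by delay within a neuron");
      prev = dl;
      if (dl > D) D = dl;
      const size_t lin = static_cast<size_t>(n) * M + m;
      tgt[lin] = post(n, m) - 1;
      dly[lin] = dl;
      s[lin] = weight(n, m);
    }
  }
  const int ring = D + 1;
  const int rec_start = total_ms - record_ms;

  // per-neuron offsets of the synapse block for each delay value:
  // block for delay dl is [del_start[n][dl-1], del_start[n][dl])
  std::vector<int> del_start(static_cast<size_t>(N) * (D + 1));
  for (int n = 0; n < N; ++n) {
    int m = 0;
    for (int dl = 1; dl <= D + 1; ++dl) {
      while (m < M && dly[static_cast<size_t>(n) * M + m] < dl) ++m;
      if (dl > 1) del_start[static_cast<size_t>(n) * (D + 1) + (dl - 1)] = m;
    }
    del_start[static_cast<size_t>(n) * (D + 1)] = 0;
  }

  // incoming excitatory synapses per target (CSR over linear index n*M + m)
  std::vector<int> pre_ptr(N + 1, 0);
  {
    std::vector<int> cnt(N, 0);
    for (int n = 0; n < N; ++n)
      if (is_exc[n])
        for (int m = 0; m < M; ++m) ++cnt[tgt[static_cast<size_t>(n) * M + m]];
    for (int i = 0; i < N; ++i) pre_ptr[i + 1] = pre_ptr[i] + cnt[i];
  }
  std::vector<int> pre_syn(pre_ptr[N]), pre_src(pre_ptr[N]), pre_dly(pre_ptr[N]);
  {
    std::vector<int> fill(N, 0);
    for (int n = 0; n < N; ++n) {
      if (!is_exc[n]) continue;
      for (int m = 0; m < M; ++m) {
        const size_t lin = static_cast<size_t>(n) * M + m;
        const int t0 = tgt[lin];
        const int at = pre_ptr[t0] + fill[t0]++;
        pre_syn[at] = static_cast<int>(lin);
        pre_src[at] = n;
        pre_dly[at] = dly[lin];
      }
    }
  }

  std::vector<double> sd(static_cast<size_t>(N) * M, 0.0);
  std::vector<double> v(N, -65.0), u(N);
  const double *ap = a.begin(), *bp = b.begin(), *cp = c.begin(),
               *dp = d.begin();
  for (int n = 0; n < N; ++n) u[n] = bp[n] * v[n];
  std::vector<double> I(N), trace(static_cast<size_t>(N) * ring, 0.0);
  std::vector<std::vector<int>> fired_ring(ring);
  std::vector<std::vector<int>> rec_spikes(N);

  SplitMix64 rng(static_cast<uint64_t>(seed));

  for (int t = 0; t < total_ms; ++t) {
    const bool stdp_on = t < stdp_ms;
    const int col = t % ring;
    double *tr_cur = &trace[static_cast<size_t>(col) * N];
    {
      const double *tr_prev =
          &trace[static_cast<size_t>((t + ring - 1) % ring) * N];
      for (int n = 0; n < N; ++n) tr_cur[n] = 0.95 * tr_prev[n];
    }

    double *Ip = I.data();
    std::fill(I.begin(), I.end(), 0.0);
    if (thal_scheme == 0) {
      // one input per ms to a uniformly chosen neuron; delivered with
      // probability N*p per ms so the per-neuron rate is honored for
      // rates other than the canonical 1/ms total
      if (N * thal_p >= 1.0 || rng.unif() < N * thal_p) {
        int n0 = rng.unif_int(N);
        if (n0 >= N) n0 = N - 1;
        Ip[n0] = thal_w;
      }
    } else {
      for (int n = 0; n < N; ++n)
        if (rng.unif() < thal_p) Ip[n] += thal_w;
    }

    std::vector<int> &fired = fired_ring[col];
    fired.clear();
    for (int n = 0; n < N; ++n) {
      if (v[n] >= 30.0) {
        v[n] = cp[n];
        u[n] += dp[n];
        tr_cur[n] = 0.1;
        fired.push_back(n);
        if (t >= rec_start) rec_spikes[n].push_back(t - rec_start);
      }
    }

    if (stdp_on) {
      // potentiation by the presynaptic trace at the last arrival time
      for (int fi : fired) {
        for (int p = pre_ptr[fi]; p < pre_ptr[fi + 1]; ++p) {
          const int tc = t - pre_dly[p];
          if (tc < 0) continue;  // trace buffer is zero before t = 0
          sd[pre_syn[p]] +=
              trace[static_cast<size_t>(tc % ring) * N + pre_src[p]];
        }
      }
    }

    // deliver spikes whose conduction delay elapses this ms
    for (int off = 0; off < D; ++off) {
      const int f = t - off;
      if (f < 0) break;
      const int need = off + 1;  // delay serviced at this offset
      for (int n : fired_ring[f % ring]) {
        const int *ds = &del_start[static_cast<size_t>(n) * (D + 1)];
        const size_t base = static_cast<size_t>(n) * M;
        const int m1 = ds[need];
        if (stdp_on && is_exc[n]) {
          for (int m = ds[need - 1]; m < m1; ++m) {
            const int t0 = tgt[base + m];
            Ip[t0] += s[base + m];
            sd[base + m] -= 1.2 * tr_cur[t0];
          }
        } else {
          for (int m = ds[need - 1]; m < m1; ++m)
            Ip[tgt[base + m]] += s[base + m];
        }
      }
    }

    for (int n = 0; n < N; ++n) {
      double vn = v[n];
      const double un = u[n], In = Ip[n];
      vn += 0.5 * ((0.04 * vn + 5.0) * vn + 140.0 - un + In);
      vn += 0.5 * ((0.04 * vn + 5.0) * vn + 140.0 - un + In);
      v[n] = vn;
      u[n] = un + ap[n] * (bp[n] * vn - un);
    }

    if ((t + 1) % 1000 == 0) {
      for (int n = 0; n < N; ++n)
        if (!std::isfinite(v[n]))
          stop("membrane potential diverged (neuron %d, t = %d ms)",
               n + 1, t);
      if (stdp_on) {
        for (int n = 0; n < N; ++n) {
          if (!is_exc[n]) continue;
          const size_t base = static_cast<size_t>(n) * M;
          for (int m = 0; m < M; ++m) {
            const double w = 0.01 + s[base + m] + sd[base + m];
            s[base + m] = w < 0.0 ? 0.0 : (w > s_max ? s_max : w);
            sd[base + m] *= 0.9;
          }
        }
      }
      Rcpp::checkUserInterrupt();
    }
  }

  List spikes(N);
  for (int n = 0; n < N; ++n)
    spikes[n] = IntegerVector(rec_spikes[n].begin(), rec_spikes[n].end());
  NumericMatrix s_out(N, M);
  for (int n = 0; n < N; ++n)
    for (int m = 0; m < M; ++m)
      s_out(n, m) = s[static_cast<size_t>(n) * M + m];
  return List::create(_["spikes"] = spikes, _["weights"] = s_out);
}
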